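#' Specify a penalized smooth term
#'
#' Describes one smooth term of an additive model: a cubic B-spline (P-spline)
#' smooth of a single covariate, or a tensor-product surface of two covariates
#' (used for the longitude/latitude adjustment). The roughness penalty is a
#' difference penalty of order \code{pord} on the basis coefficients; with
#' \code{double_penalty = TRUE} an extra penalty on the null space of the
#' roughness penalty is added, so the whole term can be shrunk out of the
#' model.
#'
#' @param vars character vector of one (univariate) or two (tensor) covariate
#'   names.
#' @param k basis dimension; scalar for univariate terms, length-2 for tensor
#'   terms (marginal dimensions). Must satisfy \code{k >= pord + 2}.
#' @param pord difference-penalty order (default 2: second differences, so the
#'   penalty null space is the linear trend).
#' @param double_penalty logical; add the null-space shrinkage penalty.
#' @param label term label; defaults to the variable names joined by ":".
#' @return An object of class \code{"sm_spec"}.
#' @export
sm <- function(vars, k = NULL, pord = 2L, double_penalty = FALSE, label = NULL) {
  vars <- as.character(vars)
  if (!length(vars) %in% 1:2) stopf("sm(): 'vars' must name 1 or 2 covariates")
  if (is.null(k)) k <- if (length(vars) == 2L) c(5L, 5L) else 10L
  k <- as.integer(k)
  if (length(k) == 1L && length(vars) == 2L) k <- rep(k, 2L)
  if (length(k) != length(vars)) stopf("sm(): length of 'k' must match 'vars'")
  pord <- as.integer(pord)
  if (any(k < pord + 2L)) stopf("sm(): basis size k must be >= pord + 2")
  structure(
    list(vars = vars, k = k, pord = pord,
         double_penalty = isTRUE(double_penalty),
         label = label %||% paste(vars, collapse = ":")),
    class = "sm_spec")
}

# Evenly spaced cubic B-spline knots covering range(x), giving k basis columns.
ps_knots <- function(xr, k) {
  if (diff(xr) <= 0) xr <- xr + c(-0.5, 0.5)
  dx <- diff(xr) / (k - 3L)
  seq(xr[1] - 3 * dx, xr[2] + 3 * dx, by = dx)
}

ps_eval <- function(x, knots) {
  splines::splineDesign(knots, x, ord = 4L, outer.ok = TRUE)
}

diff_penalty <- function(k, pord) {
  D <- diff(diag(k), differences = pord)
  crossprod(D)
}

null_range_split <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  tol <- max(e$values) * 1e-7
  null_idx <- which(e$values < tol)
  list(null = e$vectors[, null_idx, drop = FALSE], values = e$values)
}

#' Build a penalized spline design block
#'
#' Constructs the design and penalty matrices for one smooth term: a cubic
#' B-spline basis with evenly spaced knots over the observed covariate range,
#' an order-\code{pord} difference penalty, and a sum-to-zero identifiability
#' constraint absorbed into the columns (so the block is orthogonal to the
#' intercept over the observed data). Tensor-product terms combine two
#' marginal bases row-wise and carry one penalty per margin.
#'
#' @param data data frame (or list) holding the covariate(s).
#' @param spec an [sm()] specification.
#' @return A list with elements \code{X} (constrained design block),
#'   \code{S} (list of constrained penalty matrices), \code{S_raw}
#'   (unconstrained penalties), \code{S_null} (null-space shrinkage penalty of
#'   the constrained total penalty), \code{Z} (constraint transform),
#'   \code{knots}, \code{xrange} and the originating \code{spec}.
#' @export
build_basis <- function(data, spec) {
  stopifnot(inherits(spec, "sm_spec"))
  vars <- spec$vars
  for (v in vars) {
    if (is.null(data[[v]])) stopf("build_basis(): covariate '%s' not found", v)
    if (anyNA(data[[v]])) stopf("build_basis(): covariate '%s' has missing values", v)
  }
  if (length(vars) == 1L) {
    x <- as.numeric(data[[vars]])
    if (length(unique(x)) < spec$k) {
      stopf("build_basis(): %d distinct values of '%s' but k=%d requested",
            length(unique(x)), vars, spec$k)
    }
    xr <- range(x)
    knots <- ps_knots(xr, spec$k)
    B <- ps_eval(x, knots)
    S_raw <- list(diff_penalty(spec$k, spec$pord))
    knots <- list(knots)
    xrange <- list(xr)
  } else {
    x1 <- as.numeric(data[[vars[1]]]); x2 <- as.numeric(data[[vars[2]]])
    k1 <- spec$k[1]; k2 <- spec$k[2]
    xr1 <- range(x1); xr2 <- range(x2)
    kn1 <- ps_knots(xr1, k1); kn2 <- ps_knots(xr2, k2)
    B1 <- ps_eval(x1, kn1); B2 <- ps_eval(x2, kn2)
    B <- B1[, rep(seq_len(k1), each = k2), drop = FALSE] *
      B2[, rep(seq_len(k2), times = k1), drop = FALSE]
    S_raw <- list(diff_penalty(k1, spec$pord) %x% diag(k2),
                  diag(k1) %x% diff_penalty(k2, spec$pord))
    knots <- list(kn1, kn2)
    xrange <- list(xr1, xr2)
  }
  # absorb the sum-to-zero constraint: columns of Z span the null space of
  # the column-sum functional, so colSums(B %*% Z) == 0
  cs <- matrix(colSums(B), ncol = 1L)
  qr_cs <- qr(cs)
  Z <- qr.Q(qr_cs, complete = TRUE)[, -1L, drop = FALSE]
  Xc <- B %*% Z
  Sc <- lapply(S_raw, function(S) crossprod(Z, S %*% Z))
  S_tot <- Reduce(`+`, Sc)
  S_null <- {
    ns <- null_range_split(S_tot)$null
    tcrossprod(ns)
  }
  structure(
    list(X = Xc, S = Sc, S_raw = S_raw, S_null = S_null, Z = Z,
         knots = knots, xrange = xrange, spec = spec),
    class = "pgam_basis")
}

# Evaluate a fitted basis block on new covariate values. Values outside the
# training range are clamped to the range boundary (constant extrapolation)
# with a warning, matching the documented prediction contract.
eval_basis <- function(basis, data, warn_extrapolate = TRUE) {
  vars <- basis$spec$vars
  xs <- vector("list", length(vars))
  for (i in seq_along(vars)) {
    v <- vars[i]
    if (is.null(data[[v]])) stopf("prediction data lacks covariate '%s'", v)
    x <- as.numeric(data[[v]])
    xr <- basis$xrange[[i]]
    out_of <- x < xr[1] | x > xr[2]
    if (any(out_of)) {
      if (warn_extrapolate) {
        warnf("covariate '%s': %d value(s) outside training range [%.4g, %.4g]; using boundary value",
              v, sum(out_of), xr[1], xr[2])
      }
      x <- clamp(x, xr[1], xr[2])
    }
    xs[[i]] <- x
  }
  if (length(vars) == 1L) {
    B <- ps_eval(xs[[1]], basis$knots[[1]])
  } else {
    k1 <- basis$spec$k[1]; k2 <- basis$spec$k[2]
    B1 <- ps_eval(xs[[1]], basis$knots[[1]])
    B2 <- ps_eval(xs[[2]], basis$knots[[2]])
    B <- B1[, rep(seq_len(k1), each = k2), drop = FALSE] *
      B2[, rep(seq_len(k2), times = k1), drop = FALSE]
  }
  out <- B %*% basis$Z
  if (!is.null(basis$restrict)) out <- out %*% basis$restrict
  out
}
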