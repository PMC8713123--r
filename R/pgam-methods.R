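#' Predict from a penalized additive model
#'
#' Evaluates the stored basis definitions on new data. Covariate values
#' outside the training range are allowed but clamped to the boundary
#' (constant extrapolation) with a warning; unknown factor levels are an
#' error.
#'
#' @param object a [fit_pgam()] result.
#' @param newdata data frame of covariates; defaults to the training design.
#' @param type "response" (probabilities / means) or "link".
#' @param se.fit logical; also return pointwise standard errors (on the link
#'   scale).
#' @param ... unused.
#' @return A numeric vector, or a list with \code{fit} and \code{se.fit}.
#' @export
predict.pgam <- function(object, newdata = NULL, type = c("response", "link"),
                         se.fit = FALSE, ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- object$linear_predictor
    X <- object$design$X
  } else {
    newdata <- as.data.frame(newdata)
    n <- nrow(newdata)
    X <- matrix(1, n, 1L)
    for (ci in object$design$col_info) {
      if (ci$type == "intercept") next
      if (ci$type == "factor") {
        meta <- object$design$factor_meta[[ci$term]]
        v <- as.character(newdata[[ci$term]])
        if (is.null(newdata[[ci$term]])) stopf("newdata lacks factor '%s'", ci$term)
        bad <- setdiff(unique(v), meta$levels)
        if (length(bad)) {
          stopf("unknown level(s) for factor '%s': %s", ci$term, paste(bad, collapse = ", "))
        }
        vf <- factor(v, levels = meta$levels)
        M <- outer(vf, meta$levels[-1L], `==`) * 1
        X <- cbind(X, M)
      } else {
        X <- cbind(X, eval_basis(object$design$bases[[ci$term]], newdata))
      }
    }
    eta <- drop(X %*% object$coefficients)
  }
  out <- if (type == "response" && object$spec$family == "binomial") {
    stats::plogis(eta)
  } else eta
  if (se.fit) {
    se <- sqrt(pmax(rowSums((X %*% object$Vb) * X), 0))
    list(fit = out, se.fit = se)
  } else out
}

#' Partial effect of a smooth term
#'
#' The centered contribution of one univariate smooth term to the linear
#' predictor, on a grid over the observed covariate range, with a pointwise
#' 95% interval from the Bayesian coefficient covariance. The term is flagged
#' significant when no horizontal line fits inside the band.
#'
#' @param fit a [fit_pgam()] result.
#' @param term smooth term label (see \code{names(fit$edf_term)}).
#' @param n_grid grid size.
#' @param scale "link" (default: centered effect on the linear predictor) or
#'   "response" (binomial only: probability obtained by adding the intercept
#'   and holding all other terms at their reference/centered zero).
#' @return Object of class \code{"partial_effect"}: data frame \code{grid}
#'   with columns \code{x}, \code{effect}, \code{lo}, \code{hi} (plus
#'   \code{prob}, \code{prob_lo}, \code{prob_hi} on the response scale) and
#'   attributes \code{term} and \code{significant}.
#' @export
partial_effect <- function(fit, term, n_grid = 100L,
                           scale = c("link", "response")) {
  scale <- match.arg(scale)
  stopifnot(inherits(fit, "pgam"))
  basis <- fit$design$bases[[term]]
  if (is.null(basis)) stopf("unknown smooth term '%s'", term)
  if (length(basis$spec$vars) != 1L) {
    stopf("partial_effect() supports univariate terms; '%s' is bivariate", term)
  }
  ci <- Filter(function(z) z$term == term, fit$design$col_info)[[1]]
  xr <- basis$xrange[[1]]
  grid <- seq(xr[1], xr[2], length.out = n_grid)
  nd <- stats::setNames(data.frame(grid), basis$spec$vars)
  G <- eval_basis(basis, nd, warn_extrapolate = FALSE)
  beta <- fit$coefficients[ci$idx]
  eff <- drop(G %*% beta)
  V <- fit$Vb[ci$idx, ci$idx, drop = FALSE]
  se <- sqrt(pmax(rowSums((G %*% V) * G), 0))
  lo <- eff - 1.96 * se
  hi <- eff + 1.96 * se
  significant <- max(lo) > min(hi)  # no horizontal line fits inside the band
  out <- data.frame(x = grid, effect = eff, lo = lo, hi = hi)
  if (scale == "response") {
    if (fit$spec$family != "binomial") {
      stopf("response-scale partial effects require the binomial family")
    }
    b0 <- fit$coefficients[[1]]
    out$prob <- stats::plogis(b0 + eff)
    out$prob_lo <- stats::plogis(b0 + lo)
    out$prob_hi <- stats::plogis(b0 + hi)
  }
  structure(out, term = term, significant = significant,
            class = c("partial_effect", "data.frame"))
}

#' @export
print.partial_effect <- function(x, ...) {
  cat(sprintf("Partial effect of %s over [%.4g, %.4g]: %s\n",
              attr(x, "term"), min(x$x), max(x$x),
              if (attr(x, "significant")) "significant" else "not significant"))
  invisible(x)
}

#' Concordance statistic (C-index / AUROC)
#'
#' Probability that a randomly chosen case receives a higher predicted risk
#' than a randomly chosen non-case, ties counted one half; identical to the
#' area under the ROC curve for a binary outcome. The confidence interval is
#' a stratified bootstrap (cases and non-cases resampled separately).
#'
#' @param pred numeric predictions (any strictly increasing transform gives
#'   the same value).
#' @param outcome binary outcome (0/1 or logical).
#' @param n_boot bootstrap resamples for the interval (0 to skip).
#' @param conf confidence level.
#' @param seed integer seed for the bootstrap.
#' @return List with \code{value}, \code{ci} (or NULL) and \code{n_boot}.
#' @export
c_index <- function(pred, outcome, n_boot = 2000L, conf = 0.95, seed = 1L) {
  y <- as.numeric(outcome)
  stopifnot(length(pred) == length(y), all(y %in% c(0, 1)))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) stopf("c_index(): both outcome classes must be present")
  auc_of <- function(p, yy) {
    r <- rank(p)  # midranks handle ties at the half-credit convention
    (sum(r[yy == 1]) - sum(yy == 1) * (sum(yy == 1) + 1) / 2) / (sum(yy == 1) * sum(yy == 0))
  }
  value <- auc_of(pred, y)
  ci <- NULL
  if (n_boot > 0L) {
    idx1 <- which(y == 1); idx0 <- which(y == 0)
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
    set.seed(seed)
    boots <- vapply(seq_len(n_boot), function(b) {
      i <- c(sample(idx1, n1, replace = TRUE), sample(idx0, n0, replace = TRUE))
      auc_of(pred[i], y[i])
    }, 0)
    a <- (1 - conf) / 2
    ci <- unname(stats::quantile(boots, c(a, 1 - a)))
  }
  list(value = value, ci = ci, n_boot = n_boot)
}
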