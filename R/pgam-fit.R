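#' Specify a penalized additive model
#'
#' A model is an intercept plus a set of penalized smooth terms ([sm()]) plus
#' categorical covariates entered as treatment-coded factors, with a binomial
#' (logit link) or Gaussian (identity link) response.
#'
#' @param outcome name of the outcome column (binary 0/1, logical, two-level
#'   factor for binomial; numeric for Gaussian).
#' @param smooths list of [sm()] term specifications.
#' @param factors character vector of categorical covariate names.
#' @param family "binomial" or "gaussian".
#' @param refs optional named list of reference levels for factors; by default
#'   the first factor level is the reference.
#' @return An object of class \code{"pgam_spec"}.
#' @export
pgam_spec <- function(outcome, smooths = list(), factors = character(),
                      family = c("binomial", "gaussian"), refs = list()) {
  family <- match.arg(family)
  if (inherits(smooths, "sm_spec")) smooths <- list(smooths)
  for (s in smooths) stopifnot(inherits(s, "sm_spec"))
  covs <- c(unlist(lapply(smooths, `[[`, "vars")), factors)
  if (anyDuplicated(covs)) {
    stopf("pgam_spec(): covariate(s) appear more than once: %s",
          paste(unique(covs[duplicated(covs)]), collapse = ", "))
  }
  labels <- vapply(smooths, `[[`, "", "label")
  if (anyDuplicated(c(labels, factors))) stopf("pgam_spec(): duplicated term labels")
  structure(list(outcome = outcome, smooths = smooths, factors = factors,
                 family = family, refs = refs),
            class = "pgam_spec")
}

#' Fitting control parameters for [fit_pgam()]
#'
#' @param inner_tol relative convergence tolerance on the penalized deviance
#'   in the inner penalized IRLS loop.
#' @param inner_maxit maximum inner iterations.
#' @param outer_tol convergence tolerance on max absolute change in
#'   log smoothing parameters in the outer REML loop.
#' @param outer_maxit maximum outer iterations.
#' @param lambda_init initial smoothing parameter.
#' @param lambda_min,lambda_max box constraints on smoothing parameters.
#' @param step_clamp per-iteration bound on the multiplicative smoothing
#'   parameter update factor.
#' @param edf_drop effective-degrees-of-freedom threshold below which a
#'   double-penalized term counts as selected out of the model.
#' @return A list of control values.
#' @export
pgam_control <- function(inner_tol = 1e-8, inner_maxit = 200,
                         outer_tol = 1e-3, outer_maxit = 50,
                         lambda_init = 1, lambda_min = 1e-7, lambda_max = 1e9,
                         step_clamp = 100, edf_drop = 0.05,
                         separation_guard = TRUE) {
  list(inner_tol = inner_tol, inner_maxit = inner_maxit,
       outer_tol = outer_tol, outer_maxit = outer_maxit,
       lambda_init = lambda_init, lambda_min = lambda_min,
       lambda_max = lambda_max, step_clamp = step_clamp, edf_drop = edf_drop,
       separation_guard = separation_guard)
}

# ---- internal: design assembly ------------------------------------------

assemble_design <- function(spec, data) {
  n <- nrow(data)
  blocks <- list()
  X <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  col_info <- list(list(term = "(Intercept)", type = "intercept", idx = 1L))
  factor_meta <- list()
  for (f in spec$factors) {
    v <- data[[f]]
    if (is.null(v)) stopf("factor '%s' not found in data", f)
    if (anyNA(v)) stopf("factor '%s' has missing values", f)
    v <- as.factor(v)
    v <- droplevels(v)
    if (nlevels(v) < 2L) stopf("factor '%s' has fewer than 2 observed levels", f)
    ref <- spec$refs[[f]] %||% levels(v)[1]
    if (!ref %in% levels(v)) stopf("reference level '%s' not observed for factor '%s'", ref, f)
    v <- stats::relevel(v, ref = ref)
    M <- stats::model.matrix(~v)[, -1L, drop = FALSE]
    colnames(M) <- paste0(f, ":", levels(v)[-1L])
    idx <- ncol(X) + seq_len(ncol(M))
    X <- cbind(X, M)
    col_info[[length(col_info) + 1L]] <- list(term = f, type = "factor", idx = idx)
    factor_meta[[f]] <- list(levels = levels(v), ref = ref)
  }
  bases <- list()
  for (s in spec$smooths) {
    b <- build_basis(data, s)
    idx <- ncol(X) + seq_len(ncol(b$X))
    Xb <- b$X
    colnames(Xb) <- paste0(s$label, ".", seq_len(ncol(Xb)))
    X <- cbind(X, Xb)
    col_info[[length(col_info) + 1L]] <- list(term = s$label, type = "smooth", idx = idx)
    bases[[s$label]] <- b
  }
  # penalties, expanded to full coefficient dimension
  p <- ncol(X)
  pens <- list()
  for (s in spec$smooths) {
    b <- bases[[s$label]]
    idx <- col_info[[which(vapply(col_info, `[[`, "", "term") == s$label)]]$idx
    for (m in seq_along(b$S)) {
      Sf <- matrix(0, p, p)
      Sf[idx, idx] <- b$S[[m]]
      pens[[length(pens) + 1L]] <- list(term = s$label, kind = "range", S = Sf)
    }
    if (s$double_penalty) {
      Sf <- matrix(0, p, p)
      Sf[idx, idx] <- b$S_null
      pens[[length(pens) + 1L]] <- list(term = s$label, kind = "null", S = Sf)
    }
  }
  list(X = X, col_info = col_info, bases = bases, pens = pens,
       factor_meta = factor_meta)
}

# Replace every smooth term whose penalties are all forced to infinity by
# its penalty-null-space columns (no remaining penalty); terms mixing finite
# and infinite smoothing parameters are not supported.
restrict_infinite_terms <- function(des, lambda) {
  terms <- vapply(des$pens, `[[`, "", "term")
  restricted <- list()
  for (tm in unique(terms)) {
    ms <- which(terms == tm)
    inf <- !is.finite(lambda[ms])
    if (!any(inf)) next
    if (!all(inf)) stopf("term '%s': cannot mix finite and infinite lambdas", tm)
    ci <- Filter(function(z) z$term == tm, des$col_info)[[1]]
    Sb <- Reduce(`+`, lapply(des$pens[ms], function(p) p$S[ci$idx, ci$idx, drop = FALSE]))
    restricted[[tm]] <- null_range_split(Sb)$null
    des$bases[[tm]]$restrict <- restricted[[tm]]
  }
  if (!length(restricted)) return(des)
  # rebuild the design with restricted blocks narrowed in place
  old_info <- des$col_info
  blocks <- list()
  col_info <- list()
  new_idx <- list()
  pos <- 0L
  for (ci in old_info) {
    blk <- des$X[, ci$idx, drop = FALSE]
    if (ci$term %in% names(restricted)) blk <- blk %*% restricted[[ci$term]]
    if (ncol(blk) == 0L) next
    blocks[[length(blocks) + 1L]] <- blk
    idx_new <- pos + seq_len(ncol(blk))
    pos <- pos + ncol(blk)
    ci_old_idx <- ci$idx
    ci$idx <- idx_new
    col_info[[length(col_info) + 1L]] <- ci
    new_idx[[ci$term]] <- list(old = ci_old_idx, new = idx_new)
  }
  p_new <- pos
  pens <- list()
  for (m in seq_along(des$pens)) {
    pe <- des$pens[[m]]
    if (pe$term %in% names(restricted)) next
    mapping <- new_idx[[pe$term]]
    Sf <- matrix(0, p_new, p_new)
    Sf[mapping$new, mapping$new] <- pe$S[mapping$old, mapping$old, drop = FALSE]
    pe$S <- Sf
    pens[[length(pens) + 1L]] <- pe
  }
  des$X <- do.call(cbind, blocks)
  des$col_info <- col_info
  des$pens <- pens
  des
}

penalty_total <- function(pens, lambda) {
  if (!length(pens)) return(NULL)
  S <- lambda[1] * pens[[1]]$S
  for (m in seq_along(pens)[-1]) S <- S + lambda[m] * pens[[m]]$S
  S
}

# ---- internal: penalized IRLS -------------------------------------------

binomial_dev <- function(y, mu) {
  mu <- clamp(mu, 1e-12, 1 - 1e-12)
  -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
}

pirls <- function(X, y, S_lam, family, beta0 = NULL, control) {
  n <- nrow(X); p <- ncol(X)
  if (is.null(S_lam)) S_lam <- matrix(0, p, p)
  if (family == "gaussian") {
    H <- crossprod(X) + S_lam
    sol <- chol_solve(H, crossprod(X, y))
    beta <- drop(sol$x)
    eta <- drop(X %*% beta)
    dev <- sum((y - eta)^2)
    return(list(beta = beta, eta = eta, mu = eta, w = rep(1, n),
                deviance = dev, pen_dev_trace = dev + drop(crossprod(beta, S_lam %*% beta)),
                converged = TRUE, iter = 1L, XtWX = crossprod(X)))
  }
  beta <- beta0 %||% rep(0, p)
  if (is.null(beta0)) beta[1] <- stats::qlogis(clamp(mean(y), 0.01, 0.99))
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  pdev <- binomial_dev(y, mu) + drop(crossprod(beta, S_lam %*% beta))
  trace <- pdev
  converged <- FALSE
  for (it in seq_len(control$inner_maxit)) {
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    Xw <- X * w
    H <- crossprod(Xw, X) + S_lam
    beta_new <- drop(chol_solve(H, crossprod(Xw, z))$x)
    # step halving on the penalized deviance
    step <- 1
    repeat {
      beta_try <- beta + step * (beta_new - beta)
      eta_try <- drop(X %*% beta_try)
      mu_try <- stats::plogis(eta_try)
      pdev_try <- binomial_dev(y, mu_try) + drop(crossprod(beta_try, S_lam %*% beta_try))
      if (is.finite(pdev_try) && pdev_try <= pdev + 1e-10) break
      step <- step / 2
      if (step < 1e-8) { beta_try <- beta; eta_try <- eta; mu_try <- mu; pdev_try <- pdev; break }
    }
    delta <- abs(pdev - pdev_try) / (abs(pdev) + 0.1)
    beta <- beta_try; eta <- eta_try; mu <- mu_try; pdev <- pdev_try
    trace <- c(trace, pdev)
    if (delta < control$inner_tol) { converged <- TRUE; break }
  }
  w <- pmax(mu * (1 - mu), 1e-10)
  list(beta = beta, eta = eta, mu = mu, w = w,
       deviance = binomial_dev(y, mu), pen_dev_trace = trace,
       converged = converged, iter = length(trace) - 1L,
       XtWX = crossprod(X * w, X))
}

# Total penalty, its range-space pseudoinverse and positive log-determinant.
# Computed blockwise per smooth term: penalties of different terms occupy
# disjoint coefficient blocks, and a global eigenvalue tolerance would
# misclassify a lightly penalized block as null space whenever another
# term's smoothing parameter is many orders of magnitude larger.
penalty_blocks <- function(pens, lambda, p) {
  S <- matrix(0, p, p)
  pinv <- matrix(0, p, p)
  logdet <- 0
  rank <- 0L
  if (length(pens)) {
    terms <- vapply(pens, `[[`, "", "term")
    for (tm in unique(terms)) {
      ms <- which(terms == tm)
      idx <- which(colSums(abs(pens[[ms[1]]]$S)) > 0 | diag(pens[[ms[1]]]$S) > 0)
      Sb <- matrix(0, length(idx), length(idx))
      Sb1 <- Sb  # unweighted structural sum over active penalties
      for (m in ms) {
        Sb <- Sb + lambda[m] * pens[[m]]$S[idx, idx]
        if (lambda[m] > 0) Sb1 <- Sb1 + pens[[m]]$S[idx, idx]
      }
      S[idx, idx] <- S[idx, idx] + Sb
      # rank is a structural property; a magnitude cut-off on the weighted
      # sum would misclassify genuine eigenvalues whenever the block mixes
      # smoothing parameters of very different sizes (e.g. double penalty)
      e1 <- eigen(Sb1, symmetric = TRUE, only.values = TRUE)$values
      r0 <- sum(e1 > max(e1, 0) * 1e-9)
      if (r0 > 0L) {
        e <- eigen(Sb, symmetric = TRUE)
        keep <- seq_len(r0)
        vals <- pmax(e$values[keep], 1e-300)
        U <- e$vectors[, keep, drop = FALSE]
        pinv[idx, idx] <- pinv[idx, idx] + U %*% (t(U) / vals)
        logdet <- logdet + sum(log(vals))
        rank <- rank + r0
      }
    }
  }
  list(S = S, pinv = pinv, logdet_pos = logdet, rank = rank)
}

logdet_chol <- function(H) {
  R <- tryCatch(chol(H), error = function(e) NULL)
  if (is.null(R)) R <- chol(H + diag(mean(abs(diag(H))) * 1e-8, ncol(H)))
  2 * sum(log(diag(R)))
}

# Restricted marginal likelihood criterion (to be maximized over lambda).
# Binomial: Laplace approximation at the penalized MLE with scale 1.
# Gaussian: profile REML with the scale integrated out (up to lambda-free
# constants; the positive-penalty rank is constant across lambda > 0).
laml_criterion <- function(fit, pinfo, family, n) {
  S_lam <- pinfo$S
  pen <- drop(crossprod(fit$beta, S_lam %*% fit$beta))
  logH <- logdet_chol(fit$XtWX + S_lam)
  if (family == "binomial") {
    ll <- -fit$deviance / 2  # saturated loglik is 0 for binary outcomes
    ll - pen / 2 + pinfo$logdet_pos / 2 - logH / 2
  } else {
    M0 <- ncol(S_lam) - pinfo$rank
    rss_p <- max(fit$deviance + pen, 1e-300)
    -(n - M0) / 2 * log(rss_p) + pinfo$logdet_pos / 2 - logH / 2
  }
}

#' Fit a penalized additive model
#'
#' Fits the model by penalized IRLS for fixed smoothing parameters, with the
#' smoothing parameters chosen by a (Laplace-approximate, for the binomial
#' family) restricted marginal likelihood criterion optimized with the
#' generalized Fellner-Schall multiplicative update. Effective degrees of
#' freedom are the trace of the influence matrix; AIC is
#' \code{-2*loglik + 2*EDF} (plus one df for the Gaussian scale).
#'
#' @param spec a [pgam_spec()].
#' @param data data frame with the outcome and all covariates (complete cases).
#' @param control a [pgam_control()] list.
#' @param fixed_lambda optional numeric vector (recycled) forcing all
#'   smoothing parameters to fixed values, bypassing REML selection. Use large
#'   values to recover the penalty-null-space (e.g. linear) fit and 0 for the
#'   unpenalized fit.
#' @param lambda_start optional warm-start vector of smoothing parameters.
#' @return An object of class \code{"pgam"}; see the package vignette for the
#'   stored components (coefficients, per-term smoothing parameters and EDF,
#'   log-likelihood, AIC, deviances, Bayesian coefficient covariance,
#'   odds-ratio table for factor levels under the binomial family).
#' @export
fit_pgam <- function(spec, data, control = pgam_control(),
                     fixed_lambda = NULL, lambda_start = NULL) {
  stopifnot(inherits(spec, "pgam_spec"))
  data <- as.data.frame(data)
  n <- nrow(data)
  if (n < 30L) stopf("fit_pgam(): need at least 30 rows, got %d", n)
  yraw <- data[[spec$outcome]]
  if (is.null(yraw)) stopf("outcome '%s' not found", spec$outcome)
  if (anyNA(yraw)) stopf("outcome '%s' has missing values", spec$outcome)
  if (spec$family == "binomial") {
    if (is.logical(yraw)) y <- as.numeric(yraw)
    else if (is.factor(yraw)) {
      if (nlevels(yraw) != 2L) stopf("binomial outcome must have two levels")
      y <- as.numeric(yraw == levels(yraw)[2])
    } else {
      y <- as.numeric(yraw)
      if (!all(y %in% c(0, 1))) stopf("binomial outcome must be 0/1")
    }
    if (length(unique(y)) < 2L) stopf("outcome has a single observed class")
  } else y <- as.numeric(yraw)

  des <- assemble_design(spec, data)
  if (!is.null(fixed_lambda) && any(!is.finite(fixed_lambda))) {
    # lambda forced to infinity: restrict each (fully) infinite-penalty term
    # to the null space of its total penalty, exactly reproducing the
    # unpenalized null-space (e.g. linear) fit
    lam_full <- rep_len(fixed_lambda, length(des$pens))
    des <- restrict_infinite_terms(des, lam_full)
    fixed_lambda <- lam_full[is.finite(lam_full)]
    if (!length(des$pens)) fixed_lambda <- 0
  }
  X <- des$X; pens <- des$pens
  nlam <- length(pens)
  if (!is.null(fixed_lambda)) {
    lambda <- rep_len(pmax(fixed_lambda, 0), nlam)
    outer_iters <- 0L
    fit <- pirls(X, y, penalty_total(pens, lambda), spec$family, control = control)
  } else if (nlam == 0L) {
    lambda <- numeric(0)
    outer_iters <- 0L
    fit <- pirls(X, y, NULL, spec$family, control = control)
  } else {
    lambda <- rep_len(lambda_start %||% control$lambda_init, nlam)
    lambda <- clamp(lambda, control$lambda_min, control$lambda_max)
    outer_iters <- 0L
    pinfo <- penalty_blocks(pens, lambda, ncol(X))
    fit <- pirls(X, y, pinfo$S, spec$family, control = control)
    V_cur <- laml_criterion(fit, pinfo, spec$family, n)
    for (ot in seq_len(control$outer_maxit)) {
      outer_iters <- ot
      S_lam <- pinfo$S
      A <- fit$XtWX
      Hinv <- chol_inv(A + S_lam)
      phi <- if (spec$family == "gaussian") {
        edf_t <- sum(Hinv * A)
        max(fit$deviance, 1e-300) / max(n - edf_t, 1)
      } else 1
      Spinv <- pinfo$pinv
      # generalized Fellner-Schall proposal, per penalty
      lambda_prop <- lambda
      for (m in seq_len(nlam)) {
        Sm <- pens[[m]]$S
        num <- sum(Spinv * Sm) - sum(Hinv * Sm)
        den <- drop(crossprod(fit$beta, Sm %*% fit$beta)) / phi
        if (den <= 1e-14 || num <= 0) {
          fac <- if (den <= 1e-14) control$step_clamp else 1 / control$step_clamp
        } else {
          fac <- clamp(num / den, 1 / control$step_clamp, control$step_clamp)
        }
        lambda_prop[m] <- clamp(lambda[m] * fac, control$lambda_min, control$lambda_max)
      }
      dlog_full <- max(abs(log(lambda_prop) - log(lambda)))
      if (dlog_full < control$outer_tol) break
      # accept the proposal only if it improves the REML criterion,
      # halving the log-step otherwise (guards binomial separation runaway)
      step <- 1
      accepted <- FALSE
      for (h in 1:6) {
        lam_try <- clamp(exp(log(lambda) + step * (log(lambda_prop) - log(lambda))),
                         control$lambda_min, control$lambda_max)
        pinfo_try <- penalty_blocks(pens, lam_try, ncol(X))
        fit_try <- pirls(X, y, pinfo_try$S, spec$family, beta0 = fit$beta,
                         control = control)
        V_try <- laml_criterion(fit_try, pinfo_try, spec$family, n)
        # reject steps that walk into numerical separation (saturated logits
        # collapse the IRLS weights and degenerate the Laplace criterion)
        eta_ok <- spec$family != "binomial" || max(abs(fit_try$eta)) < 30
        if (eta_ok && is.finite(V_try) && V_try >= V_cur - 1e-10) {
          lambda <- lam_try; fit <- fit_try; V_cur <- V_try; pinfo <- pinfo_try
          accepted <- TRUE
          break
        }
        step <- step / 2
      }
      if (!accepted || dlog_full * step < control$outer_tol) break
    }
  }

  S_lam <- penalty_total(pens, lambda) %||% matrix(0, ncol(X), ncol(X))
  A <- fit$XtWX
  H <- A + S_lam
  Hinv <- chol_inv(H)
  Fmat <- Hinv %*% A
  edf_col <- diag(Fmat)
  edf_total <- sum(edf_col)
  phi <- if (spec$family == "gaussian") max(fit$deviance, 0) / max(n - edf_total, 1) else 1

  if (spec$family == "binomial") {
    # separation guard: coefficient magnitude on the standardized covariate scale
    sds <- apply(X, 2, stats::sd)
    chk <- sds > 0
    if (isTRUE(control$separation_guard) &&
        any(abs(fit$beta[chk] * sds[chk]) > 15) && max(abs(fit$eta)) > 20) {
      stopf("fit_pgam(): diverging coefficients suggest complete separation")
    }
    if (!fit$converged) warnf("fit_pgam(): inner IRLS did not converge (%d iterations)", fit$iter)
    loglik <- sum(stats::dbinom(y, 1, clamp(fit$mu, 1e-12, 1 - 1e-12), log = TRUE))
    null_mu <- mean(y)
    null_dev <- binomial_dev(y, rep(null_mu, n))
    scale_df <- 0
  } else {
    loglik <- {
      s2 <- max(fit$deviance / n, 1e-300)
      -n / 2 * (log(2 * pi * s2) + 1)
    }
    null_dev <- sum((y - mean(y))^2)
    scale_df <- 1
  }
  resid_dev <- fit$deviance

  term_names <- vapply(des$col_info, `[[`, "", "term")
  edf_term <- vapply(des$col_info, function(ci) sum(edf_col[ci$idx]), 0)
  names(edf_term) <- term_names
  lambda_term <- if (nlam) {
    tapply(lambda, vapply(pens, `[[`, "", "term"), function(z) z, simplify = FALSE)
  } else list()

  Vb <- Hinv * phi
  coefs <- fit$beta
  names(coefs) <- colnames(X)
  dimnames(Vb) <- list(colnames(X), colnames(X))

  or_table <- NULL
  if (spec$family == "binomial" && length(spec$factors)) {
    rows <- list()
    for (ci in des$col_info) {
      if (ci$type != "factor") next
      for (j in ci$idx) {
        b <- coefs[j]; se <- sqrt(Vb[j, j])
        rows[[length(rows) + 1L]] <- data.frame(
          term = ci$term, coef = colnames(X)[j], estimate = b, se = se,
          or = exp(b), or_lo = exp(b - 1.96 * se), or_hi = exp(b + 1.96 * se),
          p_value = 2 * stats::pnorm(-abs(b / se)))
      }
    }
    or_table <- do.call(rbind, rows)
    rownames(or_table) <- NULL
  }

  structure(list(
    spec = spec, coefficients = coefs, Vb = Vb,
    lambda = lambda, lambda_term = lambda_term,
    edf_term = edf_term, edf_total = edf_total, scale_df = scale_df,
    loglik = loglik, aic = -2 * loglik + 2 * (edf_total + scale_df),
    deviance = resid_dev, null_deviance = null_dev, phi = phi,
    fitted = unname(if (spec$family == "binomial") fit$mu else fit$eta),
    linear_predictor = unname(fit$eta), y = y, n = n,
    design = des, pirls_trace = fit$pen_dev_trace,
    inner_converged = fit$converged, outer_iters = outer_iters,
    control = control), class = "pgam")
}

#' @export
print.pgam <- function(x, ...) {
  cat("Penalized additive model (", x$spec$family, ")\n", sep = "")
  cat("  n =", x$n, " terms:",
      paste(names(x$edf_term)[-1], collapse = ", "), "\n")
  cat(sprintf("  logLik %.3f, total EDF %.2f, AIC %.3f\n",
              x$loglik, x$edf_total, x$aic))
  cat(sprintf("  deviance %.3f (null %.3f), adj. R^2 %.4f\n",
              x$deviance, x$null_deviance, adjusted_r2(x)))
  invisible(x)
}

#' @export
logLik.pgam <- function(object, ...) {
  structure(object$loglik, df = object$edf_total + object$scale_df, class = "logLik")
}

#' @export
coef.pgam <- function(object, ...) object$coefficients

#' Akaike information criterion of a penalized fit
#'
#' \code{-2*loglik + 2*EDF} with EDF the trace of the influence matrix
#' (plus one for the Gaussian scale parameter).
#' @param fit a [fit_pgam()] result.
#' @return numeric AIC.
#' @export
aic <- function(fit) {
  stopifnot(inherits(fit, "pgam"))
  fit$aic
}

#' Deviance-based adjusted R-squared
#'
#' \code{1 - (D_res/(n - EDF)) / (D_null/(n - 1))}: the proportion of null
#' deviance explained, adjusted for the effective model dimension.
#' @param fit a [fit_pgam()] result.
#' @return numeric value (1 for a saturated fit, 0 for intercept-only).
#' @export
adjusted_r2 <- function(fit) {
  stopifnot(inherits(fit, "pgam"))
  if (fit$n <= fit$edf_total) stopf("adjusted_r2(): n <= total EDF")
  1 - (fit$deviance / (fit$n - fit$edf_total)) / (fit$null_deviance / (fit$n - 1))
}
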