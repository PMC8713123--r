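#' Confounder specification for the base models
#'
#' The adjustment set of the screening base model: smooths of age, BMI,
#' transepidermal water loss and skin hydration, a tensor-product surface of
#' longitude and latitude, and factors for sex, season, investigator and the
#' collapsed socio-economic class. Individual pieces can be switched off for
#' reduced designs (e.g. an external replication cohort adjusting only for
#' age, sex and season).
#'
#' @param smooths list of [sm()] specifications.
#' @param factors character vector of factor covariates.
#' @return List with elements \code{smooths} and \code{factors}.
#' @export
confounder_spec <- function(smooths = list(sm("age"), sm("bmi"), sm("tewl"), sm("sh"),
                                           sm(c("lon", "lat"), k = c(5L, 5L))),
                            factors = c("sex", "season", "investigator", "esec_group")) {
  list(smooths = smooths, factors = factors)
}

term_labels <- function(spec) {
  c(vapply(spec$smooths, `[[`, "", "label"), spec$factors)
}

spec_drop_term <- function(spec, term) {
  sm_labels <- vapply(spec$smooths, `[[`, "", "label")
  pgam_spec(spec$outcome,
            smooths = spec$smooths[sm_labels != term],
            factors = setdiff(spec$factors, term),
            family = spec$family, refs = spec$refs)
}

spec_formula <- function(spec) {
  paste(spec$outcome, "~",
        paste(c(vapply(spec$smooths, `[[`, "", "label"), spec$factors),
              collapse = " + "))
}

lambda_by_term <- function(fit) {
  if (!length(fit$lambda)) return(NULL)
  ids <- vapply(fit$design$pens, function(p) paste(p$term, p$kind), "")
  stats::setNames(fit$lambda, ids)
}

lambda_warm_start <- function(spec, data_smooths, stored) {
  # stored: named lambda vector from a previous, similar fit
  if (is.null(stored)) return(NULL)
  ids <- unlist(lapply(spec$smooths, function(s) {
    nr <- if (length(s$vars) == 2L) 2L else 1L
    c(rep(paste(s$label, "range"), nr), if (s$double_penalty) paste(s$label, "null"))
  }))
  out <- stored[ids]
  out[is.na(out)] <- 1
  unname(out)
}

#' Screen candidate exposure windows for one variable
#'
#' Fits one model per candidate window: the confounder base model plus a
#' penalized smooth of that window's trailing average, and selects the window
#' whose model has the lowest AIC (ties broken toward the shorter window).
#'
#' @param variable ambient variable name.
#' @param cohort cohort data frame (filtered; includes outcome and
#'   confounders).
#' @param exposure an [build_exposure_matrix()] result covering the variable.
#' @param confounders a [confounder_spec()].
#' @param outcome outcome column name.
#' @param family model family.
#' @param k basis dimension of the exposure smooth.
#' @param windows candidate windows; defaults to those in the exposure
#'   matrix.
#' @param control a [pgam_control()].
#' @return List of class \code{"window_screen"}: \code{table} (window, aic,
#'   edf, converged), \code{selected} window, \code{selected_col} column
#'   label, \code{variable}.
#' @export
screen_windows <- function(variable, cohort, exposure,
                           confounders = confounder_spec(),
                           outcome = "easi10",
                           family = "binomial", k = 10L,
                           windows = attr(exposure, "windows"),
                           control = pgam_control()) {
  stopifnot(inherits(exposure, "exposure_matrix"))
  windows <- sort(as.integer(windows))
  cols <- paste(variable, windows)
  missing_cols <- setdiff(cols, colnames(exposure))
  if (length(missing_cols)) {
    stopf("exposure matrix lacks column(s): %s", paste(missing_cols, collapse = ", "))
  }
  res <- data.frame(window = windows, aic = NA_real_, edf = NA_real_,
                    converged = NA)
  warm <- NULL
  for (i in seq_along(windows)) {
    col <- cols[i]
    df <- cohort
    df[[col]] <- exposure[, col]
    spec <- pgam_spec(outcome,
                      smooths = c(list(sm(col, k = k)), confounders$smooths),
                      factors = confounders$factors, family = family)
    fit <- tryCatch(
      fit_pgam(spec, df, control = control,
               lambda_start = lambda_warm_start(spec, NULL, warm)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      warnf("screen_windows(): window %d failed: %s", windows[i], conditionMessage(fit))
      next
    }
    warm <- lambda_by_term(fit)
    res$aic[i] <- fit$aic
    res$edf[i] <- fit$edf_total
    res$converged[i] <- fit$inner_converged
  }
  if (all(is.na(res$aic))) stopf("screen_windows(): every window failed to fit")
  # unique argmin; ties broken toward the shorter window (rows are sorted)
  sel <- res$window[which.min(res$aic)]
  structure(list(table = res, selected = sel,
                 selected_col = paste(variable, sel), variable = variable),
            class = "window_screen")
}

#' @export
print.window_screen <- function(x, ...) {
  cat(sprintf("Window screen for '%s': selected window %d\n", x$variable, x$selected))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Nesting rule for an AIC-ranked candidate set
#'
#' Removes a candidate model when a strictly nested, simpler candidate is
#' almost as well supported: candidate M is eliminated if some candidate M'
#' with term set strictly contained in M's satisfies
#' \code{AIC(M') <= AIC(M) + tol} (the added complexity fails to improve the
#' AIC by more than \code{tol}). The candidate with the minimum AIC is never
#' eliminated.
#'
#' @param candidates list; each element has \code{terms} (character vector)
#'   and \code{aic}.
#' @param tol nesting tolerance (default 2 AIC units).
#' @return List with \code{keep} (logical vector) and \code{eliminated_by}
#'   (character vector naming the eliminating simpler model's formula terms,
#'   NA where kept).
#' @export
nesting_rule <- function(candidates, tol = 2) {
  n <- length(candidates)
  aics <- vapply(candidates, `[[`, 0, "aic")
  keep <- rep(TRUE, n)
  elim <- rep(NA_character_, n)
  imin <- which.min(aics)
  for (i in seq_len(n)) {
    if (i == imin) next
    ti <- candidates[[i]]$terms
    for (j in seq_len(n)) {
      if (i == j) next
      tj <- candidates[[j]]$terms
      strict_subset <- length(tj) < length(ti) && all(tj %in% ti)
      if (strict_subset && aics[j] <= aics[i] + tol) {
        keep[i] <- FALSE
        elim[i] <- paste(tj, collapse = " + ")
        break
      }
    }
  }
  list(keep = keep, eliminated_by = elim)
}

#' Backward AIC selection with a delta-AIC top set and the nesting rule
#'
#' From the base model, repeatedly fits all single-term deletions of the
#' current model, recording every fitted model in a candidate pool, and steps
#' to the best deletion while it does not worsen the AIC by more than
#' \code{stop_delta}. The top set is then every pool model within
#' \code{delta} AIC of the pool minimum, filtered by the [nesting_rule()].
#'
#' @param spec base [pgam_spec()]; every smooth and factor term is a deletion
#'   candidate (composites are dropped whole).
#' @param data model data frame.
#' @param delta top-set AIC threshold (default 6).
#' @param nesting_tol nesting-rule tolerance (default 2).
#' @param stop_delta stop the backward walk when the best deletion worsens
#'   AIC by more than this (default 6, so the walk explores the top-set
#'   region).
#' @param control a [pgam_control()].
#' @param n_boot bootstrap resamples for C-index intervals in the report.
#' @param boot_seed seed for the C-index bootstrap.
#' @return A \code{"selection_report"}; see [rank_and_report()].
#' @export
backward_select <- function(spec, data, delta = 6, nesting_tol = 2,
                            stop_delta = 6, control = pgam_control(),
                            n_boot = 2000L, boot_seed = 1L) {
  base_fit <- fit_pgam(spec, data, control = control)
  pool <- list()
  add_pool <- function(spec, fit) {
    key <- paste(sort(term_labels(spec)), collapse = "|")
    if (is.null(pool[[key]])) {
      pool[[key]] <<- list(spec = spec, terms = term_labels(spec),
                           aic = fit$aic, loglik = fit$loglik,
                           edf = fit$edf_total, provenance = "backward-step")
    }
    invisible(NULL)
  }
  add_pool(spec, base_fit)
  current_spec <- spec
  current_fit <- base_fit
  repeat {
    terms <- term_labels(current_spec)
    if (!length(terms)) break
    warm <- lambda_by_term(current_fit)
    best <- NULL
    for (tm in terms) {
      sp <- spec_drop_term(current_spec, tm)
      key <- paste(sort(term_labels(sp)), collapse = "|")
      if (!is.null(pool[[key]])) {
        cand <- list(spec = sp, aic = pool[[key]]$aic, fit = NULL)
      } else {
        fit <- tryCatch(
          fit_pgam(sp, data, control = control,
                   lambda_start = lambda_warm_start(sp, NULL, warm)),
          error = function(e) e)
        if (inherits(fit, "error")) {
          warnf("backward_select(): dropping '%s' failed to fit: %s", tm,
                conditionMessage(fit))
          next
        }
        add_pool(sp, fit)
        cand <- list(spec = sp, aic = fit$aic, fit = fit)
      }
      if (is.null(best) || cand$aic < best$aic) best <- cand
    }
    if (is.null(best) || best$aic > current_fit$aic + stop_delta) break
    current_spec <- best$spec
    current_fit <- best$fit %||% fit_pgam(best$spec, data, control = control)
  }
  pool_list <- unname(pool)
  aics <- vapply(pool_list, `[[`, 0, "aic")
  top <- pool_list[aics - min(aics) <= delta]
  nr <- nesting_rule(top, tol = nesting_tol)
  retained <- top[nr$keep]
  eliminations <- data.frame(
    model = vapply(top[!nr$keep], function(m) paste(m$terms, collapse = " + "), ""),
    aic = vapply(top[!nr$keep], `[[`, 0, "aic"),
    eliminated_by = nr$eliminated_by[!nr$keep], stringsAsFactors = FALSE)
  rank_and_report(retained, data, control = control, n_boot = n_boot,
                  boot_seed = boot_seed, pool_min_aic = min(aics),
                  eliminations = eliminations, pool_size = length(pool_list))
}

#' Double-penalty term selection
#'
#' Fits the base model once with the extra null-space penalty enabled on
#' every smooth term, so terms can be shrunk completely out of the model;
#' a smooth counts as selected out when its total effective degrees of
#' freedom fall below \code{threshold}.
#'
#' @param spec base [pgam_spec()].
#' @param data model data frame.
#' @param threshold EDF threshold (default 0.05; 0 never removes).
#' @param control a [pgam_control()].
#' @return List of class \code{"double_penalty"}: \code{fit}, \code{surviving}
#'   and \code{removed} smooth term labels, per-term EDF, threshold.
#' @export
double_penalty_select <- function(spec, data, threshold = 0.05,
                                  control = pgam_control()) {
  sm2 <- lapply(spec$smooths, function(s) {
    s$double_penalty <- TRUE
    s
  })
  spec2 <- pgam_spec(spec$outcome, smooths = sm2, factors = spec$factors,
                     family = spec$family, refs = spec$refs)
  fit <- fit_pgam(spec2, data, control = control)
  labels <- vapply(spec2$smooths, `[[`, "", "label")
  edf <- fit$edf_term[labels]
  removed <- labels[edf < threshold]
  structure(list(fit = fit, surviving = setdiff(labels, removed),
                 removed = removed, edf = edf, threshold = threshold),
            class = "double_penalty")
}

#' @export
print.double_penalty <- function(x, ...) {
  cat("Double-penalty selection (EDF threshold", x$threshold, ")\n")
  cat("  surviving:", paste(x$surviving, collapse = ", "), "\n")
  cat("  removed:  ",
      if (length(x$removed)) paste(x$removed, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Rank retained candidates and build the selection report
#'
#' Refits each retained candidate, computes AIC, delta-AIC, adjusted
#' R-squared and (for binomial models) the C-index with bootstrap interval,
#' orders deterministically by AIC then fewer terms then the formula string,
#' and extracts factor-level odds ratios for the top model.
#'
#' @param candidates list of candidates (each with \code{spec}).
#' @param data model data frame.
#' @param control a [pgam_control()].
#' @param n_boot bootstrap resamples for the C-index interval.
#' @param boot_seed seed for the C-index bootstrap.
#' @param pool_min_aic,eliminations,pool_size bookkeeping from
#'   [backward_select()] (optional).
#' @return Object of class \code{"selection_report"}: \code{table} (one row
#'   per retained model), \code{or_table} (top model), \code{eliminations},
#'   \code{fits}, \code{pool_size}.
#' @export
rank_and_report <- function(candidates, data, control = pgam_control(),
                            n_boot = 2000L, boot_seed = 1L,
                            pool_min_aic = NULL,
                            eliminations = NULL, pool_size = NA_integer_) {
  if (!length(candidates)) stopf("rank_and_report(): no candidates")
  fits <- lapply(candidates, function(cand) fit_pgam(cand$spec, data, control = control))
  aics <- vapply(fits, `[[`, 0, "aic")
  forms <- vapply(candidates, function(cand) spec_formula(cand$spec), "")
  nterms <- vapply(candidates, function(cand) length(term_labels(cand$spec)), 0L)
  ord <- order(aics, nterms, forms)
  fits <- fits[ord]; aics <- aics[ord]; forms <- forms[ord]; nterms <- nterms[ord]
  candidates <- candidates[ord]
  ref_aic <- min(aics, pool_min_aic %||% Inf)
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    ci <- if (f$spec$family == "binomial") {
      c_index(f$fitted, f$y, n_boot = n_boot, seed = boot_seed)
    } else list(value = NA_real_, ci = c(NA_real_, NA_real_))
    data.frame(model = i, formula = forms[i], n_terms = nterms[i],
               aic = f$aic, delta_aic = f$aic - ref_aic,
               r2_adj = adjusted_r2(f),
               c_index = ci$value,
               c_lo = (ci$ci %||% c(NA, NA))[1], c_hi = (ci$ci %||% c(NA, NA))[2],
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  structure(list(table = tab,
                 or_table = fits[[1]]$or_table,
                 eliminations = eliminations,
                 fits = fits, specs = lapply(candidates, `[[`, "spec"),
                 pool_size = pool_size),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, digits = 3, ...) {
  cat("Top model set (", nrow(x$table), " model(s)",
      if (!is.na(x$pool_size)) sprintf(", candidate pool %d", x$pool_size), ")\n",
      sep = "")
  tab <- x$table
  tab$aic <- round(tab$aic, digits); tab$delta_aic <- round(tab$delta_aic, digits)
  tab$r2_adj <- round(tab$r2_adj, digits)
  tab$c_index <- round(tab$c_index, digits)
  print(tab[, c("model", "formula", "aic", "delta_aic", "r2_adj", "c_index")],
        row.names = FALSE)
  if (!is.null(x$eliminations) && nrow(x$eliminations)) {
    cat("Nesting-rule eliminations:\n")
    print(x$eliminations, row.names = FALSE)
  }
  invisible(x)
}

#' Render a selection report as a markdown table
#'
#' @param report a \code{"selection_report"}.
#' @return Character vector of markdown lines.
#' @export
report_markdown <- function(report) {
  stopifnot(inherits(report, "selection_report"))
  tab <- report$table
  lines <- c("| Model | Equation | R2_adj | AIC | dAIC | C-index (95% CI) |",
             "|---|---|---|---|---|---|")
  for (i in seq_len(nrow(tab))) {
    ci_txt <- if (is.na(tab$c_index[i])) "-" else
      sprintf("%.2f (%.2f-%.2f)", tab$c_index[i], tab$c_lo[i], tab$c_hi[i])
    lines <- c(lines, sprintf("| %d | %s | %.3f | %.2f | %.2f | %s |",
                              tab$model[i], tab$formula[i], tab$r2_adj[i],
                              tab$aic[i], tab$delta_aic[i], ci_txt))
  }
  lines
}
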