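#' Trailing-average series over a whole panel
#'
#' For each panel date, the trailing mean of the variable over the
#' \code{window} days ending the previous day (window 0: the day's value);
#' NA where history is incomplete.
#'
#' @param panel an [env_panel()].
#' @param variable panel variable.
#' @param window integer window in days.
#' @return Numeric vector aligned with \code{panel$dates}.
#' @export
mav_series <- function(panel, variable, window) {
  stopifnot(inherits(panel, "env_panel"))
  x <- panel$values[[variable]]
  if (is.null(x)) stopf("unknown panel variable '%s'", variable)
  if (length(panel$dates) > 1L && any(diff(as.integer(panel$dates)) != 1L)) {
    stopf("mav_series(): panel dates must be consecutive calendar days")
  }
  window <- as.integer(window)
  if (window == 0L) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  out <- rep(NA_real_, n)
  idx <- seq_len(n)[seq_len(n) > window]
  out[idx] <- (cs[idx] - cs[idx - window]) / window
  out
}

#' Long-window ozone surrogate-prediction experiment
#'
#' Tests whether long-window averages of nitric oxide, wind, humidity and
#' fine particulate matter jointly account for long-window ozone: a Gaussian
#' additive model of the 270-day ozone trailing average on the four predictor
#' trailing averages is trained on daily rows up to \code{split_date} and
#' used to predict the held-out interval with 95% intervals.
#'
#' @param panel a complete [env_panel()] (365-day run-in required before the
#'   first training row).
#' @param split_date last training day; test rows start the next day.
#' @param predictors named integer vector: window per predictor variable.
#' @param target named integer vector of length 1: target variable and
#'   window.
#' @param k basis dimension per smooth.
#' @param control a [pgam_control()].
#' @param permute_target randomly permute the constructed target column
#'   before fitting (null calibration: the adjusted R-squared of a permuted
#'   target is near zero).
#' @return Object of class \code{"surrogate_experiment"}: the fit, train
#'   interval, test predictions with intervals, train adjusted R-squared
#'   (proportion and percent) and test RMSE.
#' @export
surrogate_experiment <- function(panel, split_date,
                                 predictors = c(no = 365L, wind = 365L,
                                                rh = 180L, pm25 = 120L),
                                 target = c(o3 = 270L),
                                 k = 10L, control = pgam_control(),
                                 permute_target = FALSE) {
  stopifnot(inherits(panel, "env_panel"))
  if (!panel_complete(panel)) stopf("surrogate_experiment(): panel must be complete")
  split_date <- as_date_checked(split_date, "split_date")
  if (split_date <= min(panel$dates) + 365L || split_date >= max(panel$dates)) {
    stopf("split date outside usable panel coverage")
  }
  tv <- names(target)[1]
  cols <- data.frame(row.names = seq_along(panel$dates))
  for (v in names(predictors)) {
    cols[[paste(v, predictors[[v]])]] <- mav_series(panel, v, predictors[[v]])
  }
  ycol <- paste(tv, target[[1]])
  cols[[ycol]] <- mav_series(panel, tv, target[[1]])
  if (isTRUE(permute_target)) {
    ok <- !is.na(cols[[ycol]])
    cols[[ycol]][ok] <- sample(cols[[ycol]][ok])
  }
  usable <- stats::complete.cases(cols)
  dates <- panel$dates
  train_idx <- which(usable & dates <= split_date)
  test_idx <- which(usable & dates > split_date)
  if (!length(train_idx) || !length(test_idx)) stopf("empty train or test interval")
  train <- cols[train_idx, , drop = FALSE]
  spec <- pgam_spec(ycol,
                    smooths = lapply(setdiff(names(cols), ycol), sm, k = k),
                    family = "gaussian")
  fit <- fit_pgam(spec, train, control = control)
  pr <- predict(fit, cols[test_idx, , drop = FALSE], type = "link", se.fit = TRUE)
  test_pred <- data.frame(date = dates[test_idx], predicted = pr$fit,
                          lo = pr$fit - 1.96 * pr$se.fit,
                          hi = pr$fit + 1.96 * pr$se.fit,
                          actual = cols[[ycol]][test_idx])
  r2 <- adjusted_r2(fit)
  structure(list(fit = fit,
                 train_dates = dates[train_idx], test_dates = dates[test_idx],
                 split_date = split_date,
                 train_adj_r2 = r2, train_adj_r2_percent = 100 * r2,
                 test_rmse = sqrt(mean((test_pred$predicted - test_pred$actual)^2)),
                 test_predictions = test_pred,
                 predictors = predictors, target = target),
            class = "surrogate_experiment")
}

#' @export
print.surrogate_experiment <- function(x, ...) {
  cat(sprintf("Surrogate prediction of %s %d from %s\n", names(x$target)[1],
              x$target[[1]],
              paste(names(x$predictors), x$predictors, collapse = ", ")))
  cat(sprintf("  train %s..%s (n=%d), adjusted R^2 %.2f%%\n",
              min(x$train_dates), max(x$train_dates), length(x$train_dates),
              x$train_adj_r2_percent))
  cat(sprintf("  test  %s..%s (n=%d), RMSE %.4g\n",
              min(x$test_dates), max(x$test_dates), length(x$test_dates),
              x$test_rmse))
  invisible(x)
}

#' End-to-end exposure-window selection pipeline
#'
#' The shared code path behind the primary and replication analyses: build
#' the exposure matrix, screen the candidate windows per variable, reduce
#' collinearity among the screened columns with principal-component
#' composites, assemble the top-set base model (one smooth per remaining
#' environmental column plus the confounders), and run both backward
#' delta-AIC selection with the nesting rule and double-penalty selection.
#'
#' @param cohort filtered cohort data frame.
#' @param panel complete [env_panel()].
#' @param variables ambient variables to screen.
#' @param confounders a [confounder_spec()].
#' @param outcome outcome column name.
#' @param windows candidate windows.
#' @param cor_threshold composite-formation correlation threshold.
#' @param delta,nesting_tol,stop_delta backward-selection thresholds.
#' @param dp_threshold double-penalty EDF threshold.
#' @param k exposure smooth basis dimension.
#' @param n_boot bootstrap resamples for C-index intervals.
#' @param boot_seed seed for the C-index bootstrap (all pipeline randomness
#'   flows from here; model fitting itself is deterministic).
#' @param control a [pgam_control()].
#' @param run_backward,run_double_penalty switches for the two selection
#'   routes.
#' @return List of class \code{"pipeline_selection"} with elements
#'   \code{exposure}, \code{screens}, \code{selected_cols}, \code{reduction},
#'   \code{base_spec}, \code{backward} (a \code{"selection_report"} or NULL)
#'   and \code{double_penalty}.
#' @export
full_selection <- function(cohort, panel, variables = env_variables(),
                           confounders = confounder_spec(),
                           outcome = "easi10", windows = default_windows(),
                           cor_threshold = 0.8, delta = 6, nesting_tol = 2,
                           stop_delta = 6, dp_threshold = 0.05, k = 10L,
                           n_boot = 2000L, boot_seed = 1L,
                           control = pgam_control(),
                           run_backward = TRUE, run_double_penalty = TRUE) {
  exposure <- build_exposure_matrix(panel, cohort, variables = variables,
                                    windows = windows)
  screens <- lapply(variables, function(v) {
    screen_windows(v, cohort, exposure, confounders = confounders,
                   outcome = outcome, k = k, windows = windows,
                   control = control)
  })
  names(screens) <- variables
  selected_cols <- vapply(screens, `[[`, "", "selected_col")
  Xenv <- exposure[, selected_cols, drop = FALSE]
  reduction <- reduce_collinearity(Xenv, threshold = cor_threshold)
  env_cols <- colnames(reduction$X)
  data2 <- cohort
  for (cn in env_cols) data2[[cn]] <- reduction$X[, cn]
  base_spec <- pgam_spec(outcome,
                         smooths = c(lapply(env_cols, sm, k = k),
                                     confounders$smooths),
                         factors = confounders$factors, family = "binomial")
  backward <- if (run_backward) {
    backward_select(base_spec, data2, delta = delta, nesting_tol = nesting_tol,
                    stop_delta = stop_delta, control = control, n_boot = n_boot,
                    boot_seed = boot_seed)
  }
  dp <- if (run_double_penalty) {
    double_penalty_select(base_spec, data2, threshold = dp_threshold,
                          control = control)
  }
  structure(list(exposure = exposure, screens = screens,
                 selected_cols = selected_cols, reduction = reduction,
                 base_spec = base_spec, model_data = data2,
                 backward = backward, double_penalty = dp),
            class = "pipeline_selection")
}

#' Replication harness for an external cohort
#'
#' Runs the identical selection machinery ([full_selection()]) with the
#' replication configuration: a reduced pollutant set, an alternative
#' dichotomized severity outcome and age/sex/season adjustment only.
#'
#' @param cohort external cohort data frame (columns: id, recruit_date, age,
#'   sex, season and the outcome).
#' @param panel complete [env_panel()] carrying the available pollutants.
#' @param pollutants variables to screen.
#' @param outcome binary outcome column (default \code{"scorad30"}).
#' @param ... passed to [full_selection()].
#' @return A \code{"pipeline_selection"}.
#' @export
replicate_external <- function(cohort, panel,
                               pollutants = c("pm10", "no2", "o3"),
                               outcome = "scorad30", ...) {
  if (!"season" %in% names(cohort)) {
    cohort$season <- assign_season(as.Date(cohort$recruit_date))
  }
  full_selection(cohort, panel, variables = pollutants,
                 confounders = confounder_spec(smooths = list(sm("age")),
                                               factors = c("sex", "season")),
                 outcome = outcome, ...)
}

#' Sensitivity reruns on truncated cohorts
#'
#' Re-runs double-penalty selection on each truncated cohort defined by a
#' declarative row filter, and summarizes the stability of the surviving
#' environmental term set across reruns.
#'
#' @param cohort filtered cohort data frame.
#' @param panel complete [env_panel()].
#' @param filters named list of predicates: each a function taking the
#'   cohort data frame and returning a logical row mask.
#' @param ... passed to [full_selection()].
#' @return List of class \code{"sensitivity_runs"}: per-filter
#'   \code{"pipeline_selection"} results (backward selection skipped) and a
#'   \code{summary} table of surviving smooth terms.
#' @export
sensitivity_rerun <- function(cohort, panel, filters, ...) {
  stopifnot(is.list(filters), length(filters) > 0)
  if (is.null(names(filters)) || any(names(filters) == "")) {
    names(filters) <- paste0("filter", seq_along(filters))
  }
  runs <- lapply(names(filters), function(nm) {
    mask <- filters[[nm]](cohort)
    sub <- cohort[mask, , drop = FALSE]
    outcome_col <- list(...)$outcome %||% "easi10"
    if (length(unique(sub[[outcome_col]])) < 2L) {
      stopf("filter '%s' leaves a single outcome class", nm)
    }
    full_selection(sub, panel, run_backward = FALSE, ...)
  })
  names(runs) <- names(filters)
  surv <- lapply(runs, function(r) r$double_penalty$surviving)
  all_terms <- unique(unlist(surv))
  summary <- data.frame(term = all_terms)
  for (nm in names(runs)) summary[[nm]] <- all_terms %in% surv[[nm]]
  structure(list(runs = runs, summary = summary), class = "sensitivity_runs")
}
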