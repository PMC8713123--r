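#' Default per-variable simulation settings
#'
#' One row per ambient variable: annual mean level, seasonal amplitude, phase
#' (day of year of the seasonal peak), linear trend per year, lag-1
#' autocorrelation of the stochastic component and its marginal SD. Units are
#' the variable's own (mph, %, deg C, ug/m3). The defaults emulate a
#' multi-year urban roadside record: winter-peaking NOx with a multi-year
#' decline, summer-peaking temperature and ozone, and particulates slowly
#' falling; the rising ozone trend emerges from its structural coupling to
#' falling NO rather than from its own trend term.
#'
#' The \code{loading} column ties each variable's stochastic component to a
#' shared latent daily "dispersion" factor (stagnant air: pollutants up, wind
#' down, humidity up), which produces the strong same-day cross-correlations
#' seen between co-measured urban series; ozone has no loading because its
#' cross-structure comes from the structural coupling instead. The
#' \code{sd_slow} column is the marginal SD of a variable-specific
#' interannual component (a near-unit-root AR process): without it,
#' long-window averages of different variables are phase-shifted annual
#' sinusoids plus trend and collapse into a single composite, which real
#' multi-year records do not do.
#'
#' @return data frame with columns var, mean, amp, phase, trend, ar, sd,
#'   loading, sd_slow.
#' @export
env_var_defaults <- function() {
  data.frame(
    var     = c("wind", "rh", "temp", "no", "no2", "pm10", "pm25", "o3"),
    mean    = c(11,     75,   12,     28,   38,    22,     13,     45),
    amp     = c(1.5,    7,    7.5,    12,   10,    4,      3,      8),
    phase   = c(20,     20,   200,    10,   10,    100,    100,    180),
    trend   = c(0,      0,    0,      -2.5, -2.0,  -0.5,   -0.8,   0),
    ar      = c(0.5,    0.6,  0.7,    0.6,  0.6,   0.5,    0.5,    0.5),
    sd      = c(2.5,    5,    2,      8,    6,     6,      4,      5),
    loading = c(-0.45,  0.3,  -0.2,   0.7,  0.7,   0.6,    0.6,    0),
    sd_slow = c(0.8,    2.5,  0.8,    4,    3,     2.5,    1.8,    2),
    stringsAsFactors = FALSE)
}

#' Environment simulation parameters
#'
#' @param n_days number of days to simulate (>= 400 for any 365-day window
#'   use).
#' @param start_date first calendar day.
#' @param var_config per-variable settings as in [env_var_defaults()].
#' @param o3_coupling named coefficients of the ozone structural equation:
#'   ozone responds to same-day deviations of NO, relative humidity, wind and
#'   PM2.5 from their configured means (negative for NO titration and
#'   humidity, positive for wind-driven mixing, negative for the particulate
#'   radical sink), on top of its own seasonal cycle and noise.
#' @param missing_rate overall fraction of daily values removed per variable
#'   (must be < 0.4, the documented validity bound of the imputer).
#' @param max_gap_days longest contiguous gap injected (gap lengths are
#'   uniform on 2..max_gap_days); 0 or 1 disables gaps.
#' @param gap_share share of the missingness budget spent on contiguous gaps
#'   (the rest is isolated days).
#' @param seed integer seed.
#' @return An object of class \code{"env_sim_params"}.
#' @export
env_sim_params <- function(n_days = 2192L, start_date = as.Date("2014-10-01"),
                           var_config = env_var_defaults(),
                           o3_coupling = c(no = -0.35, rh = -0.25,
                                           wind = 0.8, pm25 = -0.5),
                           missing_rate = 0.05, max_gap_days = 7L,
                           gap_share = 0.4, seed = 1L) {
  n_days <- as.integer(n_days)
  if (n_days < 400L) stopf("env_sim_params(): n_days must be >= 400, got %d", n_days)
  if (missing_rate < 0 || missing_rate >= 0.4) {
    stopf("env_sim_params(): missing_rate must be in [0, 0.4)")
  }
  stopifnot(all(env_variables() %in% var_config$var),
            all(var_config$sd >= 0), all(var_config$ar >= 0 & var_config$ar < 1),
            max_gap_days >= 0, gap_share >= 0, gap_share <= 1)
  structure(list(n_days = n_days, start_date = as.Date(start_date),
                 var_config = var_config, o3_coupling = o3_coupling,
                 missing_rate = missing_rate, max_gap_days = as.integer(max_gap_days),
                 gap_share = gap_share, seed = as.integer(seed)),
            class = "env_sim_params")
}

#' Daily environment panel container
#'
#' @param dates strictly increasing Date vector.
#' @param values data frame (one numeric column per variable) with NA for
#'   missing days.
#' @param provenance optional character matrix ("observed"/"imputed"), same
#'   shape as \code{values}.
#' @return Object of class \code{"env_panel"}: list with \code{dates},
#'   \code{values}, \code{provenance}.
#' @export
env_panel <- function(dates, values, provenance = NULL) {
  dates <- as.Date(dates)
  values <- as.data.frame(values)
  if (anyDuplicated(dates) || is.unsorted(dates, strictly = TRUE)) {
    stopf("env_panel(): dates must be strictly increasing without duplicates")
  }
  if (length(dates) != nrow(values)) stopf("env_panel(): dates/values length mismatch")
  if (is.null(provenance)) {
    provenance <- matrix("observed", nrow(values), ncol(values),
                         dimnames = list(NULL, names(values)))
  }
  structure(list(dates = dates, values = values, provenance = provenance),
            class = "env_panel")
}

#' @export
print.env_panel <- function(x, ...) {
  miss <- vapply(x$values, function(v) mean(is.na(v)), 0)
  cat(sprintf("Daily environment panel: %d days (%s to %s), %d variables\n",
              length(x$dates), min(x$dates), max(x$dates), ncol(x$values)))
  cat("  missing: ", paste(sprintf("%s %.1f%%", names(miss), 100 * miss),
                           collapse = ", "), "\n")
  invisible(x)
}

panel_complete <- function(panel) !anyNA(panel$values)

ar1_series <- function(n, ar, sd) {
  if (sd == 0) return(rep(0, n))
  innov_sd <- sd * sqrt(1 - ar^2)
  as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd), ar,
                           method = "recursive",
                           init = stats::rnorm(1, 0, sd)))
}

seasonal_component <- function(doy, amp, phase) {
  amp * cos(2 * pi * (doy - phase) / 365.25)
}

#' Simulate a daily ambient environment panel
#'
#' Generates the eight daily series as seasonal cycle + linear trend + AR(1)
#' noise, with ozone produced by a structural equation coupling it to
#' same-day NO, humidity, wind and PM2.5 (so long-window averages of those
#' variables predict long-window ozone), then injects missingness (isolated
#' days plus contiguous gaps). The complete truth panel is retained for
#' imputation scoring. Deterministic under a fixed seed. Humidity is clamped
#' to [0, 100] and pollutant/wind values to >= 0 after noise.
#'
#' @param params an [env_sim_params()] object.
#' @return List of class \code{"env_sim"}: \code{panel} (with missing values),
#'   \code{truth_panel} (complete), \code{mask} (logical matrix, TRUE =
#'   removed), \code{params}.
#' @export
simulate_env <- function(params = env_sim_params()) {
  stopifnot(inherits(params, "env_sim_params"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
  set.seed(params$seed)
  n <- params$n_days
  dates <- seq(params$start_date, by = "day", length.out = n)
  doy <- as.integer(format(dates, "%j"))
  tyears <- (seq_len(n) - (n + 1) / 2) / 365.25
  cfg <- params$var_config
  rownames(cfg) <- cfg$var
  if (is.null(cfg$loading)) cfg$loading <- 0
  if (is.null(cfg$sd_slow)) cfg$sd_slow <- 0
  dispersion <- ar1_series(n, 0.6, 1)  # shared stagnant-air factor
  vals <- matrix(NA_real_, n, length(env_variables()),
                 dimnames = list(NULL, env_variables()))
  for (v in setdiff(env_variables(), "o3")) {
    cv <- cfg[v, ]
    lam <- clamp(cv$loading, -0.99, 0.99)
    stoch <- cv$sd * (lam * dispersion +
                        sqrt(1 - lam^2) * ar1_series(n, cv$ar, 1))
    slow <- ar1_series(n, 0.997, cv$sd_slow)  # interannual variability
    vals[, v] <- cv$mean + seasonal_component(doy, cv$amp, cv$phase) +
      cv$trend * tyears + slow + stoch
  }
  co <- params$o3_coupling
  cv <- cfg["o3", ]
  o3 <- cv$mean + seasonal_component(doy, cv$amp, cv$phase) + cv$trend * tyears +
    ar1_series(n, 0.997, cv$sd_slow) +
    co[["no"]] * (vals[, "no"] - cfg["no", "mean"]) +
    co[["rh"]] * (vals[, "rh"] - cfg["rh", "mean"]) +
    co[["wind"]] * (vals[, "wind"] - cfg["wind", "mean"]) +
    co[["pm25"]] * (vals[, "pm25"] - cfg["pm25", "mean"]) +
    ar1_series(n, cv$ar, cv$sd)
  if (any(!is.finite(o3))) stopf("simulate_env(): ozone coupling produced non-finite values")
  vals[, "o3"] <- o3
  # physical bounds
  vals[, "rh"] <- clamp(vals[, "rh"], 0, 100)
  for (v in c("wind", pollutant_variables())) vals[, v] <- pmax(vals[, v], 0)

  truth <- env_panel(dates, as.data.frame(vals))
  mask <- matrix(FALSE, n, ncol(vals), dimnames = list(NULL, colnames(vals)))
  if (params$missing_rate > 0) {
    for (j in seq_len(ncol(vals))) {
      target_gap <- params$gap_share * params$missing_rate * n
      if (params$max_gap_days >= 2L) {
        got <- 0
        while (got < target_gap) {
          len <- sample(2:params$max_gap_days, 1L)
          start <- sample.int(n - len + 1L, 1L)
          mask[start:(start + len - 1L), j] <- TRUE
          got <- got + len
        }
      }
      iso_rate <- (1 - params$gap_share) * params$missing_rate
      mask[, j] <- mask[, j] | (stats::runif(n) < iso_rate)
    }
  }
  vals_na <- vals
  vals_na[mask] <- NA_real_
  structure(list(panel = env_panel(dates, as.data.frame(vals_na)),
                 truth_panel = truth, mask = mask, params = params),
            class = "env_sim")
}

#' Expand a daily panel to hourly records
#'
#' Each day's value plus i.i.d. hourly jitter; exists solely to exercise the
#' hourly ingestion path (the analysis itself consumes 24-hour means).
#'
#' @param panel an [env_panel()].
#' @param jitter_sd hourly noise SD (variable units).
#' @param seed integer seed.
#' @return Data frame with columns timestamp, variable, value, qc.
#' @export
as_hourly <- function(panel, jitter_sd = 0.5, seed = 1L) {
  stopifnot(inherits(panel, "env_panel"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
  set.seed(seed)
  out <- list()
  for (v in names(panel$values)) {
    ok <- !is.na(panel$values[[v]])
    days <- panel$dates[ok]
    vd <- panel$values[[v]][ok]
    ts <- as.POSIXct(rep(days, each = 24L), tz = "UTC") +
      rep(0:23, times = length(days)) * 3600
    out[[v]] <- data.frame(
      timestamp = format(ts, "%Y-%m-%dT%H:%M:%S"),
      variable = v,
      value = rep(vd, each = 24L) + stats::rnorm(24L * length(days), 0, jitter_sd),
      qc = "pass", stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Cohort simulation parameters
#'
#' @param n_participants cohort size.
#' @param recruit_start,recruit_end recruitment interval; every date must
#'   leave 365 days of panel history. Defaults (NULL) place recruitment over
#'   the last 660 days of panel coverage, mirroring a roughly 22-month
#'   recruitment drive.
#' @param true_variable ambient variable driving the outcome.
#' @param true_window its exposure window (one of [default_windows()]).
#' @param effect_fn smooth effect shape on the standardized trailing average:
#'   "linear", "saturating" (tanh) or "bump" (Gaussian bump).
#' @param amplitude effect amplitude on the logit scale (per SD of the
#'   exposure for the linear shape).
#' @param beta0 intercept on the logit scale.
#' @param age_effect logit change per SD of age.
#' @param sex_effect logit offset for males.
#' @param season_effects named logit offsets relative to Spring.
#' @param esec_effects named logit offsets relative to the higher class.
#' @param seed integer seed.
#' @return Object of class \code{"cohort_sim_params"}.
#' @export
cohort_sim_params <- function(n_participants = 600L,
                              recruit_start = NULL, recruit_end = NULL,
                              true_variable = "pm25", true_window = 120L,
                              effect_fn = c("linear", "saturating", "bump"),
                              amplitude = 1.5, beta0 = -1.3,
                              age_effect = 0.3, sex_effect = 0.4,
                              season_effects = c(Summer = 0.2, Autumn = 0.2, Winter = 0.4),
                              esec_effects = c(middle = 0.5, working = 0.2),
                              seed = 1L) {
  effect_fn <- match.arg(effect_fn)
  true_window <- as.integer(true_window)
  if (!true_window %in% default_windows()) {
    stopf("true_window must be one of: %s", paste(default_windows(), collapse = ", "))
  }
  if (!true_variable %in% env_variables()) stopf("unknown true_variable '%s'", true_variable)
  structure(list(n_participants = as.integer(n_participants),
                 recruit_start = recruit_start, recruit_end = recruit_end,
                 true_variable = true_variable, true_window = true_window,
                 effect_fn = effect_fn, amplitude = amplitude, beta0 = beta0,
                 age_effect = age_effect, sex_effect = sex_effect,
                 season_effects = season_effects, esec_effects = esec_effects,
                 seed = as.integer(seed)),
            class = "cohort_sim_params")
}

effect_shape <- function(z, shape, amplitude) {
  switch(shape,
         linear = amplitude * z,
         saturating = amplitude * tanh(z),
         bump = amplitude * exp(-z^2 / 2))
}

#' Simulate a cohort driven by one known exposure window
#'
#' Draws recruitment dates and covariates, computes the true trailing average
#' from the (complete) panel, forms the linear predictor
#' \code{beta0 + effect_fn(standardized exposure) + covariate terms}, draws
#' the binary outcome, and synthesizes a severity score consistent with the
#' label (score > 10 iff outcome is 1). The returned truth record carries the
#' parameters, per-participant linear predictor and realized prevalence.
#'
#' @param panel a complete [env_panel()] (e.g. the \code{truth_panel} of
#'   [simulate_env()]).
#' @param params a [cohort_sim_params()].
#' @return List of class \code{"cohort_sim"}: \code{cohort} (data frame) and
#'   \code{truth}.
#' @export
simulate_cohort <- function(panel, params = cohort_sim_params()) {
  stopifnot(inherits(panel, "env_panel"), inherits(params, "cohort_sim_params"))
  if (!panel_complete(panel)) stopf("simulate_cohort(): panel must be complete (no NA)")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
  set.seed(params$seed)
  n <- params$n_participants
  pstart <- min(panel$dates); pend <- max(panel$dates)
  r0 <- as.Date(params$recruit_start %||% max(pstart + 365L, pend - 660L))
  r1 <- as.Date(params$recruit_end %||% pend)
  if (r0 < pstart + 365L) stopf("recruitment start lacks 365 days of panel history")
  if (r1 > pend) stopf("recruitment end beyond panel coverage")
  dates <- r0 + sample.int(as.integer(r1 - r0) + 1L, n, replace = TRUE) - 1L

  age <- stats::runif(n, 1, 30)
  sex <- ifelse(stats::runif(n) < 0.5, "M", "F")
  bmi <- stats::rlnorm(n, log(18), 0.2)
  esec_group <- sample(c("higher", "middle", "working"), n, replace = TRUE,
                       prob = c(0.30, 0.25, 0.45))
  esec <- vapply(esec_group, function(g) {
    switch(g, higher = sample(1:3, 1L), middle = sample(4:6, 1L),
           working = sample(7:9, 1L))
  }, 0L)
  investigator <- sample(paste0("inv", 1:4), n, replace = TRUE,
                         prob = c(0.5, 0.35, 0.07, 0.08))
  lon <- stats::rnorm(n, 0.0, 0.02)
  lat <- stats::rnorm(n, 51.52, 0.015)
  tewl <- stats::rlnorm(n, log(11), 0.3)
  sh <- stats::rlnorm(n, log(25), 0.3)

  mav <- vapply(seq_len(n), function(i) {
    trailing_mav(panel, params$true_variable, params$true_window, dates[i])
  }, 0)
  z <- as.numeric(scale(mav))
  if (all(!is.finite(z))) z <- rep(0, n)  # degenerate constant exposure
  season <- assign_season(dates)
  lp <- params$beta0 +
    effect_shape(z, params$effect_fn, params$amplitude) +
    params$age_effect * as.numeric(scale(age)) +
    params$sex_effect * (sex == "M") +
    ifelse(season == "Spring", 0, params$season_effects[as.character(season)]) +
    ifelse(esec_group == "higher", 0, params$esec_effects[esec_group])
  lp <- unname(lp)
  y <- stats::rbinom(n, 1L, stats::plogis(lp))
  easi <- ifelse(y == 1L,
                 10 + stats::rgamma(n, shape = 1.5, scale = 6),
                 10 * stats::rbeta(n, 1.2, 2.2))
  cohort <- data.frame(
    id = sprintf("P%04d", seq_len(n)), recruit_date = dates,
    easi = easi, age = age, sex = sex, bmi = bmi, lon = lon, lat = lat,
    tewl = tewl, sh = sh, esec = esec, investigator = investigator,
    easi10 = as.integer(easi > 10), stringsAsFactors = FALSE)
  prevalence <- mean(y)
  if (prevalence <= 0 || prevalence >= 1) {
    warnf("simulate_cohort(): degenerate realized prevalence %.3f", prevalence)
  }
  truth <- list(env_params = NULL, cohort_params = params,
                prevalence = prevalence, linear_predictor = lp,
                true_exposure = mav)
  structure(list(cohort = cohort, truth = truth), class = "cohort_sim")
}

#' Score an imputation against retained truth
#'
#' Root-mean-square error per variable over the masked (removed) entries
#' only.
#'
#' @param truth_panel complete [env_panel()] before masking.
#' @param imputed_panel panel after imputation.
#' @param mask logical matrix, TRUE where values were removed.
#' @return Named numeric vector of per-variable RMSE (NA for variables with
#'   no masked entries); errors if the mask is entirely empty.
#' @export
score_imputation <- function(truth_panel, imputed_panel, mask) {
  stopifnot(inherits(truth_panel, "env_panel"), inherits(imputed_panel, "env_panel"))
  if (!identical(dim(mask), dim(as.matrix(truth_panel$values)))) {
    stopf("score_imputation(): mask shape does not match the panel")
  }
  if (!any(mask)) stopf("score_imputation(): empty mask")
  vars <- names(truth_panel$values)
  out <- stats::setNames(rep(NA_real_, length(vars)), vars)
  for (j in seq_along(vars)) {
    m <- mask[, j]
    if (!any(m)) next
    d <- imputed_panel$values[[vars[j]]][m] - truth_panel$values[[vars[j]]][m]
    out[vars[j]] <- sqrt(mean(d^2))
  }
  out
}
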