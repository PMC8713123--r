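read_hourly_csv <- function(source, allowed_vars, label) {
  df <- utils::read.csv(source, stringsAsFactors = FALSE)
  need <- c("timestamp", "variable", "value", "qc")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("%s: missing column(s): %s", label, paste(miss, collapse = ", "))
  if (nrow(df) == 0L) {
    warnf("%s: empty file", label)
    out <- data.frame(timestamp = as.POSIXct(character(), tz = "UTC"),
                      variable = character(), value = numeric())
    attr(out, "dropped") <- 0L
    class(out) <- c("hourly_records", class(out))
    return(out)
  }
  ts <- tryCatch(
    as.POSIXct(df$timestamp, tz = "UTC",
               tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                              "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M")),
    error = function(e) rep(as.POSIXct(NA), nrow(df)))
  if (anyNA(ts)) {
    stopf("%s: unparseable timestamp(s), first: '%s'",
          label, df$timestamp[which(is.na(ts))[1]])
  }
  bad <- setdiff(unique(df$variable), allowed_vars)
  if (length(bad)) stopf("%s: unknown variable name(s): %s", label, paste(bad, collapse = ", "))
  if ("unit" %in% names(df)) {
    pol <- df$variable %in% pollutant_variables()
    bad_unit <- pol & !df$unit %in% c("ug/m3", "µg/m³")
    if (any(bad_unit)) {
      stopf("%s: pollutant rows with unit other than ug/m3 (first variable: %s)",
            label, df$variable[which(bad_unit)[1]])
    }
  }
  keep <- df$qc == "pass"
  dropped <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  ts <- ts[keep]
  # duplicate timestamps within a variable violate the record contract
  key <- paste(df$variable, format(ts, "%Y-%m-%d %H:%M:%S"))
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stopf("%s: duplicate timestamp for %s", label, d)
  }
  out <- data.frame(timestamp = ts, variable = df$variable,
                    value = as.numeric(df$value), stringsAsFactors = FALSE)
  attr(out, "dropped") <- dropped
  class(out) <- c("hourly_records", class(out))
  out
}

#' Read hourly weather station exports
#'
#' CSV with columns \code{timestamp} (ISO-8601), \code{variable} (one of
#' wind, rh, temp), \code{value} and \code{qc} (pass/fail/absent). Rows whose
#' quality flag is not "pass" are dropped and counted (attribute
#' \code{"dropped"}); duplicate timestamps within a variable are an error.
#'
#' @param source file path or connection.
#' @return A \code{"hourly_records"} data frame (timestamp, variable, value).
#' @export
read_weather_hourly <- function(source) {
  read_hourly_csv(source, weather_variables(), "read_weather_hourly")
}

#' Read hourly air-quality station exports
#'
#' As [read_weather_hourly()] for the pollutant series (no, no2, o3, pm10,
#' pm25, all ug/m3); if a \code{unit} column is present it must read
#' \code{ug/m3} for pollutant rows.
#'
#' @param source file path or connection.
#' @return A \code{"hourly_records"} data frame.
#' @export
read_aq_hourly <- function(source) {
  read_hourly_csv(source, pollutant_variables(), "read_aq_hourly")
}

#' Average hourly records to a daily panel
#'
#' A day's mean uses all available valid hours (no minimum-coverage
#' threshold); a day is missing iff it has zero valid hours. The result
#' carries a per-variable missingness report (percentage missing and longest
#' gap in days) over the covered date range as attribute
#' \code{"missing_report"}.
#'
#' @param records one \code{"hourly_records"} object or a list of them
#'   (e.g. weather + air quality).
#' @param date_range optional length-2 Date vector fixing the panel extent;
#'   defaults to the observed range.
#' @return An [env_panel()] with NA for missing days.
#' @export
daily_average <- function(records, date_range = NULL) {
  if (inherits(records, "hourly_records")) records <- list(records)
  recs <- do.call(rbind, lapply(records, function(r) as.data.frame(r)[c("timestamp", "variable", "value")]))
  if (is.null(recs) || nrow(recs) == 0L) {
    if (is.null(date_range)) stopf("daily_average(): no records and no date_range")
    dates <- seq(as.Date(date_range[1]), as.Date(date_range[2]), by = "day")
    vals <- as.data.frame(matrix(NA_real_, length(dates), 0))
    return(env_panel(dates, vals))
  }
  recs$date <- as.Date(recs$timestamp, tz = "UTC")
  if (is.null(date_range)) date_range <- range(recs$date)
  dates <- seq(as.Date(date_range[1]), as.Date(date_range[2]), by = "day")
  vars <- unique(recs$variable)
  vals <- matrix(NA_real_, length(dates), length(vars),
                 dimnames = list(NULL, vars))
  for (v in vars) {
    rv <- recs[recs$variable == v, ]
    means <- tapply(rv$value, rv$date, mean)
    idx <- match(as.Date(names(means)), dates)
    ok <- !is.na(idx)
    vals[idx[ok], v] <- means[ok]
  }
  panel <- env_panel(dates, as.data.frame(vals))
  report <- lapply(vars, function(v) {
    na <- is.na(vals[, v])
    runs <- rle(na)
    longest <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
    list(percent_missing = 100 * mean(na), longest_gap_days = longest)
  })
  names(report) <- vars
  attr(panel, "missing_report") <- report
  panel
}

#' EM-spline imputation settings
#'
#' @param df_per_year degrees of freedom per year of the natural cubic spline
#'   time trend fitted to each variable (>= 4).
#' @param max_iterations EM iteration cap.
#' @param tol convergence tolerance: maximum relative change of imputed
#'   values between iterations.
#' @param clamp_nonnegative clamp imputed pollutant/wind values at 0 after
#'   convergence (outside the EM loop, preserving its monotonicity).
#' @return A list of settings.
#' @export
em_impute_config <- function(df_per_year = 12, max_iterations = 100L,
                             tol = 1e-4, clamp_nonnegative = TRUE) {
  if (df_per_year < 4) stopf("em_impute_config(): df_per_year must be >= 4")
  if (tol <= 0) stopf("em_impute_config(): tol must be > 0")
  list(df_per_year = df_per_year, max_iterations = as.integer(max_iterations),
       tol = tol, clamp_nonnegative = clamp_nonnegative)
}

# Observed-data log-likelihood of the multivariate normal trend+residual
# model, summing each day's marginal over its observed coordinates.
obs_loglik_mvn <- function(Y, M, Sigma) {
  ll <- 0
  pat <- apply(!is.na(Y), 1, function(z) paste(which(z), collapse = ","))
  for (pp in unique(pat)) {
    idx <- which(pat == pp)
    obs <- which(!is.na(Y[idx[1], ]))
    if (!length(obs)) next
    So <- Sigma[obs, obs, drop = FALSE]
    cholS <- chol(So + diag(1e-10, length(obs)))
    logdet <- 2 * sum(log(diag(cholS)))
    for (i in idx) {
      r <- Y[i, obs] - M[i, obs]
      q <- sum(backsolve(cholS, r, transpose = TRUE)^2)
      ll <- ll - 0.5 * (length(obs) * log(2 * pi) + logdet + q)
    }
  }
  ll
}

#' Impute missing daily values by multivariate EM with spline trends
#'
#' Model: each variable is a smooth time trend (shared natural cubic spline
#' basis, \code{df_per_year} degrees of freedom per year) plus jointly
#' Gaussian same-day residuals across variables. The E-step fills missing
#' entries with their conditional expectations given the observed same-day
#' values and the current covariance; the M-step refits the trends (exact,
#' because all variables share one basis) and the residual covariance
#' (including the conditional-covariance correction). Iterates until the
#' maximum relative change of imputed values drops below \code{tol}.
#'
#' @param panel an [env_panel()] with NA for missing days; a warning is
#'   issued above 40% missingness in any variable (documented validity
#'   bound).
#' @param cfg an [em_impute_config()].
#' @return The completed [env_panel()] with \code{provenance} marking imputed
#'   cells; attributes \code{"iterations"}, \code{"converged"},
#'   \code{"last_delta"} and \code{"loglik_trace"} record the EM run.
#' @export
em_spline_impute <- function(panel, cfg = em_impute_config()) {
  stopifnot(inherits(panel, "env_panel"))
  Y <- as.matrix(panel$values)
  n <- nrow(Y); p <- ncol(Y)
  if (p < 1L) stopf("em_spline_impute(): empty panel")
  miss <- is.na(Y)
  frac <- colMeans(miss)
  if (any(frac > 0.4)) {
    warnf("em_spline_impute(): variable(s) above the 40%% missingness validity bound: %s",
          paste(sprintf("%s (%.0f%%)", colnames(Y)[frac > 0.4], 100 * frac[frac > 0.4]),
                collapse = ", "))
  }
  if (any(frac == 1)) {
    stopf("em_spline_impute(): variable(s) with no observed values: %s",
          paste(colnames(Y)[frac == 1], collapse = ", "))
  }
  prov <- panel$provenance
  prov[miss] <- "imputed"
  if (!any(miss)) {
    out <- env_panel(panel$dates, panel$values, prov)
    attr(out, "iterations") <- 1L
    attr(out, "converged") <- TRUE
    attr(out, "last_delta") <- 0
    return(out)
  }
  years <- n / 365.25
  df <- max(4L, round(cfg$df_per_year * years))
  df <- min(df, n - 1L)
  B <- cbind(1, splines::ns(seq_len(n), df = df))

  # initialize: per-variable linear interpolation then trend fit
  Yc <- Y
  for (j in seq_len(p)) {
    yj <- Y[, j]
    if (anyNA(yj)) {
      yj <- stats::approx(seq_len(n)[!is.na(yj)], yj[!is.na(yj)], xout = seq_len(n),
                          rule = 2)$y
    }
    Yc[, j] <- yj
  }
  Theta <- qr.solve(B, Yc)
  Mu <- B %*% Theta
  R <- Yc - Mu
  Sigma <- crossprod(R) / n
  ll_trace <- numeric(0)
  converged <- FALSE
  delta <- Inf
  iters <- 0L
  pat <- apply(miss, 1, function(z) paste(which(z), collapse = ","))
  for (it in seq_len(cfg$max_iterations)) {
    iters <- it
    prev_imputed <- Yc[miss]
    # E-step: conditional means and covariance corrections per missingness pattern
    Csum <- matrix(0, p, p)
    for (pp in unique(pat)) {
      if (pp == "") next
      rows <- which(pat == pp)
      mis <- as.integer(strsplit(pp, ",", fixed = TRUE)[[1]])
      obs <- setdiff(seq_len(p), mis)
      if (length(obs)) {
        Soo <- Sigma[obs, obs, drop = FALSE] + diag(1e-10, length(obs))
        Smo <- Sigma[mis, obs, drop = FALSE]
        K <- Smo %*% chol_inv(Soo)
        Yc[rows, mis] <- Mu[rows, mis, drop = FALSE] +
          (Y[rows, obs, drop = FALSE] - Mu[rows, obs, drop = FALSE]) %*% t(K)
        Cm <- Sigma[mis, mis, drop = FALSE] - K %*% t(Smo)
      } else {
        Yc[rows, mis] <- Mu[rows, mis, drop = FALSE]
        Cm <- Sigma[mis, mis, drop = FALSE]
      }
      Csum[mis, mis] <- Csum[mis, mis] + length(rows) * Cm
    }
    # M-step: shared-basis trend refit is exact; covariance with E-step correction
    Theta <- qr.solve(B, Yc)
    Mu <- B %*% Theta
    R <- Yc - Mu
    Sigma <- (crossprod(R) + Csum) / n
    ll_trace <- c(ll_trace, obs_loglik_mvn(Y, Mu, Sigma))
    delta <- max(abs(Yc[miss] - prev_imputed) / pmax(abs(prev_imputed), 1))
    if (delta < cfg$tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warnf("em_spline_impute(): not converged after %d iterations (last delta %.3g)",
          iters, delta)
  }
  if (cfg$clamp_nonnegative) {
    for (v in intersect(colnames(Y), c("wind", pollutant_variables()))) {
      Yc[miss[, v], v] <- pmax(Yc[miss[, v], v], 0)
    }
    if ("rh" %in% colnames(Y)) Yc[miss[, "rh"], "rh"] <- clamp(Yc[miss[, "rh"], "rh"], 0, 100)
  }
  out <- env_panel(panel$dates, as.data.frame(Yc), prov)
  attr(out, "iterations") <- iters
  attr(out, "converged") <- converged
  attr(out, "last_delta") <- delta
  attr(out, "loglik_trace") <- ll_trace
  out
}

#' Per-variable linear interpolation imputation
#'
#' Baseline comparator for [em_spline_impute()]: straight-line interpolation
#' in time within each variable, with boundary values carried outward.
#'
#' @param panel an [env_panel()] with NA for missing days.
#' @return The completed [env_panel()].
#' @export
linear_impute <- function(panel) {
  stopifnot(inherits(panel, "env_panel"))
  Y <- as.matrix(panel$values)
  n <- nrow(Y)
  prov <- panel$provenance
  prov[is.na(Y)] <- "imputed"
  for (j in seq_len(ncol(Y))) {
    yj <- Y[, j]
    if (anyNA(yj) && any(!is.na(yj))) {
      Y[, j] <- stats::approx(seq_len(n)[!is.na(yj)], yj[!is.na(yj)],
                              xout = seq_len(n), rule = 2)$y
    }
  }
  env_panel(panel$dates, as.data.frame(Y), prov)
}
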