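#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonical ambient variable names
#'
#' The eight daily ambient series the pipeline understands: wind speed (mph),
#' relative humidity (%), temperature (deg C) and the pollutants NO, NO2, O3,
#' PM10, PM2.5 (all ug/m3).
#' @return Character vector of variable names.
#' @export
env_variables <- function() {
  c("wind", "rh", "temp", "no", "no2", "o3", "pm10", "pm25")
}

weather_variables <- function() c("wind", "rh", "temp")
pollutant_variables <- function() c("no", "no2", "o3", "pm10", "pm25")

#' Candidate trailing-average windows
#'
#' The ten candidate exposure windows: the recruitment day itself (coded 0)
#' and trailing means over 7, 15, 30, 60, 90, 120, 180, 270 and 365 days.
#' @return Sorted integer vector.
#' @export
default_windows <- function() {
  c(0L, 7L, 15L, 30L, 60L, 90L, 120L, 180L, 270L, 365L)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_date_scalar <- function(x) inherits(x, "Date") && length(x) == 1L && !is.na(x)

as_date_checked <- function(x, what = "date") {
  out <- tryCatch(as.Date(x), error = function(e) NA)
  if (anyNA(out)) stopf("could not parse %s: %s", what, paste(utils::head(x, 3), collapse = ", "))
  out
}

# Cholesky solve with escalating ridge jitter for near-singular systems.
chol_solve <- function(H, b) {
  p <- ncol(H)
  jit <- 0
  base <- mean(abs(diag(H))) + 1e-300
  for (i in 0:8) {
    R <- tryCatch(chol(H + diag(jit, p)), error = function(e) NULL)
    if (!is.null(R)) {
      return(list(x = backsolve(R, forwardsolve(t(R), b)), R = R, jitter = jit))
    }
    jit <- if (jit == 0) base * 1e-10 else jit * 100
  }
  stopf("linear system is singular beyond repair (jitter %g)", jit)
}

chol_inv <- function(H) {
  p <- ncol(H)
  jit <- 0
  base <- mean(abs(diag(H))) + 1e-300
  for (i in 0:8) {
    R <- tryCatch(chol(H + diag(jit, p)), error = function(e) NULL)
    if (!is.null(R)) return(chol2inv(R))
    jit <- if (jit == 0) base * 1e-10 else jit * 100
  }
  stopf("matrix not invertible")
}
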