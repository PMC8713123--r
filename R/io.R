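#' Export a fit summary as JSON
#'
#' Coefficients, per-term smoothing parameters and EDF, log-likelihood, AIC,
#' deviances, adjusted R-squared and (binomial family) the factor odds-ratio
#' table.
#'
#' @param fit a [fit_pgam()] result.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "pgam"))
  out <- list(
    family = fit$spec$family,
    n = fit$n,
    coefficients = as.list(fit$coefficients),
    lambda = lapply(fit$lambda_term, as.numeric),
    edf = as.list(fit$edf_term),
    edf_total = fit$edf_total,
    loglik = fit$loglik,
    aic = fit$aic,
    deviance = fit$deviance,
    null_deviance = fit$null_deviance,
    adjusted_r2 = adjusted_r2(fit),
    odds_ratios = fit$or_table)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "rows")
  invisible(path)
}

#' Export partial effects as tidy CSV
#'
#' One row per (term, grid point): term, x, effect, lo, hi.
#'
#' @param fit a [fit_pgam()] result.
#' @param path output file.
#' @param terms smooth terms to include (default: all univariate smooths).
#' @param n_grid grid size per term.
#' @return \code{path}, invisibly.
#' @export
write_partial_effects_csv <- function(fit, path, terms = NULL, n_grid = 100L) {
  stopifnot(inherits(fit, "pgam"))
  if (is.null(terms)) {
    terms <- names(Filter(function(b) length(b$spec$vars) == 1L,
                          fit$design$bases))
  }
  rows <- lapply(terms, function(tm) {
    pe <- partial_effect(fit, tm, n_grid = n_grid)
    data.frame(term = tm, x = pe$x, effect = pe$effect, lo = pe$lo, hi = pe$hi)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write / read an exposure matrix as CSV
#'
#' Column headers use the \code{"<var> <window>"} convention; the first
#' column is the participant id.
#'
#' @param exposure a [build_exposure_matrix()] result.
#' @param path file path.
#' @return \code{path} (writer) or the matrix (reader).
#' @export
write_exposure_csv <- function(exposure, path) {
  df <- data.frame(id = rownames(exposure), check.names = FALSE)
  df <- cbind(df, as.data.frame(unclass(exposure), check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_exposure_csv
#' @export
read_exposure_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  M <- as.matrix(df[setdiff(names(df), "id")])
  rownames(M) <- df$id
  class(M) <- c("exposure_matrix", class(M))
  M
}
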