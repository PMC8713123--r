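#' Trailing moving average of a daily series
#'
#' For a window of N > 0 days: the arithmetic mean of the variable over the N
#' calendar days ending the day \emph{before} the reference date (so the
#' reference day itself is excluded). Window 0 ("day-of") returns the value
#' on the reference day.
#'
#' @param panel a complete [env_panel()] over the required history.
#' @param variable panel variable name.
#' @param window integer window length in days (0 for day-of).
#' @param date reference (recruitment) date.
#' @return numeric value.
#' @export
trailing_mav <- function(panel, variable, window, date) {
  stopifnot(inherits(panel, "env_panel"))
  if (!variable %in% names(panel$values)) stopf("unknown panel variable '%s'", variable)
  date <- as_date_checked(date)
  window <- as.integer(window)
  if (window < 0L) stopf("window must be >= 0")
  if (window == 0L) {
    i <- match(date, panel$dates)
    if (is.na(i)) stopf("panel does not cover %s", format(date))
    v <- panel$values[[variable]][i]
    if (is.na(v)) stopf("panel value missing on %s for '%s'", format(date), variable)
    return(v)
  }
  days <- seq(date - window, date - 1L, by = "day")
  idx <- match(days, panel$dates)
  if (anyNA(idx)) {
    stopf("insufficient panel history for window %d ending %s (need %s onward)",
          window, format(date - 1L), format(date - window))
  }
  v <- panel$values[[variable]][idx]
  if (anyNA(v)) stopf("panel has missing values inside window %d before %s", window, format(date))
  mean(v)
}

#' Exposure matrix of recruitment-matched trailing averages
#'
#' One row per participant, one column per (variable, window) pair, labelled
#' \code{"<var> <window>"} (window 0 is the recruitment-day value).
#'
#' @param panel a complete [env_panel()].
#' @param cohort data frame with columns \code{id} and \code{recruit_date}.
#' @param variables panel variables to use (default: all).
#' @param windows integer windows (default [default_windows()]).
#' @return Numeric matrix of class \code{"exposure_matrix"} with participant
#'   ids as row names.
#' @export
build_exposure_matrix <- function(panel, cohort,
                                  variables = names(panel$values),
                                  windows = default_windows()) {
  stopifnot(inherits(panel, "env_panel"))
  if (!all(c("id", "recruit_date") %in% names(cohort))) {
    stopf("cohort must have 'id' and 'recruit_date' columns")
  }
  dates <- as.Date(cohort$recruit_date)
  ridx <- match(dates, panel$dates)
  if (anyNA(ridx)) {
    stopf("participant(s) %s: recruitment date outside panel coverage",
          paste(utils::head(cohort$id[is.na(ridx)], 3), collapse = ", "))
  }
  if (!panel_complete(panel)) stopf("build_exposure_matrix(): panel must be complete")
  cols <- as.vector(outer(windows, variables, function(w, v) paste(v, w)))
  out <- matrix(NA_real_, nrow(cohort), length(cols), dimnames = list(NULL, cols))
  for (v in variables) {
    for (w in windows) {
      # trailing mean over the w days ending the day before recruitment
      # (w = 0: the recruitment-day value); see trailing_mav() for the
      # scalar reference implementation of the same convention
      s <- mav_series(panel, v, w)
      val <- s[ridx]
      if (anyNA(val)) {
        bad <- cohort$id[is.na(val)]
        stopf("participant(s) %s: insufficient panel history for window %d",
              paste(utils::head(bad, 3), collapse = ", "), w)
      }
      out[, paste(v, w)] <- val
    }
  }
  rownames(out) <- as.character(cohort$id)
  class(out) <- c("exposure_matrix", class(out))
  attr(out, "variables") <- variables
  attr(out, "windows") <- windows
  out
}

#' Season from calendar date
#'
#' Fixed solstice/equinox calendar cut-offs: Mar 20, Jun 21, Sep 22, Dec 21;
#' the boundary day starts the new season.
#'
#' @param date Date vector.
#' @return factor with levels Spring, Summer, Autumn, Winter.
#' @export
assign_season <- function(date) {
  date <- as_date_checked(date)
  md <- as.integer(format(date, "%m")) * 100L + as.integer(format(date, "%d"))
  s <- ifelse(md >= 320 & md < 621, "Spring",
              ifelse(md >= 621 & md < 922, "Summer",
                     ifelse(md >= 922 & md < 1221, "Autumn", "Winter")))
  factor(s, levels = c("Spring", "Summer", "Autumn", "Winter"))
}

#' Collapse a 9-class socio-economic classification to three groups
#'
#' Classes 1-3 map to "higher", 4-6 to "middle", 7-9 to "working".
#'
#' @param class integer vector in 1..9.
#' @return factor with levels higher, middle, working.
#' @export
collapse_esec <- function(class) {
  class <- as.integer(class)
  if (anyNA(class) || any(class < 1L | class > 9L)) {
    stopf("collapse_esec(): classes must be integers in 1..9")
  }
  out <- cut(class, breaks = c(0, 3, 6, 9), labels = c("higher", "middle", "working"))
  factor(as.character(out), levels = c("higher", "middle", "working"))
}

#' Filter a raw cohort table
#'
#' Removes rows that live outside the study bounding box or that are missing
#' sex, skin-barrier measurements (TEWL/skin hydration), socio-economic
#' class, or BMI (height/weight), tallying removals per reason (each row is
#' counted under the first matching reason, in that order). Also derives or
#' checks the dichotomized outcome \code{easi10 = easi > 10}.
#'
#' @param raw data frame with the cohort columns (id, recruit_date, easi,
#'   age, sex, bmi, lon, lat, tewl, sh, esec, investigator).
#' @param bbox study area as c(lon_min, lon_max, lat_min, lat_max).
#' @return List with \code{cohort} (filtered data frame, with \code{easi10}
#'   and \code{esec_group}) and \code{tally} (named removal counts).
#' @export
filter_cohort <- function(raw, bbox = c(-0.10, 0.10, 51.45, 51.60)) {
  raw <- as.data.frame(raw)
  reasons <- rep(NA_character_, nrow(raw))
  mark <- function(cond, label) {
    cond[is.na(cond)] <- FALSE
    reasons[is.na(reasons) & cond] <<- label
  }
  mark(is.na(raw$lon) | is.na(raw$lat) |
         raw$lon < bbox[1] | raw$lon > bbox[2] |
         raw$lat < bbox[3] | raw$lat > bbox[4], "out_of_area")
  mark(is.na(raw$sex) | raw$sex == "", "sex")
  mark(is.na(raw$tewl) | is.na(raw$sh), "tewl_sh")
  mark(is.na(raw$esec), "esec")
  mark(is.na(raw$bmi), "bmi")
  keep <- is.na(reasons)
  tally <- table(reasons[!keep])
  cohort <- raw[keep, , drop = FALSE]
  cohort$easi10 <- as.integer(cohort$easi > 10)
  cohort$esec_group <- collapse_esec(cohort$esec)
  cohort$season <- assign_season(as.Date(cohort$recruit_date))
  rownames(cohort) <- NULL
  list(cohort = cohort,
       tally = stats::setNames(as.integer(tally), names(tally)))
}

#' Reduce collinear columns to principal-component composites
#'
#' Iteratively finds the pair of columns with the largest absolute Pearson
#' correlation; while it exceeds the threshold, standardizes the two columns,
#' replaces them with dimension 1 of their principal component decomposition
#' (correlation scale; loadings unit-norm, sign fixed so the first-named
#' member loads positively), labels the composite \code{"A/B Dim 1"}, and
#' repeats including the new composite. Terminates because each merge
#' removes one column.
#'
#' @param X numeric matrix of candidate columns (no missing values), with
#'   column names.
#' @param threshold absolute correlation above which a pair is merged.
#' @return List with \code{X} (reduced matrix), \code{composites} (list of
#'   definitions: members, loadings, member means/sds) and \code{max_abs_r}
#'   (final maximum absolute pairwise correlation).
#' @export
reduce_collinearity <- function(X, threshold = 0.8) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) stopf("reduce_collinearity(): need at least 2 columns")
  if (anyNA(X)) stopf("reduce_collinearity(): missing values not allowed")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stopf("reduce_collinearity(): constant column(s): %s",
          paste(colnames(X)[sds == 0], collapse = ", "))
  }
  composites <- list()
  repeat {
    if (ncol(X) < 2L) break
    C <- stats::cor(X)
    diag(C) <- 0
    mx <- which(abs(C) == max(abs(C)), arr.ind = TRUE)[1, ]
    if (abs(C[mx[1], mx[2]]) <= threshold) break
    i <- min(mx); j <- max(mx)
    a <- colnames(X)[i]; b <- colnames(X)[j]
    za <- (X[, i] - mean(X[, i])) / stats::sd(X[, i])
    zb <- (X[, j] - mean(X[, j])) / stats::sd(X[, j])
    e <- eigen(stats::cor(cbind(za, zb)), symmetric = TRUE)
    load <- e$vectors[, 1]
    if (load[1] < 0) load <- -load  # first-named member loads positively
    score <- za * load[1] + zb * load[2]
    label <- paste0(a, "/", b, " Dim 1")
    composites[[label]] <- list(
      members = c(a, b), loadings = stats::setNames(load, c(a, b)),
      member_means = c(mean(X[, i]), mean(X[, j])),
      member_sds = c(stats::sd(X[, i]), stats::sd(X[, j])),
      var_explained = e$values[1] / sum(e$values))
    X <- cbind(X[, -c(i, j), drop = FALSE], score)
    colnames(X)[ncol(X)] <- label
  }
  max_r <- if (ncol(X) >= 2L) {
    C <- stats::cor(X); diag(C) <- 0; max(abs(C))
  } else 0
  list(X = X, composites = composites, max_abs_r = max_r)
}

#' Apply stored composite definitions to new data
#'
#' Recomputes composite scores on new columns using the loadings and member
#' standardization saved by [reduce_collinearity()].
#'
#' @param X numeric matrix containing the original member columns.
#' @param composites the \code{composites} element of a
#'   [reduce_collinearity()] result.
#' @return The matrix with member columns replaced by composite scores.
#' @export
apply_composites <- function(X, composites) {
  X <- as.matrix(X)
  for (label in names(composites)) {
    cp <- composites[[label]]
    za <- (X[, cp$members[1]] - cp$member_means[1]) / cp$member_sds[1]
    zb <- (X[, cp$members[2]] - cp$member_means[2]) / cp$member_sds[2]
    score <- za * cp$loadings[1] + zb * cp$loadings[2]
    keep <- setdiff(colnames(X), cp$members)
    X <- cbind(X[, keep, drop = FALSE], score)
    colnames(X)[ncol(X)] <- label
  }
  X
}
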