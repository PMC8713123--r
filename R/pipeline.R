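#' Write / read a daily panel as CSV
#'
#' Plain CSV with a \code{date} column followed by one numeric column per
#' variable; missing days are empty cells.
#'
#' @param panel an [env_panel()].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_panel_csv <- function(panel, path) {
  stopifnot(inherits(panel, "env_panel"))
  df <- cbind(data.frame(date = format(panel$dates)), panel$values)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_panel_csv
#' @export
read_panel_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"date" %in% names(df)) stopf("panel CSV lacks 'date' column")
  env_panel(as_date_checked(df$date, "panel dates"),
            df[setdiff(names(df), "date")])
}

#' Write / read a cohort table as CSV
#'
#' @param cohort cohort data frame.
#' @param path file path.
#' @return \code{path} (writer) or the data frame (reader).
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("id", "recruit_date", "easi")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stopf("cohort CSV %s: missing column(s): %s (first data row %d)",
          path, paste(miss, collapse = ", "), 1L)
  }
  df$recruit_date <- as_date_checked(df$recruit_date, "recruit_date")
  bad <- which(!is.finite(df$easi))
  if (length(bad)) stopf("cohort CSV %s: non-numeric easi at row %d", path, bad[1])
  df
}

#' Pipeline run configuration
#'
#' Collects every tunable constant of the pipeline in one validated object;
#' [run_pipeline()] writes the resolved configuration beside its outputs.
#'
#' @param weather_csv,aq_csv hourly input CSV paths (optional if
#'   \code{panel_csv} given).
#' @param panel_csv daily panel CSV path (alternative to hourly inputs).
#' @param cohort_csv cohort CSV path.
#' @param out_dir run directory.
#' @param variables ambient variables to screen.
#' @param windows candidate windows (sorted ascending).
#' @param cor_threshold composite threshold (0.8).
#' @param delta top-set AIC threshold (6).
#' @param nesting_tol nesting tolerance (2).
#' @param dp_threshold double-penalty EDF threshold (0.05).
#' @param n_boot C-index bootstrap resamples (2000).
#' @param k exposure smooth basis size.
#' @param outcome outcome column.
#' @param family model family.
#' @param seed integer seed for any stochastic step (bootstrap).
#' @return Object of class \code{"run_config"}.
#' @export
run_config <- function(weather_csv = NULL, aq_csv = NULL, panel_csv = NULL,
                       cohort_csv = NULL, out_dir = tempfile("expowin-run-"),
                       variables = env_variables(), windows = default_windows(),
                       cor_threshold = 0.8, delta = 6, nesting_tol = 2,
                       dp_threshold = 0.05, n_boot = 2000L, k = 10L,
                       outcome = "easi10", family = "binomial", seed = 1L) {
  if (is.null(panel_csv) && (is.null(weather_csv) || is.null(aq_csv))) {
    stopf("run_config(): give panel_csv, or both weather_csv and aq_csv")
  }
  if (is.null(cohort_csv)) stopf("run_config(): cohort_csv is required")
  stopifnot(cor_threshold > 0, delta > 0, nesting_tol > 0, dp_threshold >= 0)
  windows <- sort(as.integer(windows))
  structure(list(weather_csv = weather_csv, aq_csv = aq_csv,
                 panel_csv = panel_csv, cohort_csv = cohort_csv,
                 out_dir = out_dir, variables = variables, windows = windows,
                 cor_threshold = cor_threshold, delta = delta,
                 nesting_tol = nesting_tol, dp_threshold = dp_threshold,
                 n_boot = as.integer(n_boot), k = as.integer(k),
                 outcome = outcome, family = family, seed = as.integer(seed)),
            class = "run_config")
}

# content hash of an arbitrary R object (serialize + md5 of the bytes)
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

stage_cached <- function(cache_dir, stage, input_hash, compute, log) {
  key <- file.path(cache_dir, paste0(stage, "-", input_hash, ".rds"))
  if (file.exists(key)) {
    log(stage, "cache-hit", input_hash)
    return(list(value = readRDS(key), cached = TRUE))
  }
  t0 <- proc.time()[["elapsed"]]
  value <- tryCatch(compute(), error = function(e) {
    stopf("stage '%s' failed (input hash %s): %s", stage, input_hash,
          conditionMessage(e))
  })
  saveRDS(value, key, version = 2)
  log(stage, sprintf("computed in %.1fs", proc.time()[["elapsed"]] - t0), input_hash)
  list(value = value, cached = FALSE)
}

#' Run the full pipeline from configuration
#'
#' Executes ingest, imputation, exposure construction, window screening,
#' collinearity reduction, model selection and reporting in order. Each
#' stage's artifact is cached in the run directory under a content hash of
#' its inputs, so re-running with identical configuration and inputs is a
#' no-op. Writes \code{config.json}, \code{report.json},
#' \code{report.md} and \code{log.jsonl} to the run directory.
#'
#' @param config a [run_config()].
#' @return List of class \code{"pipeline_run"}: \code{selection} (a
#'   \code{"pipeline_selection"}), \code{panel}, \code{cohort},
#'   \code{exclusions}, \code{out_dir}, \code{cache_hits}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cache_dir <- file.path(config$out_dir, "cache")
  dir.create(cache_dir, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "log.jsonl")
  log <- function(stage, msg, hash = "") {
    cat(jsonlite::toJSON(list(time = format(Sys.time()), stage = stage,
                              message = msg, input_hash = hash),
                         auto_unbox = TRUE), "\n",
        file = log_path, append = TRUE)
  }
  cfg_json <- file.path(config$out_dir, "config.json")
  jsonlite::write_json(unclass(config), cfg_json, auto_unbox = TRUE,
                       null = "null", digits = NA)
  cache_hits <- character(0)
  note_cache <- function(stage, res) {
    if (res$cached) cache_hits <<- c(cache_hits, stage)
    res$value
  }

  file_hash <- function(path) if (is.null(path)) "" else unname(tools::md5sum(path))

  # ingest + impute -> complete panel
  if (!is.null(config$panel_csv)) {
    h <- object_hash(list("panel", file_hash(config$panel_csv)))
    raw_panel <- note_cache("ingest", stage_cached(cache_dir, "ingest", h, function() {
      read_panel_csv(config$panel_csv)
    }, log))
  } else {
    h <- object_hash(list("hourly", file_hash(config$weather_csv),
                          file_hash(config$aq_csv)))
    raw_panel <- note_cache("ingest", stage_cached(cache_dir, "ingest", h, function() {
      wx <- read_weather_hourly(config$weather_csv)
      aq <- read_aq_hourly(config$aq_csv)
      daily_average(list(wx, aq))
    }, log))
  }
  h_imp <- object_hash(list("impute", object_hash(raw_panel)))
  panel <- note_cache("impute", stage_cached(cache_dir, "impute", h_imp, function() {
    em_spline_impute(raw_panel)
  }, log))

  # cohort
  h_coh <- object_hash(list("cohort", file_hash(config$cohort_csv)))
  filt <- note_cache("cohort", stage_cached(cache_dir, "cohort", h_coh, function() {
    filter_cohort(read_cohort_csv(config$cohort_csv))
  }, log))

  # exposure + screening + reduction + selection (one cached unit per stage)
  h_sel <- object_hash(list("select", object_hash(panel), object_hash(filt$cohort),
                            config[c("variables", "windows", "cor_threshold",
                                     "delta", "nesting_tol", "dp_threshold",
                                     "n_boot", "k", "outcome", "seed")]))
  selection <- note_cache("select", stage_cached(cache_dir, "select", h_sel, function() {
    full_selection(filt$cohort, panel, variables = config$variables,
                   outcome = config$outcome, windows = config$windows,
                   cor_threshold = config$cor_threshold, delta = config$delta,
                   nesting_tol = config$nesting_tol,
                   dp_threshold = config$dp_threshold, k = config$k,
                   n_boot = config$n_boot, boot_seed = config$seed)
  }, log))

  report <- list(
    n_cohort = nrow(filt$cohort),
    exclusions = as.list(filt$tally),
    screened_windows = lapply(selection$screens, function(s) s$selected),
    composites = lapply(selection$reduction$composites, function(cp) {
      list(members = cp$members, loadings = as.list(cp$loadings))
    }),
    top_set = selection$backward$table,
    or_table = selection$backward$or_table,
    double_penalty = list(surviving = selection$double_penalty$surviving,
                          removed = selection$double_penalty$removed))
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  writeLines(report_markdown(selection$backward),
             file.path(config$out_dir, "report.md"))
  log("report", "written")
  structure(list(selection = selection, panel = panel, cohort = filt$cohort,
                 exclusions = filt$tally, out_dir = config$out_dir,
                 cache_hits = cache_hits),
            class = "pipeline_run")
}

#' Generate bundled fixture data sets
#'
#' Writes a panel CSV, cohort CSV and ground-truth JSON for one of the named
#' presets: \code{"null"} (no effects at all), \code{"single-window"} (one
#' variable/window drives the outcome; the default stated world),
#' \code{"collinear"} (outcome driven by long-window ozone, exercising the
#' composite machinery) and \code{"korean-like"} (three pollutants only,
#' severity dichotomized at 30, age/sex/season covariates).
#'
#' @param preset preset name.
#' @param seed integer seed.
#' @param dir output directory.
#' @param n_participants cohort size.
#' @param n_days panel length.
#' @return Invisible list with the simulated objects and file paths.
#' @export
make_fixtures <- function(preset = c("null", "single-window", "collinear",
                                     "korean-like"),
                          seed = 1L, dir = tempfile("expowin-fixture-"),
                          n_participants = 600L, n_days = 2192L) {
  preset <- match.arg(preset)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ep <- env_sim_params(n_days = n_days, seed = seed)
  sim <- simulate_env(ep)
  cp <- switch(preset,
    "null" = cohort_sim_params(n_participants = n_participants, amplitude = 0,
                               beta0 = 0, age_effect = 0, sex_effect = 0,
                               season_effects = c(Summer = 0, Autumn = 0, Winter = 0),
                               esec_effects = c(middle = 0, working = 0),
                               seed = seed + 1L),
    "single-window" = cohort_sim_params(n_participants = n_participants,
                                        seed = seed + 1L),
    "collinear" = cohort_sim_params(n_participants = n_participants,
                                    true_variable = "o3", true_window = 270L,
                                    seed = seed + 1L),
    "korean-like" = cohort_sim_params(n_participants = n_participants,
                                      true_variable = "o3", true_window = 270L,
                                      seed = seed + 1L))
  csim <- simulate_cohort(sim$truth_panel, cp)
  cohort <- csim$cohort
  panel <- sim$panel
  if (preset == "korean-like") {
    keep <- c("pm10", "no2", "o3")
    panel <- env_panel(panel$dates, panel$values[keep])
    cohort$scorad <- ifelse(cohort$easi10 == 1L,
                            30 + (cohort$easi - 10) * 1.5,
                            cohort$easi * 2.9)
    cohort$scorad30 <- as.integer(cohort$scorad > 30)
    cohort <- cohort[c("id", "recruit_date", "age", "sex", "scorad",
                       "scorad30", "easi")]
  }
  panel_path <- file.path(dir, "panel.csv")
  cohort_path <- file.path(dir, "cohort.csv")
  truth_path <- file.path(dir, "truth.json")
  write_panel_csv(panel, panel_path)
  write_cohort_csv(cohort, cohort_path)
  truth <- list(preset = preset, seed = seed,
                env_params = list(n_days = ep$n_days,
                                  start_date = format(ep$start_date),
                                  missing_rate = ep$missing_rate,
                                  o3_coupling = as.list(ep$o3_coupling)),
                cohort_params = list(
                  n_participants = cp$n_participants,
                  true_variable = cp$true_variable,
                  true_window = cp$true_window, effect_fn = cp$effect_fn,
                  amplitude = cp$amplitude, beta0 = cp$beta0),
                prevalence = csim$truth$prevalence)
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  invisible(list(dir = dir, panel = panel, cohort = cohort,
                 truth = csim$truth, env_sim = sim,
                 paths = c(panel = panel_path, cohort = cohort_path,
                           truth = truth_path)))
}
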