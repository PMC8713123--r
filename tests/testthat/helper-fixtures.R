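# Shared fixture builders; everything is generated in code at test time.

# Panel with fully deterministic values from a generator function of the
# day index (1-based), one column per variable.
toy_panel <- function(n_days = 30L, start = as.Date("2020-01-01"),
                      vars = list(x = function(i) rep(5, length(i)))) {
  dates <- seq(start, by = "day", length.out = n_days)
  vals <- as.data.frame(lapply(vars, function(f) f(seq_len(n_days))))
  env_panel(dates, vals)
}

# A fully degenerate environment parameter set: no seasonality, no noise,
# no trend, no interannual component, no coupling, no missingness.
degenerate_env_params <- function(n_days = 500L, seed = 1L) {
  cfg <- env_var_defaults()
  cfg$amp <- 0; cfg$sd <- 0; cfg$trend <- 0; cfg$sd_slow <- 0; cfg$loading <- 0
  env_sim_params(n_days = n_days, var_config = cfg,
                 o3_coupling = c(no = 0, rh = 0, wind = 0, pm25 = 0),
                 missing_rate = 0, seed = seed)
}

# Small hourly CSV on disk; rows is a data.frame(timestamp, variable, value,
# qc) or a character vector of raw lines.
write_hourly_csv <- function(rows) {
  path <- tempfile(fileext = ".csv")
  if (is.data.frame(rows)) {
    utils::write.csv(rows, path, row.names = FALSE)
  } else {
    writeLines(rows, path)
  }
  path
}

hourly_row <- function(ts, var, value, qc = "pass") {
  data.frame(timestamp = ts, variable = var, value = value, qc = qc,
             stringsAsFactors = FALSE)
}

# Small simulated cohort + complete panel pair for model-level tests.
toy_model_data <- function(n = 200L, seed = 1L, amplitude = 1.5,
                           true_variable = "pm25", true_window = 120L) {
  sim <- simulate_env(env_sim_params(n_days = 1100L, seed = seed))
  cs <- simulate_cohort(sim$truth_panel,
                        cohort_sim_params(n_participants = n,
                                          true_variable = true_variable,
                                          true_window = true_window,
                                          amplitude = amplitude,
                                          seed = seed + 1000L))
  cohort <- filter_cohort(cs$cohort)$cohort
  list(panel = sim$truth_panel, cohort = cohort, truth = cs$truth, sim = sim)
}

# Independent brute-force nesting-rule filter used as the enumeration oracle:
# same guarded rule, written against sets directly rather than the package's
# loop structure.
oracle_nesting_filter <- function(term_sets, aics, tol = 2) {
  n <- length(term_sets)
  imin <- which.min(aics)
  keep <- rep(TRUE, n)
  for (i in setdiff(seq_len(n), imin)) {
    for (j in seq_len(n)) {
      if (identical(i, j)) next
      if (all(term_sets[[j]] %in% term_sets[[i]]) &&
          length(term_sets[[j]]) < length(term_sets[[i]]) &&
          aics[j] <= aics[i] + tol) {
        keep[i] <- FALSE
        break
      }
    }
  }
  keep
}

# Brute-force concordance over all case/non-case pairs (ties get half credit).
oracle_c_index <- function(pred, y) {
  cases <- pred[y == 1]; ctrls <- pred[y == 0]
  tot <- 0
  for (a in cases) for (b in ctrls) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(cases) * length(ctrls))
}
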