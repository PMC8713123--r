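test_that("degenerate parameters give constant series at the configured means", {
  sim <- simulate_env(degenerate_env_params())
  cfg <- env_var_defaults()
  for (v in env_variables()) {
    expect_equal(unique(sim$truth_panel$values[[v]]),
                 cfg$mean[cfg$var == v], tolerance = 1e-12, label = v)
  }
  expect_false(anyNA(sim$panel$values))  # missing_rate 0
})

test_that("simulation is bit-identical under a fixed seed", {
  a <- simulate_env(env_sim_params(n_days = 600L, seed = 7L))
  b <- simulate_env(env_sim_params(n_days = 600L, seed = 7L))
  expect_identical(a$panel$values, b$panel$values)
  expect_identical(a$mask, b$mask)
  ca <- simulate_cohort(a$truth_panel, cohort_sim_params(n_participants = 50L, seed = 3L))
  cb <- simulate_cohort(b$truth_panel, cohort_sim_params(n_participants = 50L, seed = 3L))
  expect_identical(ca$cohort, cb$cohort)
})

test_that("seasonal component matches the analytic oracle and sample means are unbiased", {
  cfg <- env_var_defaults()
  cfg$amp <- 10; cfg$sd <- 0; cfg$trend <- 0; cfg$sd_slow <- 0; cfg$loading <- 0
  p0 <- env_sim_params(n_days = 730L, var_config = cfg,
                       o3_coupling = c(no = 0, rh = 0, wind = 0, pm25 = 0),
                       missing_rate = 0, seed = 2L)
  sim0 <- simulate_env(p0)
  # analytic oracle: amp * cos(2*pi*(doy - phase)/365.25) on top of the mean
  dates <- sim0$truth_panel$dates
  doy <- as.integer(format(dates, "%j"))
  for (v in c("temp", "no")) {
    ph <- cfg$phase[cfg$var == v]; mu <- cfg$mean[cfg$var == v]
    oracle <- mu + 10 * cos(2 * pi * (doy - ph) / 365.25)
    got <- sim0$truth_panel$values[[v]]
    # humidity/pollutant clamping does not bite for these two variables
    expect_equal(got, oracle, tolerance = 1e-10, label = v)
    seasonal <- got - mu
    lag <- 365L
    r365 <- cor(seasonal[1:(730 - lag)], seasonal[(lag + 1):730])
    expect_gt(r365, 0.9)
  }
  # with noise back on: sample mean within 3 analytic standard errors
  cfg$sd <- env_var_defaults()$sd
  p1 <- env_sim_params(n_days = 730L, var_config = cfg,
                       o3_coupling = c(no = 0, rh = 0, wind = 0, pm25 = 0),
                       missing_rate = 0, seed = 2L)
  sim1 <- simulate_env(p1)
  for (v in c("temp", "no2")) {
    sdv <- cfg$sd[cfg$var == v]; arv <- cfg$ar[cfg$var == v]
    se <- sdv * sqrt((1 + arv) / (1 - arv) / 730)
    expect_lt(abs(mean(sim1$truth_panel$values[[v]]) - cfg$mean[cfg$var == v]),
              3 * se + 1e-9, label = v)
  }
})

test_that("missingness respects the rate and gap structure", {
  sim <- simulate_env(env_sim_params(n_days = 2000L, missing_rate = 0.10,
                                     max_gap_days = 7L, seed = 9L))
  frac <- colMeans(is.na(sim$panel$values))
  expect_true(all(frac > 0.03 & frac < 0.2))
  # truth retained where masked
  expect_false(anyNA(sim$truth_panel$values))
  expect_true(all(is.na(as.matrix(sim$panel$values))[sim$mask]))
  # at least one multi-day gap exists
  gaps <- vapply(seq_len(ncol(sim$mask)), function(j) {
    r <- rle(sim$mask[, j]); max(c(r$lengths[r$values], 0L))
  }, 0L)
  expect_true(any(gaps >= 2L))
  expect_error(env_sim_params(missing_rate = 0.5), "missing_rate")
  expect_error(env_sim_params(n_days = 200L), "n_days")
})

test_that("null cohort has prevalence near one half and extreme intercept near zero", {
  sim <- simulate_env(degenerate_env_params(n_days = 1100L))
  null_params <- cohort_sim_params(
    n_participants = 500L, amplitude = 0, beta0 = 0, age_effect = 0,
    sex_effect = 0, season_effects = c(Summer = 0, Autumn = 0, Winter = 0),
    esec_effects = c(middle = 0, working = 0), seed = 5L)
  cs <- simulate_cohort(sim$truth_panel, null_params)
  se <- sqrt(0.25 / 500)
  expect_lt(abs(cs$truth$prevalence - 0.5), 3 * se)
  # binomial tail oracle: with beta0 = -10, P(prevalence > 0.01 at n = 500)
  # = P(Binom(500, 4.54e-5) >= 6) ~ 2e-12
  low <- null_params; low$beta0 <- -10
  cs2 <- suppressWarnings(simulate_cohort(sim$truth_panel, low))
  expect_lte(cs2$truth$prevalence, 0.01)
})

test_that("a strong linear exposure effect is detectable by a plain logistic fit", {
  md <- toy_model_data(n = 600L, seed = 21L, amplitude = 1.5)
  mav <- vapply(seq_len(nrow(md$cohort)), function(i) {
    trailing_mav(md$panel, "pm25", 120L, md$cohort$recruit_date[i])
  }, 0)
  g <- stats::glm(md$cohort$easi10 ~ mav, family = stats::binomial())
  sl <- summary(g)$coefficients["mav", ]
  expect_gt(sl[["Estimate"]], 0)
  expect_lt(sl[["Pr(>|z|)"]], 0.01)
})

test_that("prevalence is monotone in the intercept", {
  sim <- simulate_env(degenerate_env_params(n_days = 1100L))
  prevs <- vapply(c(-2, 0, 2), function(b0) {
    cp <- cohort_sim_params(n_participants = 2000L, amplitude = 0, beta0 = b0,
                            age_effect = 0, sex_effect = 0,
                            season_effects = c(Summer = 0, Autumn = 0, Winter = 0),
                            esec_effects = c(middle = 0, working = 0), seed = 8L)
    simulate_cohort(sim$truth_panel, cp)$truth$prevalence
  }, 0)
  expect_true(all(diff(prevs) > 0))
})

test_that("severity score is consistent with the binary label and covariates look sane", {
  md <- toy_model_data(n = 300L, seed = 33L)
  ch <- md$cohort
  expect_identical(ch$easi10, as.integer(ch$easi > 10))
  expect_true(all(ch$age >= 1 & ch$age <= 30))
  expect_true(all(ch$esec %in% 1:9))
  expect_true(all(ch$sex %in% c("F", "M")))
  # every recruitment date has a full year of panel history
  expect_true(all(ch$recruit_date - 365 >= min(md$panel$dates)))
})

test_that("default preset induces at least one long-window pair above the composite threshold", {
  sim <- simulate_env(env_sim_params(seed = 5L))
  p <- sim$truth_panel
  M <- cbind(mav_series(p, "wind", 365), mav_series(p, "no", 365),
             mav_series(p, "no2", 365), mav_series(p, "o3", 270),
             mav_series(p, "rh", 180), mav_series(p, "temp", 180),
             mav_series(p, "pm10", 270), mav_series(p, "pm25", 120))
  M <- M[stats::complete.cases(M), ]
  C <- stats::cor(M)
  expect_gt(max(abs(C[upper.tri(C)])), 0.8)
})

test_that("score_imputation computes masked-cell RMSE exactly", {
  truth <- toy_panel(10L, vars = list(a = function(i) i, b = function(i) 2 * i))
  mask <- matrix(FALSE, 10L, 2L, dimnames = list(NULL, c("a", "b")))
  mask[c(2, 5), 1] <- TRUE
  mask[7, 2] <- TRUE
  expect_equal(unname(score_imputation(truth, truth, mask)), c(0, 0))
  shifted <- env_panel(truth$dates, truth$values + 1)
  expect_equal(unname(score_imputation(truth, shifted, mask)), c(1, 1))
  # random fixture against direct arithmetic
  set.seed(4)
  imp_vals <- truth$values
  imp_vals$a[c(2, 5)] <- truth$values$a[c(2, 5)] + c(0.5, -1.5)
  imp_vals$b[7] <- truth$values$b[7] + 3
  got <- score_imputation(truth, env_panel(truth$dates, imp_vals), mask)
  expect_equal(unname(got["a"]), sqrt(mean(c(0.5, -1.5)^2)))
  expect_equal(unname(got["b"]), 3)
  expect_error(score_imputation(truth, truth, mask & FALSE), "empty mask")
})

test_that("hourly expansion reproduces daily means up to jitter", {
  pan <- toy_panel(5L, vars = list(temp = function(i) 10 + i))
  h <- as_hourly(pan, jitter_sd = 0, seed = 1L)
  expect_equal(nrow(h), 5L * 24L)
  m <- tapply(h$value, as.Date(h$timestamp), mean)
  expect_equal(as.numeric(m), 10 + 1:5, tolerance = 1e-12)
})
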