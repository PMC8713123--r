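test_that("basis blocks have the documented penalty rank and centering", {
  d <- data.frame(x = 0:9)
  b <- build_basis(d, sm("x", k = 4L, pord = 2L))
  expect_equal(qr(b$S_raw[[1]])$rank, 2L)            # k - pord before constraint
  expect_equal(max(abs(colSums(b$X))), 0, tolerance = 1e-10)
  # cubic B-splines reproduce a quadratic exactly (least-squares oracle)
  d2 <- data.frame(x = seq(0, 1, length.out = 50))
  b2 <- build_basis(d2, sm("x", k = 8L))
  y <- 3 * d2$x^2 - d2$x + 0.5
  Xf <- cbind(1, b2$X)
  res <- y - Xf %*% qr.solve(Xf, y)
  expect_lt(max(abs(res)), 1e-8)
  expect_error(build_basis(data.frame(x = rep(1:3, 5)), sm("x", k = 10L)),
               "distinct")
})

test_that("tensor-product blocks carry two penalties and center like univariate ones", {
  set.seed(1)
  d <- data.frame(u = runif(60), v = runif(60))
  b <- build_basis(d, sm(c("u", "v"), k = c(4L, 4L)))
  expect_length(b$S, 2L)
  expect_equal(ncol(b$X), 15L)  # 16 tensor columns minus one constraint
  expect_equal(max(abs(colSums(b$X))), 0, tolerance = 1e-8)
})

test_that("infinite-penalty binomial fits match the linear logistic oracle", {
  set.seed(2)
  n <- 250L
  d <- data.frame(x = runif(n), z = rnorm(n))
  d$y <- rbinom(n, 1L, plogis(-0.4 + 1.8 * d$x - 0.9 * d$z))
  spec <- pgam_spec("y", smooths = list(sm("x"), sm("z")))
  f <- fit_pgam(spec, d, fixed_lambda = Inf)
  g <- stats::glm(y ~ x + z, family = stats::binomial(), data = d)
  expect_lt(max(abs(f$fitted - stats::fitted(g))), 1e-6)
})

test_that("zero-penalty fits match the unpenalized basis-regression oracle", {
  set.seed(3)
  n <- 200L
  d <- data.frame(x = runif(n))
  d$y <- rbinom(n, 1L, plogis(sin(6 * d$x)))
  spec <- pgam_spec("y", smooths = list(sm("x", k = 6L)))
  f <- fit_pgam(spec, d, fixed_lambda = 0)
  B <- f$design$X[, -1, drop = FALSE]
  g <- stats::glm(d$y ~ B, family = stats::binomial())
  expect_lt(max(abs(f$fitted - stats::fitted(g))), 1e-6)
  # AIC difference of an unpenalized nested pair equals LR statistic - 2*ddf
  f0 <- fit_pgam(pgam_spec("y"), d)
  lr <- -2 * (f0$loglik - f$loglik)
  ddf <- f$edf_total - f0$edf_total
  expect_equal(f$aic - f0$aic, -lr + 2 * ddf, tolerance = 1e-6)
})

test_that("infinite-penalty Gaussian fits reproduce ordinary least squares", {
  set.seed(4)
  n <- 120L
  d <- data.frame(x = runif(n), z = runif(n))
  d$y <- 1 + 2 * d$x - d$z + rnorm(n, 0, 0.3)
  f <- fit_pgam(pgam_spec("y", smooths = list(sm("x"), sm("z")),
                          family = "gaussian"), d, fixed_lambda = Inf)
  o <- stats::lm(y ~ x + z, data = d)
  expect_lt(max(abs(f$fitted - stats::fitted(o))), 1e-8)
})

test_that("the inner penalized deviance trace is non-increasing", {
  md <- toy_model_data(n = 200L, seed = 18L)
  expo <- build_exposure_matrix(md$panel, md$cohort, variables = "pm25",
                                windows = 120L)
  d <- md$cohort
  d$mav <- expo[, "pm25 120"]
  f <- fit_pgam(pgam_spec("easi10", smooths = list(sm("mav")),
                          factors = "sex"), d)
  tr <- f$pirls_trace
  expect_true(all(diff(tr) <= 1e-8 * pmax(abs(tr[-length(tr)]), 1)))
})

test_that("effective degrees of freedom decrease monotonically in lambda", {
  set.seed(5)
  n <- 150L
  d <- data.frame(x = runif(n))
  d$y <- rbinom(n, 1L, plogis(sin(5 * d$x)))
  spec <- pgam_spec("y", smooths = list(sm("x", k = 10L)))
  edfs <- vapply(10^seq(-3, 6, by = 1), function(lam) {
    fit_pgam(spec, d, fixed_lambda = lam)$edf_total
  }, 0)
  expect_true(all(diff(edfs) <= 1e-8))
  expect_lt(min(edfs), 3)         # heavy penalty: intercept + linear
  expect_gt(max(edfs), 5)         # light penalty: close to k - 1
})

test_that("REML-chosen smoothing shrinks null effects relative to no penalty", {
  # simulated null: the REML fit should essentially never lose to the
  # unpenalized fit on AIC
  wins <- 0L
  for (s in 1:50) {
    set.seed(1000 + s)
    n <- 120L
    d <- data.frame(x = runif(n), y = rbinom(n, 1L, 0.4))
    spec <- pgam_spec("y", smooths = list(sm("x", k = 8L)))
    f_reml <- fit_pgam(spec, d)
    f_wiggly <- fit_pgam(spec, d, fixed_lambda = 1e-4)
    wins <- wins + (f_reml$aic <= f_wiggly$aic + 1e-8)
  }
  expect_gte(wins, 45L)
})

test_that("prediction reproduces training fits and manual basis evaluation", {
  set.seed(6)
  n <- 150L
  d <- data.frame(x = runif(n), sex = sample(c("F", "M"), n, replace = TRUE))
  d$y <- rbinom(n, 1L, plogis(-0.3 + sin(4 * d$x) + 0.5 * (d$sex == "M")))
  f <- fit_pgam(pgam_spec("y", smooths = list(sm("x")), factors = "sex"), d)
  expect_equal(predict(f, d), f$fitted, tolerance = 1e-10)
  # intercept-only model predicts the outcome mean
  f0 <- fit_pgam(pgam_spec("y"), d)
  expect_equal(unique(round(predict(f0, d), 10)), round(mean(d$y), 10))
  # manual dot product on a 2-row newdata
  nd <- data.frame(x = c(0.3, 0.6), sex = c("F", "M"))
  G <- expowin:::eval_basis(f$design$bases[["x"]], nd)
  ci <- Filter(function(z) z$term == "x", f$design$col_info)[[1]]
  eta_manual <- f$coefficients[1] + drop(G %*% f$coefficients[ci$idx]) +
    f$coefficients[["sex:M"]] * c(0, 1)
  expect_equal(predict(f, nd, type = "link"), eta_manual, tolerance = 1e-10)
  expect_error(predict(f, data.frame(x = 0.5, sex = "X")), "unknown level")
  expect_warning(predict(f, data.frame(x = 2, sex = "F")), "outside training range")
})

test_that("partial effects are centered, linear in the heavy-penalty limit, and banded correctly", {
  set.seed(7)
  n <- 200L
  d <- data.frame(x = runif(n))
  d$y <- rbinom(n, 1L, plogis(2 * (d$x - 0.5)))
  f <- fit_pgam(pgam_spec("y", smooths = list(sm("x"))), d, fixed_lambda = Inf)
  pe <- partial_effect(f, "x", n_grid = 50L)
  # straight line through zero at the covariate mean
  fit_line <- stats::lm(effect ~ x, data = pe)
  expect_lt(max(abs(stats::resid(fit_line))), 1e-6)
  expect_lt(abs(stats::predict(fit_line, data.frame(x = mean(d$x)))), 0.05)
  # band half-width equals the linear-algebra oracle at 3 grid points
  ci <- Filter(function(z) z$term == "x", f$design$col_info)[[1]]
  V <- f$Vb[ci$idx, ci$idx]
  G <- expowin:::eval_basis(f$design$bases[["x"]],
                            data.frame(x = pe$x[c(1, 25, 50)]))
  half <- 1.96 * sqrt(diag(G %*% V %*% t(G)))
  expect_equal((pe$hi - pe$lo)[c(1, 25, 50)] / 2, half, tolerance = 1e-10)
  # a null effect is flagged not significant
  set.seed(8)
  d0 <- data.frame(x = runif(n), y = rbinom(n, 1L, 0.5))
  f0 <- fit_pgam(pgam_spec("y", smooths = list(sm("x"))), d0)
  expect_false(attr(partial_effect(f0, "x"), "significant"))
})

test_that("concordance equals brute-force pair counting and is rank-invariant", {
  y <- c(1, 1, 0, 0, 0, 1)
  p <- c(0.9, 0.4, 0.4, 0.2, 0.1, 0.8)
  got <- c_index(p, y, n_boot = 0L)
  expect_equal(got$value, oracle_c_index(p, y))
  expect_equal(c_index(rank(p) + 100, y, n_boot = 0L)$value, got$value)
  expect_equal(c_index(qlogis(p), y, n_boot = 0L)$value, got$value)
  expect_equal(c_index(c(1, 1, 0, 0, 0, 1), y, n_boot = 0L)$value, 1)
  expect_equal(c_index(rep(0.3, 6), y, n_boot = 0L)$value, 0.5)
  set.seed(9)
  y2 <- rbinom(40, 1, 0.5); p2 <- runif(40)
  expect_equal(c_index(p2, y2, n_boot = 0L)$value, oracle_c_index(p2, y2))
  ci <- c_index(p2, y2, n_boot = 200L, seed = 4L)
  expect_true(ci$ci[1] <= ci$value && ci$value <= ci$ci[2])
  expect_error(c_index(p2, rep(1, 40)), "both outcome classes")
})

test_that("adjusted R-squared follows its deviance definition", {
  set.seed(10)
  n <- 120L
  d <- data.frame(x = runif(n))
  d$y <- rbinom(n, 1L, plogis(3 * (d$x - 0.5)))
  f0 <- fit_pgam(pgam_spec("y"), d)
  expect_equal(adjusted_r2(f0), 0, tolerance = 1e-10)
  f <- fit_pgam(pgam_spec("y", smooths = list(sm("x"))), d)
  oracle <- 1 - (f$deviance / (f$n - f$edf_total)) / (f$null_deviance / (f$n - 1))
  expect_equal(adjusted_r2(f), oracle)
  expect_equal(aic(f), -2 * f$loglik + 2 * f$edf_total)
  # noiseless Gaussian fit approaches 1
  dg <- data.frame(x = seq(0, 1, length.out = 100))
  dg$y <- 2 + 3 * dg$x
  fg <- fit_pgam(pgam_spec("y", smooths = list(sm("x")), family = "gaussian"), dg)
  expect_gt(adjusted_r2(fg), 0.999)
})

test_that("degenerate model inputs are rejected", {
  d <- data.frame(y = rbinom(50, 1, 0.5), x = runif(50),
                  g = rep("a", 50))
  expect_error(fit_pgam(pgam_spec("y", smooths = list(sm("x"))), d[1:10, ]),
               "at least 30")
  expect_error(fit_pgam(pgam_spec("y", factors = "g"), d), "fewer than 2")
  expect_error(pgam_spec("y", smooths = list(sm("x"), sm("x"))), "more than once")
  d2 <- d
  d2$y <- 0L
  expect_error(fit_pgam(pgam_spec("y", smooths = list(sm("x"))), d2),
               "single observed class")
  # perfectly separated factor triggers the separation guard
  d3 <- data.frame(y = rep(c(0L, 1L), each = 25), g = rep(c("a", "b"), each = 25),
                   x = runif(50))
  expect_error(fit_pgam(pgam_spec("y", smooths = list(sm("x")), factors = "g"), d3),
               "separation")
})

test_that("AIC comparisons agree with an independent penalized-spline engine", {
  skip_if_not_installed("mgcv")
  md <- toy_model_data(n = 250L, seed = 19L)
  expo <- build_exposure_matrix(md$panel, md$cohort, variables = "pm25",
                                windows = 120L)
  d <- md$cohort
  d$mav <- expo[, "pm25 120"]
  f <- fit_pgam(pgam_spec("easi10",
                          smooths = list(sm("mav"), sm("age"), sm("bmi")),
                          factors = c("sex", "season")), d)
  g <- mgcv::gam(easi10 ~ s(mav, bs = "ps", k = 10) + s(age, bs = "ps", k = 10) +
                   s(bmi, bs = "ps", k = 10) + sex + season,
                 family = stats::binomial(), method = "REML", data = d)
  # engines differ in basis details and AIC correction; agreement is coarse
  expect_lt(abs(f$edf_total - sum(g$edf)), 1.5)
  expect_gt(stats::cor(f$fitted, stats::fitted(g)), 0.99)
  expect_lt(abs(f$aic - stats::AIC(g)), 10)
})

test_that("response-scale partial effects transform through the intercept", {
  set.seed(12)
  n <- 150L
  d <- data.frame(x = runif(n))
  d$y <- rbinom(n, 1L, plogis(-1 + 2 * d$x))
  f <- fit_pgam(pgam_spec("y", smooths = list(sm("x"))), d)
  pe <- partial_effect(f, "x", n_grid = 25L, scale = "response")
  expect_equal(pe$prob, plogis(coef(f)[[1]] + pe$effect), tolerance = 1e-12)
  expect_true(all(pe$prob_lo <= pe$prob & pe$prob <= pe$prob_hi))
  d$z <- d$x + rnorm(n, 0, 0.1)
  fg <- fit_pgam(pgam_spec("z", smooths = list(sm("x")), family = "gaussian"), d)
  expect_error(partial_effect(fg, "x", scale = "response"), "binomial")
})
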