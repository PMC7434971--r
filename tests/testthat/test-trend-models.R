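test_that("logistic fit reproduces the closed-form 2x2 odds ratio", {
  # grouped data: 2/10 successes at x = 0, 8/10 at x = 1
  y <- c(rep(0, 8), rep(1, 2), rep(0, 2), rep(1, 8))
  x <- rep(c(0, 1), each = 10)
  fit <- fit_logistic_trend(y, x)
  expect_equal(fit$or_time, 16.0, tolerance = 1e-6)
  expect_equal(fit$beta_time, log(16), tolerance = 1e-6)
  expect_equal(fit$se_time, sqrt(1 / 8 + 1 / 2 + 1 / 2 + 1 / 8),
               tolerance = 1e-4)
  expect_equal(fit$or_time, exp(fit$beta_time), tolerance = 1e-9)
  expect_equal(fit$wald_time, (fit$beta_time / fit$se_time)^2,
               tolerance = 1e-6)
  expect_true(fit$lr_chi2 > 0)
  expect_true(fit$p_time >= 0 && fit$p_time <= 1)
})

test_that("single class and separation are explicit errors", {
  expect_error(fit_logistic_trend(rep(1L, 20)), "single class")
  y <- rep(c(0, 1), each = 15)
  expect_error(fit_logistic_trend(y, seq_along(y)),
               "separation|converge")
})

test_that("time reversal negates the slope and preserves Wald", {
  withr::local_seed(31)
  y <- rbinom(60, 1, plogis(-1 + 0.05 * (1:60)))
  f1 <- fit_logistic_trend(y)
  f2 <- fit_logistic_trend(rev(y))
  expect_equal(f1$beta_time, -f2$beta_time, tolerance = 1e-6)
  expect_equal(f1$wald_time, f2$wald_time, tolerance = 1e-6)
})

test_that("Wald test holds its nominal type-I error under the null", {
  withr::local_seed(77)
  rej <- vapply(1:200, function(i) {
    y <- rbinom(95, 1, 0.3)
    f <- tryCatch(fit_logistic_trend(y), error = function(e) NULL)
    if (is.null(f)) NA else f$p_time < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej, na.rm = TRUE) - 0.05), 0.03)
})

test_that("ACF matches direct formulas and stats::acf; PACF matches
           Durbin-Levinson expectations", {
  x <- rep(c(1, -1), 50)
  cg <- acf_pacf(x, max_lag = 3)
  expect_equal(cg$acf[1], -99 / 100, tolerance = 1e-12)
  expect_equal(cg$ci_bound, 1.96 / 10)

  withr::local_seed(41)
  y <- as.numeric(arima.sim(list(ar = 0.8), 400))
  cg <- acf_pacf(y, max_lag = 10)
  ref_acf <- as.numeric(stats::acf(y, lag.max = 10, plot = FALSE)$acf)[-1]
  ref_pacf <- as.numeric(stats::pacf(y, lag.max = 10, plot = FALSE)$acf)
  expect_equal(cg$acf, ref_acf, tolerance = 1e-10)
  expect_equal(cg$pacf, ref_pacf, tolerance = 1e-8)
  # AR(1): geometric ACF decay, PACF cutoff after lag 1
  expect_equal(cg$acf[2], cg$acf[1]^2, tolerance = 0.1)
  expect_true(all(abs(cg$pacf[3:10]) < 0.15))
  expect_error(acf_pacf(rep(1, 50), 5), "zero variance")
})

test_that("white-noise ACF stays inside the asymptotic band", {
  withr::local_seed(53)
  hits <- vapply(1:100, function(i) {
    abs(acf_pacf(rnorm(500), max_lag = 1)$acf[1]) < 0.1
  }, logical(1))
  expect_gt(mean(hits), 0.9)        # theoretical approx. 0.97
})

test_that("ARIMA(1,1,1) on white noise finds null coefficients", {
  withr::local_seed(61)
  x <- cumsum(rnorm(300))
  fit <- fit_arima(x, 1, 1, 1)
  expect_lt(abs(fit$ar1), 2 * fit$se[1] + 0.05)
  expect_lt(abs(fit$ma1), 2 * fit$se[2] + 0.05)
  expect_equal(length(fit$residuals), 299L)
  expect_equal(fit$ma_sign_convention, "+theta")
})

test_that("differencing a linear trend recovers the slope as constant", {
  withr::local_seed(67)
  x <- 0.35 * (1:200) + rnorm(200, sd = 0.4)
  fit <- fit_arima(x, 1, 1, 1)
  expect_equal(fit$constant, 0.35, tolerance = 0.05)
})

test_that("drift is invariant to adding a constant when d = 1", {
  withr::local_seed(71)
  x <- cumsum(rnorm(120, mean = 0.2))
  f1 <- fit_arima(x, 1, 1, 1)
  f2 <- fit_arima(x + 100, 1, 1, 1)
  expect_equal(f1$constant, f2$constant, tolerance = 1e-6)
  expect_equal(f1$ar1, f2$ar1, tolerance = 1e-6)
})

test_that("Ljung-Box matches the direct formula and Box.test", {
  # zero-autocorrelation residuals -> Q = 0
  z <- rep(c(1, -1), 20)                     # r1 = -1, not zero; use iid
  withr::local_seed(83)
  r0 <- rnorm(50)
  direct_Q <- function(x, h) {
    n <- length(x); xc <- x - mean(x)
    r <- sapply(1:h, function(k)
      sum(xc[1:(n - k)] * xc[(k + 1):n]) / sum(xc^2))
    n * (n + 2) * sum(r^2 / (n - 1:h))
  }
  hand <- c(1, 2, 1, 2, 1, 2, 1, 2)
  lb <- ljung_box(hand, lags = 2)
  expect_equal(lb$Q, direct_Q(hand, 2), tolerance = 1e-12)
  expect_equal(lb$df, 2L)
  bt <- stats::Box.test(r0, lag = 5, type = "Ljung-Box")
  lb2 <- ljung_box(r0, lags = 5)
  expect_equal(lb2$Q, unname(bt$statistic), tolerance = 1e-8)
  expect_equal(lb2$p, bt$p.value, tolerance = 1e-8)
  expect_error(ljung_box(r0, lags = 2, fitdf = 2), "freedom")
})

test_that("Ljung-Box rejection rate is nominal under white noise", {
  withr::local_seed(89)
  rej <- vapply(1:200, function(i)
    ljung_box(rnorm(95), lags = 10)$p < 0.05, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.03)
})
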