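#' Logistic trend of centroid category on time
#'
#' Maximum-likelihood binary logistic regression of the outside-centroid
#' indicator on the dream sequence number, testing whether highly
#' charged documents become more frequent with time.  Reports Wald
#' statistics per coefficient, the likelihood-ratio chi-square against
#' the intercept-only model, odds ratios, and two concordance readings:
#' percent correctly classified at cutoff 0.5 (the default headline
#' number) and the concordant-pairs c-statistic.
#'
#' @param labels Binary series: values in \{1, 2\} (1 = inside,
#'   2 = outside) or \{0, 1\} or logical; the larger value is the event.
#' @param time Time covariate, defaults to `seq_along(labels)`.
#' @return A `logistic_fit`: coefficients (`beta_time`, `beta_const`),
#'   standard errors, Wald chi-squares, p-values, odds ratios,
#'   `lr_chi2`/`lr_df`/`lr_p`, `concordance_pct`, `c_statistic`,
#'   `converged`.
#' @export
fit_logistic_trend <- function(labels, time = seq_along(labels)) {
  y <- as.integer(labels)
  stopifnot(length(y) == length(time))
  u <- sort(unique(y))
  if (length(u) != 2L) stop("single class: both categories must be present")
  y <- as.integer(y == u[2])

  # glm.fit's separation/convergence warnings are re-raised below as
  # explicit errors, so the raw warnings are muffled here
  fit <- withCallingHandlers(
    stats::glm(y ~ time, family = stats::binomial()),
    warning = function(w) invokeRestart("muffleWarning"))
  if (!fit$converged) stop("logistic fit did not converge")
  p_hat <- stats::fitted(fit)
  if (any(p_hat > 1 - 1e-10) || any(p_hat < 1e-10)) {
    stop("complete or quasi-complete separation detected")
  }
  cf <- summary(fit)$coefficients
  beta <- cf[, "Estimate"]
  se <- cf[, "Std. Error"]
  wald <- (beta / se)^2
  p <- stats::pchisq(wald, df = 1, lower.tail = FALSE)
  lr <- fit$null.deviance - fit$deviance

  concord <- 100 * mean((p_hat >= 0.5) == (y == 1L))
  # concordant-pairs c-statistic (area under the ROC curve)
  r <- rank(p_hat)
  n1 <- sum(y)
  n0 <- length(y) - n1
  cstat <- if (n0 > 0 && n1 > 0)
    (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n0 * n1) else NA_real_

  structure(list(
    beta_const = unname(beta[1]), beta_time = unname(beta[2]),
    se_const = unname(se[1]), se_time = unname(se[2]),
    wald_const = unname(wald[1]), wald_time = unname(wald[2]),
    p_const = unname(p[1]), p_time = unname(p[2]),
    or_const = exp(unname(beta[1])), or_time = exp(unname(beta[2])),
    lr_chi2 = lr, lr_df = 1L,
    lr_p = stats::pchisq(lr, df = 1, lower.tail = FALSE),
    concordance_pct = concord, c_statistic = cstat,
    converged = fit$converged
  ), class = "logistic_fit")
}

#' Sample autocorrelation and partial autocorrelation
#'
#' ACF with the biased denominator N on the mean-centered series,
#' \eqn{r_k = \sum_{t=1}^{N-k}(x_t-\bar x)(x_{t+k}-\bar x) /
#' \sum(x_t-\bar x)^2}; PACF by Durbin-Levinson recursion; the 95%
#' white-noise band is \eqn{\pm 1.96/\sqrt N}.
#'
#' @param x Numeric series.
#' @param max_lag Largest lag (default `10 * log10(N)` as is customary).
#' @return A `correlogram`: list with `acf`, `pacf` (lags 1..max_lag),
#'   `ci_bound`, `n`.
#' @export
acf_pacf <- function(x, max_lag = floor(10 * log10(length(x)))) {
  x <- as.numeric(x)
  n <- length(x)
  stopifnot(n > max_lag + 1, max_lag >= 1)
  if (stats::var(x) == 0) stop("constant series: zero variance")
  xc <- x - mean(x)
  denom <- sum(xc^2)
  r <- vapply(seq_len(max_lag), function(k)
    sum(xc[seq_len(n - k)] * xc[(k + 1):n]) / denom, numeric(1))

  # Durbin-Levinson: phi[k,k] is the lag-k partial autocorrelation
  pacf <- numeric(max_lag)
  phi_prev <- numeric(0)
  for (k in seq_len(max_lag)) {
    if (k == 1L) {
      phi_k <- r[1]
      phi_new <- phi_k
    } else {
      num <- r[k] - sum(phi_prev * r[(k - 1):1])
      den <- 1 - sum(phi_prev * r[1:(k - 1)])
      phi_k <- num / den
      phi_new <- c(phi_prev - phi_k * rev(phi_prev), phi_k)
    }
    pacf[k] <- phi_k
    phi_prev <- phi_new
  }
  structure(list(acf = r, pacf = pacf, ci_bound = 1.96 / sqrt(n), n = n),
            class = "correlogram")
}

#' Fit an ARIMA(p, d, q) model with drift
#'
#' The series is differenced `d` times and an ARMA(p, q) with constant
#' (drift on the original scale) is estimated by maximum likelihood via
#' [stats::arima()].  The moving-average polynomial uses the
#' \eqn{x_t = \ldots + \varepsilon_t + \theta_1\varepsilon_{t-1}} sign
#' convention ("+theta" form); this convention is recorded in the
#' returned object because clinical-stats packages disagree about it.
#' The reported R-squared is the "stationary R-squared": variance
#' explained on the differenced scale, `1 - SSE(residuals) /
#' SST(differenced series)`.
#'
#' @param x Numeric series, `length(x) - d > 10`.
#' @param p,d,q Model order (defaults 1, 1, 1).
#' @return An `arima_fit`: `order`, `coef` (constant, ar, ma), `se`,
#'   `t_stats`, `p_values`, `r_squared`, `residuals`, `converged`,
#'   `stationary`, `invertible`, `ma_sign_convention`.
#' @export
fit_arima <- function(x, p = 1L, d = 1L, q = 1L) {
  x <- as.numeric(x)
  stopifnot(length(x) - d > 10L, p >= 0L, d >= 0L, q >= 0L)
  w <- if (d > 0) diff(x, differences = d) else x
  fit <- tryCatch(
    stats::arima(w, order = c(p, 0L, q), include.mean = TRUE,
                 method = "ML"),
    error = function(e) stats::arima(w, order = c(p, 0L, q),
                                     include.mean = TRUE, method = "CSS"))
  cf <- fit$coef
  se <- sqrt(pmax(diag(fit$var.coef), 0))
  tt <- cf / ifelse(se > 0, se, NA_real_)
  pv <- 2 * stats::pnorm(-abs(tt))
  res <- as.numeric(stats::residuals(fit))
  sst <- sum((w - mean(w))^2)
  r2 <- if (sst > 0) 1 - sum(res^2) / sst else NA_real_

  ar <- if (p > 0) unname(cf[grep("^ar", names(cf))]) else numeric(0)
  ma <- if (q > 0) unname(cf[grep("^ma", names(cf))]) else numeric(0)
  structure(list(
    order = c(p = p, d = d, q = q),
    coef = cf, se = se, t_stats = tt, p_values = pv,
    constant = unname(cf["intercept"]),
    ar1 = if (p >= 1) ar[1] else NA_real_,
    ma1 = if (q >= 1) ma[1] else NA_real_,
    r_squared = r2,
    residuals = res,
    converged = is.null(fit$code) || fit$code == 0,
    stationary = all(Mod(polyroot(c(1, -ar))) > 1) || p == 0,
    invertible = all(Mod(polyroot(c(1, ma))) > 1) || q == 0,
    ma_sign_convention = "+theta",
    aic = fit$aic
  ), class = "arima_fit")
}

#' Ljung-Box portmanteau test on residuals
#'
#' \eqn{Q = N(N+2)\sum_{k=1}^{h} r_k^2/(N-k)}, compared to a chi-square
#' with `h - fitdf` degrees of freedom, where `fitdf` is the number of
#' ARMA parameters estimated from the same data.
#'
#' @param residuals Residual series.
#' @param lags Number of autocorrelation lags h.
#' @param fitdf Parameters already fitted (default 0).
#' @return List with `Q`, `df`, `p`.
#' @export
ljung_box <- function(residuals, lags, fitdf = 0L) {
  x <- as.numeric(residuals)
  n <- length(x)
  stopifnot(n > lags, lags >= 1)
  df <- lags - fitdf
  if (df <= 0) stop("degrees of freedom <= 0: increase lags")
  xc <- x - mean(x)
  denom <- sum(xc^2)
  r <- vapply(seq_len(lags), function(k)
    sum(xc[seq_len(n - k)] * xc[(k + 1):n]) / denom, numeric(1))
  Q <- n * (n + 2) * sum(r^2 / (n - seq_len(lags)))
  list(Q = Q, df = df, p = stats::pchisq(Q, df = df, lower.tail = FALSE))
}
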