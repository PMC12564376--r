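#' Moment-ratio skewness and kurtosis
#'
#' Skewness \eqn{\sum (Z_i - \bar Z)^3 / ((m-1) s^3)} and raw (non-excess)
#' kurtosis \eqn{\sum (Z_i - \bar Z)^4 / ((m-1) s^4)}, with `s` the sample
#' standard deviation (the `m - 1` divisor throughout). The normal reference
#' for kurtosis is 3.
#'
#' @param series Numeric vector, length >= 3, non-constant.
#' @return A single numeric value.
#' @export
skewness <- function(series) {
  m <- .check_moments(series)
  s <- stats::sd(series)
  sum((series - mean(series))^3) / ((m - 1) * s^3)
}

#' @rdname skewness
#' @export
kurtosis <- function(series) {
  m <- .check_moments(series)
  s <- stats::sd(series)
  sum((series - mean(series))^4) / ((m - 1) * s^4)
}

.check_moments <- function(series) {
  if (length(series) < 3) stop("'series' must have length >= 3")
  if (!all(is.finite(series))) stop("'series' must be finite")
  if (stats::sd(series) == 0) stop("constant series: zero standard deviation")
  length(series)
}

#' Jarque-Bera normality test
#'
#' Statistic \eqn{n S^2/6 + n (K-3)^2/24} with `S` the skewness and `K` the
#' raw kurtosis as computed by [skewness()]/[kurtosis()]; p-value from the
#' asymptotic chi-squared reference with 2 degrees of freedom. Rejection
#' indicates departure from normality.
#'
#' @param series Numeric vector, length >= 3, non-constant.
#' @return List with `statistic`, `p_value`, `skewness`, `kurtosis`.
#' @export
jarque_bera <- function(series) {
  n <- .check_moments(series)
  s <- skewness(series)
  k <- kurtosis(series)
  stat <- n * s^2 / 6 + n * (k - 3)^2 / 24
  list(statistic = stat, p_value = stats::pchisq(stat, df = 2, lower.tail = FALSE),
       skewness = s, kurtosis = k)
}

#' Durbin-Watson statistic
#'
#' \eqn{\sum_{t=2}^n (e_t - e_{t-1})^2 / \sum_t e_t^2}, bounded in
#' \[0, 4\]. Values near 2 indicate no first-order serial correlation;
#' below 2, positive correlation; between 2 and 4, negative correlation.
#'
#' @param residuals Numeric vector, length >= 2, not all zero.
#' @return List with `statistic` and `interpretation` (band label).
#' @export
durbin_watson <- function(residuals) {
  if (length(residuals) < 2) stop("'residuals' must have length >= 2")
  if (all(residuals == 0)) stop("all-zero residuals")
  d <- sum(diff(residuals)^2) / sum(residuals^2)
  interp <- if (d < 2) "positive correlation" else if (d > 2) "negative correlation" else "no correlation"
  list(statistic = d, interpretation = interp)
}

#' ARCH-LM test for conditional heteroskedasticity
#'
#' Engle's Lagrange-multiplier test: regress squared residuals on their own
#' first `lags` lags (with intercept); the statistic is `n * R^2` of that
#' auxiliary regression, referred to chi-squared(`lags`).
#'
#' @param residuals Numeric residual series.
#' @param lags Number of lags (default 5).
#' @return List with `statistic`, `p_value`, `lags`.
#' @export
arch_lm_test <- function(residuals, lags = 5) {
  if (lags < 1) stop("'lags' must be >= 1")
  lags <- as.integer(lags)
  if (length(residuals) <= lags + 2) stop("residual series too short for ", lags, " lags")
  e2 <- residuals^2
  if (stats::sd(e2) == 0) stop("degenerate input: constant squared residuals")
  E <- stats::embed(e2, lags + 1L)
  y <- E[, 1L]
  X <- cbind(1, E[, -1L, drop = FALSE])
  res <- qr.resid(qr(X), y)
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  stat <- length(y) * r2
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = lags, lower.tail = FALSE),
       lags = lags)
}

#' Ljung-Box test on squared residuals
#'
#' Standard Ljung-Box portmanteau test applied to the squared
#' (standardised) residuals, the usual check that a variance model has
#' removed volatility clustering.
#'
#' @param residuals Residual series (standardised residuals for a fitted
#'   variance model).
#' @param lags Number of autocorrelation lags (>= 1).
#' @return List with `statistic`, `p_value`, `lags`.
#' @export
ljung_box_squared <- function(residuals, lags = 5) {
  if (lags < 1) stop("'lags' must be >= 1")
  if (length(residuals) <= lags + 2) stop("residual series too short for ", lags, " lags")
  bt <- stats::Box.test(residuals^2, lag = as.integer(lags), type = "Ljung-Box")
  list(statistic = unname(bt$statistic), p_value = unname(bt$p.value),
       lags = as.integer(lags))
}

## Dickey-Fuller tau_mu quantiles (ADF regression with constant), by sample
## size and probability; interpolated in both dimensions for the p-value.
.adf_tau_mu <- local({
  tbl <- rbind(
    c(-3.75, -3.33, -3.00, -2.62, -0.37, 0.00, 0.34, 0.72),
    c(-3.58, -3.22, -2.93, -2.60, -0.40, -0.03, 0.29, 0.66),
    c(-3.51, -3.17, -2.89, -2.58, -0.42, -0.05, 0.26, 0.63),
    c(-3.46, -3.14, -2.88, -2.57, -0.42, -0.06, 0.24, 0.62),
    c(-3.44, -3.13, -2.87, -2.57, -0.43, -0.07, 0.24, 0.61),
    c(-3.43, -3.12, -2.86, -2.57, -0.44, -0.07, 0.23, 0.60))
  list(n = c(25, 50, 100, 250, 500, 1e5),
       probs = c(0.01, 0.025, 0.05, 0.10, 0.90, 0.95, 0.975, 0.99),
       tbl = tbl)
})

#' Augmented Dickey-Fuller unit-root test (with constant)
#'
#' Fits \eqn{\Delta y_t = a + \rho y_{t-1} + \sum_{i=1}^k \phi_i \Delta
#' y_{t-i} + e_t}, choosing the augmentation order `k` in `0..max_lag` by
#' AIC on a common sample, and tests \eqn{\rho = 0}. The p-value
#' interpolates the Dickey-Fuller tau quantile table (constant case) in
#' both sample size and probability; values outside the tabulated range are
#' clamped to 0.01/0.99 with a note.
#'
#' @param series Numeric vector, length >= 25, non-constant.
#' @param max_lag Maximum augmentation order (default
#'   `trunc((length(series) - 1)^(1/3))`).
#' @return List with `statistic`, `p_value`, `lag_used`.
#' @export
adf_test <- function(series, max_lag = NULL) {
  series <- as.numeric(series)
  n <- length(series)
  if (n < 25) stop("'series' too short for ADF test: need length >= 25")
  if (stats::sd(series) == 0) stop("constant series")
  if (is.null(max_lag)) max_lag <- trunc((n - 1)^(1/3))
  max_lag <- max(0L, as.integer(max_lag))

  dy <- diff(series)
  ylag <- series[-n]
  fit_k <- function(k, common_start) {
    idx <- seq.int(common_start, length(dy))
    y <- dy[idx]
    X <- cbind(1, ylag[idx])
    if (k > 0) {
      dlags <- sapply(seq_len(k), function(i) dy[idx - i])
      X <- cbind(X, dlags)
    }
    qrX <- qr(X)
    res <- qr.resid(qrX, y)
    m <- length(y)
    s2 <- sum(res^2) / (m - ncol(X))
    XtXinv <- chol2inv(qr.R(qrX))
    tstat <- qr.coef(qrX, y)[2L] / sqrt(s2 * XtXinv[2L, 2L])
    ll <- -0.5 * m * (log(2 * pi * mean(res^2)) + 1)
    list(aic = -2 * ll + 2 * (ncol(X) + 1), tstat = unname(tstat))
  }
  common_start <- max_lag + 1L
  fits <- lapply(0:max_lag, fit_k, common_start = common_start)
  k_best <- (0:max_lag)[which.min(vapply(fits, `[[`, numeric(1), "aic"))]
  # refit at the chosen order on its own maximal sample
  stat <- fit_k(k_best, common_start = k_best + 1L)$tstat

  tab <- .adf_tau_mu
  row <- vapply(seq_along(tab$probs), function(j)
    stats::approx(tab$n, tab$tbl[, j], xout = min(n, max(tab$n)), rule = 2)$y,
    numeric(1))
  p <- stats::approx(row, tab$probs, xout = stat, rule = 2)$y
  list(statistic = stat, p_value = p, lag_used = k_best)
}

#' Information criteria in the published and textbook forms
#'
#' Returns the criteria exactly as printed in the source tables
#' (`aic = -2 ll + 2T`, `sic = -2 ll + (T + T log M)`,
#' `hqc = -2 ll + 2 (T + T log M)`, with `T` the parameter count and `M`
#' the number of observations), their per-observation variants (raw / M,
#' the scale on which the published tables report them), and the textbook
#' variants (`bic = -2 ll + T log M`, `hqc_std = -2 ll + 2T log log M`).
#'
#' @param loglik Log-likelihood of the fitted model.
#' @param n_params Parameter count `T` (>= 0).
#' @param n_obs Observation count `M` (> n_params).
#' @return List with `raw` (aic, sic, hqc), `per_obs` (same names, divided
#'   by `n_obs`) and `textbook` (aic, bic, hqc).
#' @export
information_criteria <- function(loglik, n_params, n_obs) {
  if (n_params < 0 || n_obs <= n_params) stop("need n_obs > n_params >= 0")
  T_ <- n_params; M <- n_obs
  raw <- list(aic = -2 * loglik + 2 * T_,
              sic = -2 * loglik + (T_ + T_ * log(M)),
              hqc = -2 * loglik + 2 * (T_ + T_ * log(M)))
  textbook <- list(aic = raw$aic,
                   bic = -2 * loglik + T_ * log(M),
                   hqc = -2 * loglik + 2 * T_ * log(log(M)))
  list(raw = raw,
       per_obs = lapply(raw, function(v) v / M),
       textbook = textbook)
}

#' Full diagnostics report for one series
#'
#' Convenience wrapper assembling the descriptive and test battery used in
#' the per-session normality/model tables: location/spread, skewness,
#' kurtosis, Jarque-Bera, and (when `residuals` are supplied)
#' Durbin-Watson, ARCH-LM, Ljung-Box on squared residuals and the
#' information criteria of the associated fit.
#'
#' @param series Numeric series.
#' @param residuals Optional model residuals for the serial-correlation and
#'   heteroskedasticity tests.
#' @param loglik,n_params Optional fit information for the criteria.
#' @param arch_lags Lag order for ARCH-LM / Ljung-Box (default 5).
#' @param adf Run the augmented Dickey-Fuller test (default `FALSE`; needs
#'   length >= 25).
#' @return A list of class `"diagnostics_report"`.
#' @export
diagnose_series <- function(series, residuals = NULL, loglik = NULL,
                            n_params = NULL, arch_lags = 5, adf = FALSE) {
  jb <- jarque_bera(series)
  rep_ <- list(
    n = length(series), mean = mean(series),
    median = stats::median(series), sd = stats::sd(series),
    skewness = jb$skewness, kurtosis = jb$kurtosis,
    jarque_bera = jb[c("statistic", "p_value")])
  if (!is.null(residuals)) {
    rep_$durbin_watson <- durbin_watson(residuals)
    rep_$arch_lm <- arch_lm_test(residuals, arch_lags)
    rep_$ljung_box_sq <- ljung_box_squared(residuals, arch_lags)
  }
  if (adf) rep_$adf <- adf_test(series)
  if (!is.null(loglik) && !is.null(n_params))
    rep_$criteria <- information_criteria(loglik, n_params, length(series))
  class(rep_) <- "diagnostics_report"
  rep_
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat(sprintf("n=%d mean=%.4g median=%.4g sd=%.4g skew=%.3f kurt=%.3f JB=%.3f (p=%.3g)\n",
              x$n, x$mean, x$median, x$sd, x$skewness, x$kurtosis,
              x$jarque_bera$statistic, x$jarque_bera$p_value))
  if (!is.null(x$durbin_watson))
    cat(sprintf("DW=%.3f (%s)  ARCH-LM=%.3f (p=%.3g)  LB(sq)=%.3f (p=%.3g)\n",
                x$durbin_watson$statistic, x$durbin_watson$interpretation,
                x$arch_lm$statistic, x$arch_lm$p_value,
                x$ljung_box_sq$statistic, x$ljung_box_sq$p_value))
  invisible(x)
}
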