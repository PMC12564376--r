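test_that("skewness and kurtosis use the (m-1) moment-ratio convention", {
  expect_equal(skewness(c(-1, 0, 1)), 0)
  z <- rnorm(200)
  expect_equal(skewness(z), -skewness(-z))

  # hand-computed oracle for a small fixed series
  x <- c(1, 2, 3, 4, 10)
  s <- sd(x); m <- length(x); xb <- mean(x)
  expect_equal(skewness(x), sum((x - xb)^3) / ((m - 1) * s^3))
  expect_equal(kurtosis(x), sum((x - xb)^4) / ((m - 1) * s^4))

  # large-sample Gaussian kurtosis approaches the normal reference 3
  set.seed(1)
  expect_equal(kurtosis(rnorm(1e5)), 3, tolerance = 0.1)

  expect_error(skewness(rep(2, 10)), "constant")
  expect_error(kurtosis(c(1, 2)), "length")
})

test_that("Jarque-Bera follows the printed formula and is affine-invariant", {
  # n = 55, skewness 0.34, kurtosis 2.08 give a statistic of about 3.00
  expect_equal(55 * 0.34^2 / 6 + 55 * (2.08 - 3)^2 / 24, 3.00,
               tolerance = 0.001)
  set.seed(2)
  z <- rnorm(300)
  jb <- jarque_bera(z)
  expect_equal(jb$statistic,
               300 * jb$skewness^2 / 6 + 300 * (jb$kurtosis - 3)^2 / 24)
  expect_gte(jb$statistic, 0)
  # invariance under affine transforms aZ + b, a != 0
  expect_equal(jarque_bera(-3.2 * z + 7)$statistic, jb$statistic)
  expect_equal(jarque_bera(0.001 * z)$statistic, jb$statistic,
               tolerance = 1e-8)
})

test_that("Durbin-Watson hits its closed-form extremes and stays in [0, 4]", {
  expect_equal(durbin_watson(c(1, 1, 1, 1))$statistic, 0)
  alt <- rep(c(1, -1), 500)
  expect_gt(durbin_watson(alt)$statistic, 3.9)
  set.seed(3)
  expect_equal(durbin_watson(rnorm(10000))$statistic, 2, tolerance = 0.05)
  for (i in 1:20) {
    d <- durbin_watson(rnorm(50))$statistic
    expect_gte(d, 0); expect_lte(d, 4)
  }
  expect_error(durbin_watson(rep(0, 10)), "zero")
})

test_that("ARCH-LM detects conditional heteroskedasticity and rejects degenerate input", {
  set.seed(4)
  # power: GARCH innovations with persistence 0.9 are flagged
  rejections <- sum(replicate(10, {
    tau <- simulate_ar_garch(1000, delta = 0.1, beta = 0.25,
                             gamma = 0.65)$innovations
    arch_lm_test(tau, 5)$p_value <= 0.05
  }))
  expect_gte(rejections, 8)
  expect_error(arch_lm_test(rnorm(6), 5), "too short")
  expect_error(arch_lm_test(rep(1, 100), 2), "degenerate")
})

test_that("Ljung-Box on squared residuals flags volatility clustering", {
  set.seed(5)
  tau <- simulate_ar_garch(1000, delta = 0.1, beta = 0.25,
                           gamma = 0.65)$innovations
  expect_lt(ljung_box_squared(tau, 5)$p_value, 0.05)
  expect_error(ljung_box_squared(rnorm(100), 0), "lags")
})

test_that("ADF test separates random walks from mean-reverting series", {
  set.seed(6)
  rw_keep <- sum(replicate(15, adf_test(cumsum(rnorm(500)))$p_value > 0.05))
  expect_gte(rw_keep, 12)
  mr_reject <- sum(replicate(15, {
    z <- as.numeric(arima.sim(list(ar = 0.2), 500))
    adf_test(z)$p_value <= 0.05
  }))
  expect_gte(mr_reject, 13)
  expect_error(adf_test(rnorm(10)), "too short")
  expect_error(adf_test(rep(1, 100)), "constant")
})

test_that("information criteria: printed forms, per-observation scale, ordering invariance", {
  expect_equal(information_criteria(0, 0, 10)$raw$aic, 0)
  expect_equal(information_criteria(-100, 3, 50)$raw$aic, 206)
  ic <- information_criteria(-143.43, 3, 55)
  expect_equal(ic$per_obs$aic, 5.3, tolerance = 0.02)
  expect_equal(ic$raw$sic, -2 * -143.43 + (3 + 3 * log(55)))
  expect_equal(ic$textbook$bic, -2 * -143.43 + 3 * log(55))
  # per-observation scaling preserves the raw AIC ordering of nested fits
  ic1 <- information_criteria(-120, 2, 55)
  ic2 <- information_criteria(-118, 4, 55)
  expect_identical(ic1$raw$aic < ic2$raw$aic,
                   ic1$per_obs$aic < ic2$per_obs$aic)
  expect_error(information_criteria(-10, 5, 5), "n_obs")
})

test_that("diagnose_series assembles the full battery", {
  set.seed(7)
  x <- rnorm(120)
  fit <- fit_ar(x, 1)
  rep_ <- diagnose_series(x, residuals = fit$residuals,
                          loglik = fit$loglik, n_params = 3, adf = TRUE)
  expect_s3_class(rep_, "diagnostics_report")
  expect_named(rep_$jarque_bera, c("statistic", "p_value"))
  expect_true(rep_$durbin_watson$statistic >= 0 &&
              rep_$durbin_watson$statistic <= 4)
  expect_true(is.finite(rep_$adf$statistic))
  expect_equal(rep_$criteria$raw$aic, -2 * fit$loglik + 6)
})
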