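test_that("fit_ar recovers AR coefficients and handles degenerate orders", {
  set.seed(11)
  sim <- simulate_ar_garch(5000, ar_coeffs = 0.7, delta = 0.01,
                           beta = 0, gamma = 0)
  fit <- fit_ar(sim$series, 1)
  expect_equal(unname(fit$coeffs), 0.7, tolerance = 0.03)
  expect_length(fit$residuals, 5000 - 1)

  # p = 0: intercept is the sample mean, residuals the demeaned series
  x <- rnorm(50)
  f0 <- fit_ar(x, 0)
  expect_equal(f0$intercept, mean(x))
  expect_equal(f0$residuals, x - mean(x))

  # exact noiseless AR(1) recursion is recovered to machine precision
  z <- numeric(60); z[1] <- 1
  for (t in 2:60) z[t] <- 0.5 * z[t - 1]
  expect_equal(unname(fit_ar(z, 1)$coeffs), 0.5, tolerance = 1e-10)

  expect_error(fit_ar(rnorm(5), 4), "too short")
  expect_error(fit_ar(rep(3, 100), 1), "singular|constant")
})

test_that("order selection by BIC prefers the generating order", {
  set.seed(21)
  wn_hits <- sum(replicate(15, select_ar_order(rnorm(1000), 5, "bic") == 0L))
  expect_gt(wn_hits, 15 / 2)
  ar_hits <- sum(replicate(15, {
    z <- as.numeric(arima.sim(list(ar = 0.8), 1000))
    select_ar_order(z, 5, "bic") == 1L
  }))
  expect_gt(ar_hits, 15 / 2)
  # too-short series: range reduced with a warning, never an error
  expect_warning(p <- select_ar_order(rnorm(20), 15), "reduced")
  expect_lte(p, 8)
})

test_that("conditional variance recursion matches closed forms", {
  # direct substitution: sigma1^2 = 0.5 + 0.2*1 + 0.3*1 = 1
  path <- conditional_variance_path(0.5, 0.2, 0.3, rep(0, 4),
                                    sigma2_init = 1, tau2_init = 1)
  expect_equal(path[1], 1.0)
  # beta = gamma = 0: path constant at delta
  expect_equal(conditional_variance_path(0.7, 0, 0, rnorm(10)), rep(0.7, 10))
  # after a single spike with zero subsequent residuals the recursion is
  # sigma2_{t+1} = delta + gamma sigma2_t, so the deviation from its fixed
  # point delta/(1 - gamma) decays geometrically at rate gamma
  res <- c(rep(0, 5), 10, rep(0, 20))
  p2 <- conditional_variance_path(0.1, 0.3, 0.6, res)
  fp <- 0.1 / (1 - 0.6)
  dev <- p2[8:17] - fp
  expect_equal(dev[-1] / dev[-length(dev)], rep(0.6, length(dev) - 1),
               tolerance = 1e-8)
  expect_error(conditional_variance_path(-1, 0.1, 0.1, rnorm(5)), "delta")
})

test_that("AR-GARCH QMLE is deterministic, nests the constant-variance model, and flags degeneracy", {
  set.seed(31)
  sim <- simulate_ar_garch(800, mean_level = 100, ar_coeffs = 0.5,
                           delta = 0.1, beta = 0.1, gamma = 0.8)
  f1 <- fit_ar_garch(sim$series, p = 1)
  f2 <- fit_ar_garch(sim$series, p = 1)
  expect_identical(f1[c("delta", "beta", "gamma", "loglik")],
                   f2[c("delta", "beta", "gamma", "loglik")])
  expect_true(all(f1$cond_var_path > 0))
  expect_equal(f1$std_resid, f1$ar$residuals / sqrt(f1$cond_var_path))
  expect_gte(f1$loglik, f1$loglik_const_var)

  # homoskedastic input: delta near the residual variance, beta/gamma near 0
  set.seed(32)
  x <- 50 + rnorm(600)
  fh <- fit_ar_garch(x, p = 0)
  expect_equal(fh$delta / (1 - fh$beta - fh$gamma), mean(fh$ar$residuals^2),
               tolerance = 0.1)
  # beta shrinks toward the boundary; gamma is not identified when beta = 0
  # (any delta/(1 - gamma) on the flat ridge gives the same likelihood), so
  # only the ARCH coefficient and the implied variance are pinned down
  expect_lt(fh$beta, 0.15)
  expect_gte(fh$loglik, fh$loglik_const_var)

  expect_error(fit_ar_garch(rnorm(20)), "too short")
  expect_error(fit_ar_garch(rep(1, 100)), "zero variance")
  expect_warning(fit_ar_garch(sim$series, p = 1, constrained = FALSE),
                 "unconstrained")
})

test_that("volatility summary: persistence, half-life, unconditional variance", {
  vs <- volatility_summary(-0.21, gamma = 1.12)
  expect_equal(vs$persistence, 0.91)
  expect_equal(vs$half_life_steps, log(0.5) / log(0.91))

  vs2 <- volatility_summary(0.2, gamma = 0.3, delta = 0.5)
  expect_equal(vs2$uncond_var, 1.0)

  # persistence >= 1: infinite half-life, undefined unconditional variance
  vs3 <- volatility_summary(0.5, gamma = 0.6, delta = 0.1)
  expect_identical(vs3$half_life_steps, Inf)
  expect_true(is.na(vs3$uncond_var))
  # persistence <= 0: half-life not applicable, reported as NA not an error
  expect_true(is.na(volatility_summary(0, gamma = 0)$half_life_steps))

  # half-life is monotone increasing in persistence on (0, 1)
  rho <- seq(0.05, 0.95, by = 0.05)
  hl <- vapply(rho, function(r) volatility_summary(r, gamma = 0)$half_life_steps,
               numeric(1))
  expect_true(all(diff(hl) > 0))
})

test_that("fit objects serialize to JSON with persistence metadata", {
  set.seed(41)
  f <- fit_ar_garch(simulate_ar_garch(300, delta = 0.2, beta = 0.1,
                                      gamma = 0.7)$series, p = 0)
  js <- jsonlite::fromJSON(ar_garch_to_json(f))
  expect_equal(js$persistence, f$beta + f$gamma)
  expect_equal(js$variance_model$delta, f$delta)
})
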