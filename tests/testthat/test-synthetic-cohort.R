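test_that("simulated GARCH innovations reproduce the closed-form unconditional variance", {
  sim <- simulate_ar_garch(50000, delta = 0.1, beta = 0.1, gamma = 0.8,
                           seed = 101)
  target <- 0.1 / (1 - 0.1 - 0.8)  # = 1
  # 3 Monte-Carlo standard errors; GARCH(1,1) squared innovations are
  # autocorrelated so the SE of the variance estimate is inflated relative
  # to iid sampling
  mc_se <- sd(sim$innovations^2) / sqrt(50000) *
    sqrt((1 + 0.9) / (1 - 0.9))
  expect_equal(var(sim$innovations), target, tolerance = 3 * mc_se)
  expect_error(simulate_ar_garch(100, beta = 0.5, gamma = 0.6),
               "non-stationary")
})

test_that("session traces are deterministic, baselined, and degenerate correctly", {
  p <- trace_gen_params(seed = 7)
  t1 <- generate_session_trace(p)
  t2 <- generate_session_trace(trace_gen_params(seed = 7))
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 600)
  expect_equal(sum(t1$scene == "baseline"), 120)
  # baseline sits at resting levels well below the exposure mean
  expect_lt(mean(t1$hr_bpm[t1$scene == "baseline"]), 90)
  # session-1 default exposure heart rate tracks the cohort target
  expect_equal(mean(t1$hr_bpm[t1$scene == "exposure"]), 118.31,
               tolerance = 0.05 * 118.31)

  # zero-variance degenerate case: no innovations, no AR memory -> constant
  pz <- trace_gen_params(ar_coeffs = numeric(0), garch_delta = 0.5,
                         garch_beta = 0, garch_gamma = 0,
                         innovation = "none", seed = 1)
  tz <- generate_session_trace(pz)
  expo <- tz$hr_bpm[tz$scene == "exposure"]
  expect_true(all(expo == expo[1]))
  expect_equal(expo[1], 118.31)

  expect_error(trace_gen_params(garch_beta = 0.5, garch_gamma = 0.6),
               "non-stationary")
  expect_error(trace_gen_params(duration_s = 100), "too short")
})

test_that("cohort generation honours strata, targets, and monotone session trends", {
  coh <- generate_cohort(cohort_config(seed = 5))
  expect_equal(nrow(coh$sessions), 55 * 7)
  expect_equal(unname(table(coh$participants$stratum)[c("high", "moderate", "low_moderate")]),
               c(18L, 24L, 13L), ignore_attr = TRUE)

  # SDs -> 0 pins the session means to their targets exactly
  tg <- session_mean_targets()
  tg[paste0(c("time", "hm", "hr"), "_sd")] <- 0
  coh0 <- generate_cohort(cohort_config(session_targets = tg, seed = 1))
  s1 <- coh0$sessions[coh0$sessions$session == 1, ]
  expect_identical(mean(s1$time_s), 56.56)

  # with tight SDs the configured directions are monotone: time rises,
  # head movement and heart rate fall across sessions
  tg2 <- session_mean_targets()
  tg2[paste0(c("time", "hm", "hr"), "_sd")] <- 0.01
  coh2 <- generate_cohort(cohort_config(session_targets = tg2, seed = 2))
  bym <- aggregate(cbind(time_s, head_move, hr_bpm) ~ session, coh2$sessions, mean)
  expect_true(all(diff(bym$time_s) > 0))
  expect_true(all(diff(bym$head_move) < 0))
  expect_true(all(diff(bym$hr_bpm) < 0))

  expect_error(cohort_config(n_participants = 50), "do not sum")
  # single participant, single stratum
  st <- data.frame(label = "moderate", n = 1L, pre_mean = 60, pre_sd = 0,
                   post_mean = 40, post_sd = 0)
  one <- generate_cohort(cohort_config(n_participants = 1, strata = st, seed = 3))
  expect_equal(nrow(one$participants), 1)
  expect_equal(one$participants$fsq_pre, 60)
})

test_that("questionnaire responses follow their profile and determinism contracts", {
  calm <- generate_psq_responses(40, "calm", seed = 9)
  expect_true(mean(unlist(calm[c("AV1", "AV2", "AV3")])) < 2.5)
  expect_true(mean(unlist(calm[c("C1", "C2", "C3")])) > 5.5)
  expect_true(all(calm$A1 >= 0 & calm$A1 <= 100))
  expect_true(all(unlist(calm[c("T1", "T2", "T3", "R1")]) %in% 1:7))

  r1 <- generate_psq_responses(20, "random", seed = 3)
  r2 <- generate_psq_responses(20, "random", seed = 3)
  expect_identical(r1, r2)

  empty <- generate_psq_responses(0, "calm")
  expect_equal(nrow(empty), 0)
  expect_equal(ncol(empty), 16)  # 15 scale items + adverse-event flag
  expect_error(generate_psq_responses(5, "agitated"), "arg")
})

test_that("trace CSV round-trips with its baseline marker", {
  tr <- generate_session_trace(trace_gen_params(seed = 4, duration_s = 200))
  f <- tempfile(fileext = ".csv")
  write_trace_csv(tr, f)
  back <- read_trace_csv(f)
  expect_equal(back$hr_bpm, tr$hr_bpm)
  expect_equal(attr(back, "baseline_s"), 120)
  unlink(f)
})
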