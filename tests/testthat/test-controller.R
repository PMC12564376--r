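test_that("baselined z series behave as constructed", {
  cfg <- controller_config()
  # constant heart rate at the baseline mean gives z near 0 throughout
  tr <- make_trace(rep(72, 300), seed = 5)
  z <- baseline_hr_z(tr, cfg)
  expect_lt(max(abs(tail(z, 150))), 1)

  # a sustained shift of +2 baseline SDs settles near z = +2
  base_sm <- zoo::rollapplyr(tr$hr_bpm[1:120], 5, median, partial = TRUE)
  shift <- rep(mean(base_sm) + 2 * sd(base_sm), 300)
  z2 <- baseline_hr_z(make_trace(shift, seed = 5), cfg)
  expect_equal(mean(tail(z2, 100)), 2, tolerance = 0.2)

  # a single 1-s spike is attenuated by the 5-s median below its raw z
  spike <- rep(72, 300); spike[150] <- 110
  z3 <- baseline_hr_z(make_trace(spike, seed = 5), cfg)
  raw_z <- (110 - mean(base_sm)) / sd(base_sm)
  expect_lt(max(z3[260:280]), raw_z / 2)

  expect_error(baseline_hr_z(make_trace(rep(72, 300), n_base = 30)), "baseline")
  flat <- make_trace(rep(72, 300)); flat$hr_bpm[1:120] <- 70
  expect_error(baseline_hr_z(flat), "zero baseline SD")

  # head-movement variability: constant velocity is a degenerate baseline
  cv <- make_trace(rep(72, 300)); cv$head_vel_dps <- 5
  expect_error(hmv_z(cv), "zero variability")
  # variability doubling mid-session drives a sustained positive z
  set.seed(6)
  hv <- c(rnorm(180, 8, 1.2), rnorm(120, 8, 4))
  zh <- hmv_z(make_trace(rep(72, 300), hv_expo = hv, seed = 6), cfg)
  expect_gt(mean(tail(zh, 80)), 1)
})

test_that("quiescent session steps up once at the five-minute mark", {
  log <- run_session(make_trace(calm_hr(360)))
  expect_equal(log$n_triggers, 0)
  expect_equal(event_times(log, "step_up"), 300)
  expect_equal(log$final_difficulty, 2)
})

test_that("a sustained heart-rate excursion fires one trigger with a 30-s prompt", {
  hr <- calm_hr(360, excursions = 100)
  log <- run_session(make_trace(hr))
  expect_equal(log$n_triggers, 1)
  tt <- event_times(log, "trigger")
  expect_true(tt >= 108 && tt <= 111)
  expect_equal(event_times(log, "prompt_end") - event_times(log, "prompt_start"), 30)
  expect_equal(log$events$detail[log$events$kind == "trigger"], "hr")
})

test_that("three triggers inside the window impose a hold and suppress step-ups", {
  hr <- calm_hr(420, excursions = c(50, 140, 240))
  log <- run_session(make_trace(hr))
  expect_equal(log$n_triggers, 3)
  ht <- event_times(log, "hold")
  expect_equal(ht, max(event_times(log, "trigger")))
  expect_equal(sum(log$events$kind == "step_up"), 0)
  expect_equal(log$final_difficulty, 1)
})

test_that("breaching the hard ceiling switches scenes immediately and exits after recovery", {
  hr <- calm_hr(360); hr[80:85] <- 125
  log <- run_session(make_trace(hr))
  expect_equal(event_times(log, "relax_scene_enter"), 80)
  ex <- event_times(log, "relax_scene_exit")
  expect_true(length(ex) == 1 && ex > 80 + 30)
})

test_that("controller replay is deterministic and self-consistent", {
  hr <- calm_hr(400, excursions = c(90, 200))
  tr <- make_trace(hr)
  l1 <- run_session(tr)
  l2 <- run_session(tr)
  expect_identical(l1, l2)
  # final difficulty is reproduced by counting step-ups from the start level
  expect_equal(l1$final_difficulty,
               tr$difficulty[121] + sum(l1$events$kind == "step_up"))
  # prompts strictly alternate and no step_up falls inside a prompt
  ev <- l1$events
  starts <- ev$t_s[ev$kind == "prompt_start"]
  ends <- ev$t_s[ev$kind == "prompt_end"]
  expect_equal(length(starts), length(ends))
  expect_true(all(ends > starts))
  for (su in ev$t_s[ev$kind == "step_up"])
    expect_false(any(su > starts & su < ends))

  bad <- tr; bad$t_s[10] <- bad$t_s[12]
  expect_error(run_session(bad), "non-monotone")
})

test_that("lowering the heart-rate threshold never reduces the trigger count", {
  for (s in 1:4) {
    set.seed(100 + s)
    hr <- 72 + as.numeric(arima.sim(list(ar = 0.8), 400, sd = 1.5))
    tr <- make_trace(hr, seed = 200 + s)
    n_hi <- run_session(tr, controller_config(hr_z_threshold = 1.5))$n_triggers
    n_lo <- run_session(tr, controller_config(hr_z_threshold = 0.75))$n_triggers
    expect_gte(n_lo, n_hi)
  }
})

test_that("controller logs export to CSV", {
  log <- run_session(make_trace(calm_hr(360, excursions = 100)))
  f <- tempfile(fileext = ".csv")
  write_controller_log(log, f)
  back <- utils::read.csv(f)
  expect_named(back, c("t_s", "event", "detail"))
  expect_equal(nrow(back), nrow(log$events))
  unlink(f)
})
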