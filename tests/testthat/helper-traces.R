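# Crafted session traces for controller tests: 120-s resting baseline
# followed by an exposure-phase heart-rate profile supplied by the caller.
# Exposure head velocity is kept quieter than baseline so head-movement
# triggers stay silent unless a test injects them.
make_trace <- function(hr_expo, hv_expo = NULL, n_base = 120, seed = 99) {
  set.seed(seed)
  n <- length(hr_expo)
  if (is.null(hv_expo)) hv_expo <- 8 + stats::rnorm(n, sd = 0.4)
  tr <- data.frame(
    t_s = seq_len(n_base + n),
    hr_bpm = c(72 + stats::rnorm(n_base, sd = 1.5), hr_expo),
    head_vel_dps = c(pmax(0, 8 + stats::rnorm(n_base, sd = 1.2)),
                     pmax(0, hv_expo)),
    scene = rep(c("baseline", "exposure"), c(n_base, n)),
    difficulty = rep(c(0L, 1L), c(n_base, n)))
  attr(tr, "baseline_s") <- n_base
  class(tr) <- c("session_trace", "data.frame")
  tr
}

# a calm exposure heart-rate profile with an optional set of sustained
# excursions (each strong enough to fire the 10-s heart-rate rule)
calm_hr <- function(n, excursions = integer(0), width = 12, level = 90,
                    seed = 1) {
  set.seed(seed)
  hr <- 72 + stats::rnorm(n, sd = 0.5)
  for (t0 in excursions) hr[t0:min(n, t0 + width - 1L)] <- level
  hr
}

event_times <- function(log, kind) log$events$t_s[log$events$kind == kind]
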