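#' Simulate an AR(p) series with GARCH(1,1) innovations
#'
#' Draws \eqn{\tau_t = \sigma_t \epsilon_t} with
#' \eqn{\sigma^2_t = \delta + \beta \tau^2_{t-1} + \gamma \sigma^2_{t-1}} and
#' feeds the innovations through the AR recursion
#' \eqn{Z_t = c + \sum_i \alpha_i Z_{t-i} + \tau_t}, where the intercept `c`
#' is chosen so the process mean equals `mean_level`. The conditional
#' variance starts at the unconditional variance
#' \eqn{\delta/(1-\beta-\gamma)}; the first `max(p, 1)` mean-model values are
#' initialised at the series mean. Uses the session R RNG: call `set.seed()`
#' (or pass `seed`) for reproducibility.
#'
#' @param n Number of samples returned (after burn-in).
#' @param mean_level Long-run mean of the series.
#' @param ar_coeffs Numeric vector of AR coefficients (may be empty).
#' @param delta,beta,gamma GARCH(1,1) parameters; `beta + gamma < 1` required
#'   unless `stationary = FALSE`.
#' @param innovation One of `"gaussian"` (default), `"t"` (scaled Student t
#'   with `t_df` degrees of freedom, unit variance, for heavy-tailed
#'   experiments), or `"none"` (all innovations zero: degenerate,
#'   deterministic output).
#' @param t_df Degrees of freedom for `innovation = "t"` (must be > 2).
#' @param burn_in Samples discarded from the start (default 200).
#' @param stationary Require `beta + gamma < 1` (default `TRUE`).
#' @param seed Optional integer; if supplied, `set.seed(seed)` is called.
#' @return List with numeric vectors `series`, `innovations`, `cond_var`
#'   (each length `n`).
#' @export
simulate_ar_garch <- function(n, mean_level = 0, ar_coeffs = numeric(0),
                              delta = 0.1, beta = 0.1, gamma = 0.8,
                              innovation = c("gaussian", "t", "none"),
                              t_df = 7, burn_in = 200,
                              stationary = TRUE, seed = NULL) {
  innovation <- match.arg(innovation)
  if (n < 1) stop("'n' must be positive")
  if (delta < 0 || beta < 0 || gamma < 0) stop("GARCH parameters must be non-negative")
  if (stationary && beta + gamma >= 1)
    stop("non-stationary variance equation: beta + gamma = ", beta + gamma,
         " >= 1 (set stationary = FALSE to allow)")
  if (!is.null(seed)) set.seed(seed)
  p <- length(ar_coeffs)
  ntot <- n + burn_in
  eps <- switch(innovation,
    gaussian = stats::rnorm(ntot),
    t = stats::rt(ntot, df = t_df) / sqrt(t_df / (t_df - 2)),
    none = rep(0, ntot))
  uncond <- if (beta + gamma < 1) delta / (1 - beta - gamma) else delta
  sig2 <- numeric(ntot)
  tau <- numeric(ntot)
  s2 <- uncond
  for (t in seq_len(ntot)) {
    sig2[t] <- s2
    tau[t] <- sqrt(s2) * eps[t]
    s2 <- delta + beta * tau[t]^2 + gamma * s2
  }
  intercept <- mean_level * (1 - sum(ar_coeffs))
  z <- if (p == 0L) mean_level + tau
       else as.numeric(stats::filter(intercept + tau, ar_coeffs,
                                     method = "recursive",
                                     init = rep(mean_level, p)))
  keep <- (burn_in + 1L):ntot
  list(series = z[keep], innovations = tau[keep], cond_var = sig2[keep])
}

#' Per-session summary targets emulating the published cohort
#'
#' Session-level target means and standard deviations for time-on-task (s),
#' head movement (deg) and heart rate (bpm) across the seven sessions, as
#' used by [generate_cohort()]. Time-on-task rises across sessions while
#' head movement and heart rate decline.
#'
#' @return A data frame with columns `session`, `time_mean`, `time_sd`,
#'   `hm_mean`, `hm_sd`, `hr_mean`, `hr_sd` (7 rows).
#' @export
session_mean_targets <- function() {
  data.frame(
    session = 1:7,
    time_mean = c(56.56, 62.53, 68.33, 74.19, 80.05, 88.27, 97.331),
    time_sd = c(3.68, 2.83, 3.44, 3.77, 4.26, 6.58, 10.32),
    hm_mean = c(171.47, 164.28, 158.04, 153.03, 145.98, 140.74, 135.93),
    hm_sd = c(5.67, 6.36, 6.03, 5.91, 6.28, 6.91, 6.14),
    hr_mean = c(118.31, 110.33, 105.05, 99.80, 94.86, 90.6, 86.62),
    hr_sd = c(6.83, 6.94, 6.95, 7.54, 9.26, 9.40, 9.26)
  )
}

#' Default fear-severity strata for the synthetic cohort
#'
#' Three baseline fear-severity strata (18 high, 24 moderate, 13
#' low-moderate participants) with pre/post questionnaire score targets.
#'
#' @return Data frame with columns `label`, `n`, `pre_mean`, `pre_sd`,
#'   `post_mean`, `post_sd`.
#' @export
fsq_strata <- function() {
  data.frame(
    label = c("high", "moderate", "low_moderate"),
    n = c(18L, 24L, 13L),
    pre_mean = c(88.2, 67.8, 44.2),
    pre_sd = c(4.5, 6.9, 3.2),
    post_mean = c(54.7, 46.2, 34.9),
    post_sd = c(6.2, 7.8, 4.1)
  )
}

#' Parameters for one synthetic session trace
#'
#' Bundles and validates the generator settings for a single
#' participant-session trace. Heart-rate and head-velocity defaults follow
#' the per-session cohort targets in [session_mean_targets()]; the variance
#' equation defaults give persistence 0.9 with unconditional innovation
#' variance 4 (bpm^2).
#'
#' @param session_index Session number 1-7.
#' @param duration_s Total trace length in seconds, including the
#'   pre-exposure baseline; at least `baseline_s + 60` samples required.
#' @param sample_hz Sampling rate (default 1 Hz).
#' @param hr_mean_bpm Exposure-phase mean heart rate; default from
#'   [session_mean_targets()] for `session_index`.
#' @param hmv_mean_dps Exposure-phase mean head-pose angular velocity
#'   (deg/s).
#' @param ar_coeffs AR mean-model coefficients for the innovations process.
#' @param garch_delta,garch_beta,garch_gamma GARCH(1,1) variance parameters.
#' @param baseline_s Pre-exposure baseline length in seconds (default 120).
#' @param innovation Innovation distribution, see [simulate_ar_garch()].
#' @param stationary Require a stationary variance equation (default `TRUE`).
#' @param seed Integer seed making the trace reproducible.
#' @return A list of class `"trace_gen_params"`.
#' @export
trace_gen_params <- function(session_index = 1, duration_s = 600, sample_hz = 1,
                             hr_mean_bpm = NULL, hmv_mean_dps = 30,
                             ar_coeffs = 0.6,
                             garch_delta = 0.4, garch_beta = 0.1,
                             garch_gamma = 0.8,
                             baseline_s = 120,
                             innovation = "gaussian",
                             stationary = TRUE, seed = 1L) {
  if (!(session_index %in% 1:7)) stop("'session_index' must be in 1..7")
  if (duration_s <= 0 || sample_hz <= 0) stop("'duration_s' and 'sample_hz' must be positive")
  if (is.null(hr_mean_bpm))
    hr_mean_bpm <- session_mean_targets()$hr_mean[session_index]
  if (hr_mean_bpm <= 0 || hmv_mean_dps <= 0) stop("signal means must be positive")
  if (garch_delta <= 0) stop("'garch_delta' must be positive")
  if (garch_beta < 0 || garch_gamma < 0) stop("'garch_beta'/'garch_gamma' must be non-negative")
  if (stationary && garch_beta + garch_gamma >= 1)
    stop("non-stationary parameter set: garch_beta + garch_gamma >= 1 ",
         "with stationary = TRUE")
  n_total <- floor(duration_s * sample_hz)
  n_base <- floor(baseline_s * sample_hz)
  if (n_total < n_base + 60)
    stop("duration too short: need at least baseline_s + 60 seconds of samples")
  structure(list(session_index = as.integer(session_index),
                 duration_s = duration_s, sample_hz = sample_hz,
                 hr_mean_bpm = hr_mean_bpm, hmv_mean_dps = hmv_mean_dps,
                 ar_coeffs = as.numeric(ar_coeffs),
                 garch_delta = garch_delta, garch_beta = garch_beta,
                 garch_gamma = garch_gamma,
                 baseline_s = baseline_s, innovation = innovation,
                 stationary = stationary, seed = as.integer(seed)),
            class = "trace_gen_params")
}

#' Generate one synthetic session trace
#'
#' Produces a per-second multimodal trace: a pre-exposure baseline segment
#' (resting heart rate around 72 bpm, low head motion) followed by an
#' exposure segment in which heart rate and head-pose velocity follow the
#' configured AR mean model with GARCH(1,1) innovations around the
#' session-level means. Deterministic for a fixed seed.
#'
#' @param params A [trace_gen_params()] object.
#' @return A data frame of class `"session_trace"` with columns `t_s`,
#'   `hr_bpm`, `head_vel_dps`, `scene` (`"baseline"`/`"exposure"`),
#'   `difficulty`; attribute `baseline_s` marks the pre-exposure segment.
#' @export
#' @examples
#' tr <- generate_session_trace(trace_gen_params(seed = 42))
#' head(tr)
generate_session_trace <- function(params) {
  if (!inherits(params, "trace_gen_params"))
    params <- do.call(trace_gen_params, params)
  set.seed(params$seed)
  hz <- params$sample_hz
  n_total <- floor(params$duration_s * hz)
  n_base <- floor(params$baseline_s * hz)
  n_expo <- n_total - n_base

  noise <- if (identical(params$innovation, "none")) "none" else "gaussian"
  base_hr <- 72 + if (noise == "none") rep(0, n_base) else stats::rnorm(n_base, sd = 1.5)
  base_hv <- pmax(0, 8 + if (noise == "none") rep(0, n_base) else stats::rnorm(n_base, sd = 1.2))

  hr_sim <- simulate_ar_garch(n_expo, mean_level = params$hr_mean_bpm,
                              ar_coeffs = params$ar_coeffs,
                              delta = params$garch_delta,
                              beta = params$garch_beta,
                              gamma = params$garch_gamma,
                              innovation = params$innovation,
                              stationary = params$stationary)
  hv_sim <- simulate_ar_garch(n_expo, mean_level = params$hmv_mean_dps,
                              ar_coeffs = params$ar_coeffs,
                              delta = 2.25 * params$garch_delta,
                              beta = params$garch_beta,
                              gamma = params$garch_gamma,
                              innovation = params$innovation,
                              stationary = params$stationary)
  tr <- data.frame(
    t_s = seq_len(n_total) / hz,
    hr_bpm = c(base_hr, hr_sim$series),
    head_vel_dps = pmax(0, c(base_hv, hv_sim$series)),
    scene = rep(c("baseline", "exposure"), c(n_base, n_expo)),
    difficulty = rep(c(0L, 1L), c(n_base, n_expo))
  )
  attr(tr, "baseline_s") <- params$baseline_s
  attr(tr, "session_index") <- params$session_index
  class(tr) <- c("session_trace", "data.frame")
  tr
}

#' Configuration for a synthetic cohort
#'
#' @param n_participants Number of participants (default 55).
#' @param n_sessions Number of sessions (default 7).
#' @param session_targets Per-session target means/SDs, layout of
#'   [session_mean_targets()]; truncated or recycled checks applied.
#' @param strata Fear-severity strata table, layout of [fsq_strata()];
#'   stratum counts must sum to `n_participants` and all SDs must be
#'   positive (zero SDs are allowed to pin values exactly).
#' @param seed Integer seed.
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_participants = 55, n_sessions = 7,
                          session_targets = session_mean_targets(),
                          strata = fsq_strata(), seed = 1L) {
  if (n_participants < 1) stop("'n_participants' must be >= 1")
  if (n_sessions < 1 || n_sessions > nrow(session_targets))
    stop("'n_sessions' must be between 1 and nrow(session_targets)")
  if (sum(strata$n) != n_participants)
    stop("stratum counts (", sum(strata$n), ") do not sum to n_participants (",
         n_participants, ")")
  sds <- c(session_targets$time_sd, session_targets$hm_sd, session_targets$hr_sd,
           strata$pre_sd, strata$post_sd)
  if (any(sds < 0)) stop("all SD targets must be non-negative")
  structure(list(n_participants = as.integer(n_participants),
                 n_sessions = as.integer(n_sessions),
                 session_targets = session_targets, strata = strata,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a synthetic cohort dataset
#'
#' Draws a participants-by-sessions table of session summaries (time-on-task
#' s, head movement, mean heart rate bpm) around the configured per-session
#' targets, plus per-participant pre/post fear-questionnaire scores by
#' severity stratum. Reproducible by seed.
#'
#' @param config A [cohort_config()] object.
#' @return A list of class `"cohort_dataset"` with data frames `sessions`
#'   (`participant`, `session`, `time_s`, `head_move`, `hr_bpm`) and
#'   `participants` (`participant`, `stratum`, `fsq_pre`, `fsq_post`).
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  set.seed(config$seed)
  np <- config$n_participants
  ns <- config$n_sessions
  tg <- config$session_targets

  sessions <- do.call(rbind, lapply(seq_len(ns), function(s) {
    data.frame(participant = seq_len(np), session = s,
               time_s = stats::rnorm(np, tg$time_mean[s], tg$time_sd[s]),
               head_move = stats::rnorm(np, tg$hm_mean[s], tg$hm_sd[s]),
               hr_bpm = stats::rnorm(np, tg$hr_mean[s], tg$hr_sd[s]))
  }))

  st <- config$strata
  stratum <- rep(st$label, st$n)
  pre <- stats::rnorm(np, rep(st$pre_mean, st$n), rep(st$pre_sd, st$n))
  post <- stats::rnorm(np, rep(st$post_mean, st$n), rep(st$post_sd, st$n))
  participants <- data.frame(participant = seq_len(np), stratum = stratum,
                             fsq_pre = pre, fsq_post = post)
  structure(list(sessions = sessions, participants = participants,
                 config = config),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat("Synthetic VRET cohort:", x$config$n_participants, "participants x",
      x$config$n_sessions, "sessions\n")
  cat("  strata:", paste(sprintf("%s (n=%d)", x$config$strata$label,
                                 x$config$strata$n), collapse = ", "), "\n")
  invisible(x)
}

#' Generate synthetic post-session questionnaire responses
#'
#' Emits the 15-item response table (two 0-100 state-anxiety items A1/A2;
#' 1-7 Likert items AV1-AV3, C1-C3, P1-P3, T1-T3, R1) plus the binary
#' adverse-event flag AE, under one of three respondent profiles.
#'
#' @param n Number of respondents (0 gives an empty table with the full
#'   header).
#' @param profile `"calm"` (low anxiety/avoidance, high control), `"anxious"`
#'   (the reverse), or `"random"` (uniform over the scales).
#' @param seed Integer seed.
#' @return Data frame with 16 columns (15 scale items + `AE`).
#' @export
generate_psq_responses <- function(n, profile = c("calm", "anxious", "random"),
                                   seed = 1L) {
  profile <- match.arg(profile)
  if (n < 0) stop("'n' must be >= 0")
  cols <- c("A1", "A2", "AV1", "AV2", "AV3", "C1", "C2", "C3",
            "P1", "P2", "P3", "T1", "T2", "T3", "R1", "AE")
  if (n == 0L) {
    out <- as.data.frame(stats::setNames(rep(list(numeric(0)), 15), cols[1:15]))
    out$AE <- character(0)
    return(out)
  }
  set.seed(seed)
  likert <- function(center, spread = 1) {
    pmin(7L, pmax(1L, as.integer(round(stats::rnorm(n, center, spread)))))
  }
  vas <- function(center, spread = 8) {
    pmin(100, pmax(0, round(stats::rnorm(n, center, spread))))
  }
  out <- switch(profile,
    calm = data.frame(
      A1 = vas(10), A2 = vas(20),
      AV1 = likert(1.3, 0.6), AV2 = likert(1.3, 0.6), AV3 = likert(1.3, 0.6),
      C1 = likert(6.6, 0.5), C2 = likert(6.6, 0.5), C3 = likert(6.4, 0.6),
      P1 = likert(6, 0.8), P2 = likert(5.5, 0.9), P3 = likert(6, 0.8),
      T1 = likert(6.5, 0.6), T2 = likert(1.4, 0.6), T3 = likert(6.5, 0.6),
      R1 = likert(6, 0.8),
      AE = rep("no", n)),
    anxious = data.frame(
      A1 = vas(70, 12), A2 = vas(85, 10),
      AV1 = likert(6, 0.8), AV2 = likert(6, 0.8), AV3 = likert(5.8, 0.9),
      C1 = likert(2.4, 0.9), C2 = likert(2.8, 0.9), C3 = likert(2.2, 0.9),
      P1 = likert(5, 1), P2 = likert(5.3, 1), P3 = likert(4, 1),
      T1 = likert(3.5, 1), T2 = likert(4.5, 1), T3 = likert(3, 1),
      R1 = likert(2.6, 1),
      AE = ifelse(stats::runif(n) < 0.15, "yes", "no")),
    random = data.frame(
      A1 = round(stats::runif(n, 0, 100)), A2 = round(stats::runif(n, 0, 100)),
      AV1 = sample(1:7, n, TRUE), AV2 = sample(1:7, n, TRUE),
      AV3 = sample(1:7, n, TRUE),
      C1 = sample(1:7, n, TRUE), C2 = sample(1:7, n, TRUE),
      C3 = sample(1:7, n, TRUE),
      P1 = sample(1:7, n, TRUE), P2 = sample(1:7, n, TRUE),
      P3 = sample(1:7, n, TRUE),
      T1 = sample(1:7, n, TRUE), T2 = sample(1:7, n, TRUE),
      T3 = sample(1:7, n, TRUE),
      R1 = sample(1:7, n, TRUE),
      AE = sample(c("yes", "no"), n, TRUE, prob = c(0.1, 0.9))))
  out
}

#' Write a session trace or cohort to delimited text
#'
#' @param x A `"session_trace"` or `"cohort_dataset"`.
#' @param path Output CSV path. For a cohort, the per-session table is
#'   written with one row per participant-session; the participants table
#'   goes to a sibling file with suffix `_participants.csv`.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(x, path) {
  if (inherits(x, "session_trace")) {
    utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  } else if (inherits(x, "cohort_dataset")) {
    utils::write.csv(x$sessions, path, row.names = FALSE)
    utils::write.csv(x$participants,
                     sub("\\.csv$", "_participants.csv", path),
                     row.names = FALSE)
  } else stop("'x' must be a session_trace or cohort_dataset")
  invisible(path)
}

#' Read a session trace from CSV
#'
#' @param path CSV with columns `t_s, hr_bpm, head_vel_dps, scene,
#'   difficulty`.
#' @param baseline_s Length of the pre-exposure segment (default: inferred
#'   from rows with `scene == "baseline"`, else 120).
#' @return A `"session_trace"` data frame.
#' @export
read_trace_csv <- function(path, baseline_s = NULL) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t_s", "hr_bpm", "head_vel_dps")
  if (!all(need %in% names(tr)))
    stop("trace CSV must contain columns: ", paste(need, collapse = ", "))
  if (is.null(baseline_s)) {
    baseline_s <- if ("scene" %in% names(tr) && any(tr$scene == "baseline"))
      max(tr$t_s[tr$scene == "baseline"]) else 120
  }
  attr(tr, "baseline_s") <- baseline_s
  class(tr) <- c("session_trace", "data.frame")
  tr
}
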