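#' Configuration of the micro-relaxation controller
#'
#' Bundles the trigger thresholds and pacing rules of the closed-loop
#' controller: a trigger fires when the z-scored heart rate stays at or
#' above `hr_z_threshold` for `hr_sustain_s` consecutive seconds, or the
#' z-scored head-movement variability stays at or above `hmv_z_threshold`
#' for `hmv_sustain_s` seconds; each trigger starts a breathing prompt of
#' `prompt_duration_s` seconds during which difficulty is held and trigger
#' evaluation is suspended. Three or more triggers
#' (`trigger_count_hold`) inside any `trigger_window_s` window sustain the
#' current difficulty for the remainder of the block; `quiescence_stepup_s`
#' seconds without a trigger step difficulty up one level. Raw heart rate
#' above `hr_hard_ceiling_bpm` switches immediately to the relaxation
#' scene, exited after the smoothed heart rate stays below the ceiling for
#' `relax_exit_s` consecutive seconds.
#'
#' @param hr_z_threshold,hmv_z_threshold Trigger thresholds on the z scale
#'   (default +1.0).
#' @param hr_sustain_s,hmv_sustain_s Required consecutive seconds at or
#'   above threshold (defaults 10 and 5).
#' @param prompt_duration_s Breathing-prompt length, seconds in \[30, 45\]
#'   (default 30).
#' @param trigger_window_s,trigger_count_hold Hold rule: window (default
#'   300 s) and trigger count (default 3).
#' @param quiescence_stepup_s Trigger-free seconds before a step-up
#'   (default 300).
#' @param hr_hard_ceiling_bpm Hard heart-rate ceiling (default 120 bpm),
#'   tested on the raw signal.
#' @param hr_smooth_window_s Rolling-median window for heart-rate smoothing
#'   (default 5 s).
#' @param hmv_window_s Rolling-SD window defining head-movement variability
#'   (default 5 s).
#' @param hmv_baseline_s Baseline window for the head-movement z score
#'   (default 120 s, the first two minutes).
#' @param relax_exit_s Consecutive below-ceiling seconds required to leave
#'   the relaxation scene (default 30).
#' @return A list of class `"controller_config"`.
#' @export
controller_config <- function(hr_z_threshold = 1.0, hr_sustain_s = 10,
                              hmv_z_threshold = 1.0, hmv_sustain_s = 5,
                              prompt_duration_s = 30,
                              trigger_window_s = 300, trigger_count_hold = 3,
                              quiescence_stepup_s = 300,
                              hr_hard_ceiling_bpm = 120,
                              hr_smooth_window_s = 5, hmv_window_s = 5,
                              hmv_baseline_s = 120, relax_exit_s = 30) {
  durs <- c(hr_sustain_s, hmv_sustain_s, prompt_duration_s, trigger_window_s,
            quiescence_stepup_s, hr_smooth_window_s, hmv_window_s,
            hmv_baseline_s, relax_exit_s)
  if (any(durs <= 0)) stop("all durations must be positive")
  if (prompt_duration_s < 30 || prompt_duration_s > 45)
    stop("'prompt_duration_s' must lie in [30, 45]")
  if (trigger_count_hold < 1) stop("'trigger_count_hold' must be >= 1")
  structure(list(hr_z_threshold = hr_z_threshold, hr_sustain_s = hr_sustain_s,
                 hmv_z_threshold = hmv_z_threshold, hmv_sustain_s = hmv_sustain_s,
                 prompt_duration_s = prompt_duration_s,
                 trigger_window_s = trigger_window_s,
                 trigger_count_hold = trigger_count_hold,
                 quiescence_stepup_s = quiescence_stepup_s,
                 hr_hard_ceiling_bpm = hr_hard_ceiling_bpm,
                 hr_smooth_window_s = hr_smooth_window_s,
                 hmv_window_s = hmv_window_s, hmv_baseline_s = hmv_baseline_s,
                 relax_exit_s = relax_exit_s),
            class = "controller_config")
}

## trailing rolling window; the first (k-1) samples reuse the partial window
.roll_trailing <- function(x, k, fun) {
  zoo::rollapplyr(x, width = k, FUN = fun, partial = TRUE)
}

.trace_baseline_n <- function(trace, default = 120) {
  b <- attr(trace, "baseline_s")
  if (is.null(b)) b <- default
  sum(trace$t_s <= b)
}

#' Baseline-standardised heart-rate series
#'
#' 5-second (trailing) rolling median of heart rate, z-scored against the
#' mean and SD of the smoothed signal over the pre-exposure baseline
#' segment. Length is preserved; the first `window - 1` samples use the
#' partial trailing window.
#'
#' @param trace A `"session_trace"` (needs >= 60 s of pre-exposure
#'   baseline).
#' @param config A [controller_config()].
#' @return Numeric vector of z scores, same length as the trace.
#' @export
baseline_hr_z <- function(trace, config = controller_config()) {
  nb <- .trace_baseline_n(trace)
  if (nb < 60) stop("trace needs a pre-exposure baseline segment of >= 60 s")
  sm <- .roll_trailing(trace$hr_bpm, config$hr_smooth_window_s, stats::median)
  mu <- mean(sm[seq_len(nb)])
  sdv <- stats::sd(sm[seq_len(nb)])
  if (sdv == 0) stop("zero baseline SD: heart rate constant over the baseline segment")
  (sm - mu) / sdv
}

#' Baseline-standardised head-movement-variability series
#'
#' Head-movement variability (HMV) is the 5-second trailing rolling SD of
#' head-pose angular velocity; it is z-scored against the distribution of
#' that statistic over the first two minutes of the trace.
#'
#' @inheritParams baseline_hr_z
#' @return Numeric vector of z scores, same length as the trace.
#' @export
hmv_z <- function(trace, config = controller_config()) {
  if (nrow(trace) < config$hmv_baseline_s)
    stop("trace shorter than the head-movement baseline window")
  hmv <- .roll_trailing(trace$head_vel_dps, config$hmv_window_s,
                        function(w) if (length(w) < 2) 0 else stats::sd(w))
  base <- hmv[seq_len(config$hmv_baseline_s)]
  mu <- mean(base); sdv <- stats::sd(base)
  if (sdv == 0) stop("zero variability over the head-movement baseline window")
  (hmv - mu) / sdv
}

#' Replay the adaptive controller over a session trace
#'
#' Deterministic per-second evaluation of the micro-relaxation rule over
#' the exposure segment of a trace (everything after the pre-exposure
#' baseline). Event times in the log are seconds since exposure onset.
#'
#' Semantics: sustain counters reset when the z series drops below
#' threshold; trigger evaluation is suspended during an active prompt and
#' inside the relaxation scene (the quiescence clock also pauses there);
#' simultaneous heart-rate and head-movement triggers log as one trigger
#' with both causes; a hold lasts for the remainder of the block; step-ups
#' never occur during a prompt or while a hold is in force.
#'
#' @param trace A `"session_trace"` with strictly increasing integer-second
#'   timestamps.
#' @param config A [controller_config()].
#' @return An object of class `"controller_log"`: list with `events` (data
#'   frame `t_s`, `kind`, `detail`), `final_difficulty`, `n_triggers`.
#' @export
run_session <- function(trace, config = controller_config()) {
  if (is.unsorted(trace$t_s, strictly = TRUE))
    stop("non-monotone timestamps in trace")
  nb <- .trace_baseline_n(trace)
  hrz <- baseline_hr_z(trace, config)
  hvz <- hmv_z(trace, config)
  n <- nrow(trace)
  expo <- (nb + 1L):n

  ev_t <- numeric(0); ev_kind <- character(0); ev_detail <- character(0)
  log_event <- function(t, kind, detail = "") {
    ev_t <<- c(ev_t, t); ev_kind <<- c(ev_kind, kind); ev_detail <<- c(ev_detail, detail)
  }

  hr_run <- 0L; hmv_run <- 0L
  prompt_until <- -Inf          # local time at which the active prompt ends
  hold_active <- FALSE
  trigger_times <- numeric(0)
  quiesce_anchor <- 0
  difficulty <- if (length(expo)) trace$difficulty[expo[1L]] else 0L
  in_relax <- FALSE; relax_ok <- 0L
  hr_smooth <- .roll_trailing(trace$hr_bpm, config$hr_smooth_window_s, stats::median)

  for (i in expo) {
    t <- trace$t_s[i] - trace$t_s[nb]   # seconds since exposure onset

    # hard heart-rate ceiling: immediate relaxation-scene switch on raw HR
    if (!in_relax && trace$hr_bpm[i] > config$hr_hard_ceiling_bpm) {
      log_event(t, "relax_scene_enter",
                sprintf("hr=%.1f>%g", trace$hr_bpm[i], config$hr_hard_ceiling_bpm))
      in_relax <- TRUE; relax_ok <- 0L
      hr_run <- 0L; hmv_run <- 0L
    }
    if (in_relax) {
      relax_ok <- if (hr_smooth[i] < config$hr_hard_ceiling_bpm) relax_ok + 1L else 0L
      if (relax_ok >= config$relax_exit_s) {
        log_event(t, "relax_scene_exit", sprintf("smoothed hr < ceiling for %ds", relax_ok))
        in_relax <- FALSE
      }
      quiesce_anchor <- quiesce_anchor + 1  # quiescence clock pauses in relaxation
      next
    }

    in_prompt <- t < prompt_until
    if (!in_prompt && is.finite(prompt_until) && t >= prompt_until) {
      log_event(prompt_until, "prompt_end", "")
      prompt_until <- -Inf
    }

    if (!in_prompt) {
      hr_run <- if (hrz[i] >= config$hr_z_threshold) hr_run + 1L else 0L
      hmv_run <- if (hvz[i] >= config$hmv_z_threshold) hmv_run + 1L else 0L
      hr_fire <- hr_run >= config$hr_sustain_s
      hmv_fire <- hmv_run >= config$hmv_sustain_s
      if (hr_fire || hmv_fire) {
        cause <- if (hr_fire && hmv_fire) "hr+hmv" else if (hr_fire) "hr" else "hmv"
        log_event(t, "trigger", cause)
        trigger_times <- c(trigger_times, t)
        log_event(t, "prompt_start", sprintf("%gs breathing prompt", config$prompt_duration_s))
        prompt_until <- t + config$prompt_duration_s
        hr_run <- 0L; hmv_run <- 0L
        quiesce_anchor <- t
        if (!hold_active &&
            sum(trigger_times > t - config$trigger_window_s) >= config$trigger_count_hold) {
          log_event(t, "hold", sprintf("%d triggers within %gs",
                                       config$trigger_count_hold, config$trigger_window_s))
          hold_active <- TRUE
        }
        next
      }
    }

    if (!hold_active && !in_prompt &&
        (t - quiesce_anchor) >= config$quiescence_stepup_s) {
      difficulty <- difficulty + 1L
      log_event(t, "step_up", sprintf("difficulty=%d", difficulty))
      quiesce_anchor <- t
    }
  }
  if (is.finite(prompt_until)) log_event(prompt_until, "prompt_end", "(at block end)")

  ord <- order(ev_t)  # stable: prompt_end logged late still sorts by its time
  out <- list(events = data.frame(t_s = ev_t[ord], kind = ev_kind[ord],
                                  detail = ev_detail[ord],
                                  stringsAsFactors = FALSE),
              final_difficulty = difficulty,
              n_triggers = length(trigger_times))
  class(out) <- "controller_log"
  out
}

#' @export
print.controller_log <- function(x, ...) {
  cat("Controller replay:", nrow(x$events), "events,", x$n_triggers,
      "triggers, final difficulty", x$final_difficulty, "\n")
  if (nrow(x$events)) {
    counts <- table(x$events$kind)
    cat("  ", paste(sprintf("%s=%d", names(counts), counts), collapse = "  "), "\n")
  }
  invisible(x)
}

#' Write a controller log to CSV
#'
#' @param log A `"controller_log"`.
#' @param path Output path; columns `t_s, event, detail`.
#' @return `path`, invisibly.
#' @export
write_controller_log <- function(log, path) {
  stopifnot(inherits(log, "controller_log"))
  df <- log$events
  names(df) <- c("t_s", "event", "detail")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
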