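#' Pipeline configuration
#'
#' Settings for the end-to-end report run: where outputs go, the cohort
#' and controller settings, and the analysis parameters (AR order search,
#' ARCH-LM lags, proxy window).
#'
#' @param out_dir Output directory (created if missing).
#' @param cohort A [cohort_config()].
#' @param controller A [controller_config()].
#' @param p_max,criterion AR order search bounds for [select_ar_order()].
#' @param arch_lm_lags Lags for ARCH-LM / Ljung-Box (default 5).
#' @param proxy_window_s Volatility-proxy window (default 30 s).
#' @param seed Master seed recorded in every output.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir = tempfile("vretvol_"),
                            cohort = cohort_config(seed = seed),
                            controller = controller_config(),
                            p_max = 4, criterion = "bic",
                            arch_lm_lags = 5, proxy_window_s = 30,
                            seed = 1L) {
  structure(list(out_dir = out_dir, cohort = cohort, controller = controller,
                 p_max = p_max, criterion = criterion,
                 arch_lm_lags = arch_lm_lags, proxy_window_s = proxy_window_s,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

## polynomial rolling hash (mod 2^31 - 1) of the JSON-serialised config:
## a short provenance fingerprint, not cryptographic
.config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL  # paths are not part of the analytic configuration
  js <- jsonlite::toJSON(cfg, auto_unbox = TRUE, force = TRUE)
  h <- 7
  for (b in utf8ToInt(js)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

.write_report_csv <- function(df, path, seed, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed=%d config_hash=%s", seed, hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline report CSV (skipping the provenance header)
#'
#' @param path CSV written by [run_pipeline()].
#' @return Data frame.
#' @export
read_report_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

## per-session analysis of one signal across the cohort: the 55-participant
## cross-section per session is the analysed series, matching the published
## table layout (one row per session)
.analyse_signal <- function(sessions, signal_col, config) {
  per_session <- split(sessions, sessions$session)
  norm_rows <- list(); model_rows <- list(); fc_rows <- list()
  for (s in names(per_session)) {
    x <- per_session[[s]][order(per_session[[s]]$participant), signal_col]
    jb <- jarque_bera(x)
    norm_rows[[s]] <- data.frame(
      session = as.integer(s), mean = mean(x), median = stats::median(x),
      sd = stats::sd(x), skewness = jb$skewness, kurtosis = jb$kurtosis,
      jarque_bera = jb$statistic, jb_p = jb$p_value)

    p <- select_ar_order(x, p_max = config$p_max, criterion = config$criterion)
    gain <- fit_gain(x, p = p, arch_lags = config$arch_lm_lags,
                     force_garch = TRUE)
    fit <- gain$garch_fit
    ar <- gain$ar_fit
    M <- length(x)
    ll <- if (!is.null(fit)) fit$loglik else ar$loglik
    T_ <- if (!is.null(fit)) fit$n_params else ar$order_p + 2L
    ic <- information_criteria(ll, T_, M)
    dw <- durbin_watson(ar$residuals)
    r2 <- 1 - sum(ar$residuals^2) / sum((x[(p + 1):M] - mean(x[(p + 1):M]))^2)
    model_rows[[s]] <- data.frame(
      session = as.integer(s), ar_order = p,
      gated_garch = gain$gated_garch, arch_lm_p = gain$arch_lm_p,
      r_square = r2, se_regression = sqrt(mean(ar$residuals^2)),
      loglik = ll, aic = ic$per_obs$aic, sic = ic$per_obs$sic,
      hqc = ic$per_obs$hqc, durbin_watson = dw$statistic)

    fc <- one_step_forecasts(if (!is.null(fit)) fit else ar)
    sc <- score_forecasts(fc$actual, fc$forecast)
    fc_rows[[s]] <- data.frame(
      session = as.integer(s), ar_order = p,
      rmse = sc$rmse, mae = sc$mae, mape = sc$mape, theils_u = sc$theils_u,
      garch_delta = if (!is.null(fit)) fit$delta else NA_real_,
      garch_beta = if (!is.null(fit)) fit$beta else NA_real_,
      garch_gamma = if (!is.null(fit)) fit$gamma else NA_real_,
      persistence = if (!is.null(fit)) fit$beta + fit$gamma else NA_real_)
  }
  list(normality = do.call(rbind, norm_rows),
       model = do.call(rbind, model_rows),
       forecast = do.call(rbind, fc_rows))
}

#' Run the end-to-end analysis pipeline
#'
#' Generates (or accepts) a synthetic cohort, then for each of the three
#' signals (time-on-task, head movement, heart rate) and each session
#' produces the normality table, the model-selection/diagnostic table and
#' the forecast-evaluation table; adds the two cohort outcome tables
#' (fear-score change by stratum; paired pre/post tests), a controller
#' replay summary on a generated session trace, and a provenance log.
#' Every CSV embeds the seed and a hash of the configuration; identical
#' config and seed give byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param cohort Optional pre-built `"cohort_dataset"`; generated from
#'   `config$cohort` when `NULL`.
#' @return Invisibly, a list with all tables, the controller log, and
#'   `paths` of the files written.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  hash <- .config_hash(config)
  if (is.null(cohort)) cohort <- generate_cohort(config$cohort)

  signals <- c(time = "time_s", head_movement = "head_move", heart_rate = "hr_bpm")
  tables <- list(); paths <- character(0)
  for (nm in names(signals)) {
    res <- .analyse_signal(cohort$sessions, signals[[nm]], config)
    for (kind in names(res)) {
      key <- paste0(kind, "_", nm)
      tables[[key]] <- res[[kind]]
      p <- file.path(config$out_dir, paste0(key, ".csv"))
      .write_report_csv(res[[kind]], p, config$seed, hash)
      paths <- c(paths, p)
    }
  }

  tables$fsq_change <- fsq_change_table(cohort$participants)
  tables$paired_tests <- paired_outcomes_table(cohort)
  for (key in c("fsq_change", "paired_tests")) {
    p <- file.path(config$out_dir, paste0(key, ".csv"))
    .write_report_csv(tables[[key]], p, config$seed, hash)
    paths <- c(paths, p)
  }

  trace <- generate_session_trace(trace_gen_params(seed = config$seed))
  log <- run_session(trace, config$controller)
  replay <- data.frame(
    n_events = nrow(log$events), n_triggers = log$n_triggers,
    n_step_up = sum(log$events$kind == "step_up"),
    n_relax = sum(log$events$kind == "relax_scene_enter"),
    final_difficulty = log$final_difficulty)
  tables$controller_replay <- replay
  p <- file.path(config$out_dir, "controller_replay.csv")
  .write_report_csv(replay, p, config$seed, hash)
  paths <- c(paths, p)

  prov <- list(seed = config$seed, config_hash = hash,
               package = "vretvol",
               version = as.character(utils::packageVersion("vretvol")),
               r_version = R.version.string,
               n_tables = length(tables))
  pp <- file.path(config$out_dir, "provenance.json")
  writeLines(jsonlite::toJSON(prov, auto_unbox = TRUE, pretty = TRUE), pp)
  paths <- c(paths, pp)

  invisible(list(tables = tables, controller_log = log, cohort = cohort,
                 paths = paths, config_hash = hash))
}
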