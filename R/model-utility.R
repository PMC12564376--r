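#' Model-free volatility proxies: rolling SD and EWMA variance
#'
#' Trailing rolling standard deviation, or exponentially weighted moving
#' variance of the demeaned series with decay
#' `lambda = 1 - 2/(window_s + 1)` so the effective memory matches the
#' requested window. Windows of 30-60 s are the intended range; values
#' outside it are accepted with a warning.
#'
#' @param series Numeric vector, longer than `window_s`.
#' @param kind `"rolling_sd"` or `"ewma"` (variance).
#' @param window_s Window length in samples/seconds (default 30).
#' @return Numeric vector, same length as `series`.
#' @export
volatility_proxy <- function(series, kind = c("rolling_sd", "ewma"),
                             window_s = 30) {
  kind <- match.arg(kind)
  if (window_s >= length(series)) stop("'window_s' longer than the series")
  if (window_s < 30 || window_s > 60)
    warning("'window_s' outside the intended 30-60 s range")
  if (kind == "rolling_sd") {
    return(zoo::rollapplyr(series, window_s,
                           function(w) if (length(w) < 2) 0 else stats::sd(w),
                           partial = TRUE))
  }
  lambda <- 1 - 2 / (window_s + 1)
  x2 <- (series - mean(series))^2
  as.numeric(stats::filter((1 - lambda) * x2, lambda, method = "recursive",
                           init = mean(x2)))
}

#' AR vs AR-GARCH fit gain with ARCH-LM gating
#'
#' Implements the preconditioned model-utility sequence: fit the AR(p) mean
#' model, test its residuals for ARCH effects, and proceed to the GARCH
#' variance model only when heteroskedasticity is detected
#' (ARCH-LM p <= `alpha`) or `force_garch = TRUE`. When GARCH is fitted,
#' reports the criterion gains `delta_aic = AIC_AR - AIC_ARGARCH` and
#' `delta_bic` (positive favours GARCH) and whether the variance model
#' removed residual volatility (Ljung-Box on squared standardised residuals
#' non-significant at `alpha`).
#'
#' @param series Numeric series.
#' @param p AR order; selected by BIC when `NULL`.
#' @param arch_lags Lags for the ARCH-LM and Ljung-Box tests (default 5).
#' @param alpha Gating level (default 0.05).
#' @param force_garch Fit GARCH regardless of the gate (default `FALSE`).
#' @param constrained Passed to [fit_ar_garch()].
#' @return A list of class `"utility_report"` with `arch_lm_p`,
#'   `gated_garch`, `delta_aic`, `delta_bic`, `residual_vol_removed`,
#'   `ar_fit`, `garch_fit` (the latter `NULL` when not fitted), and
#'   `garch_error` (message, if estimation failed).
#' @export
fit_gain <- function(series, p = NULL, arch_lags = 5, alpha = 0.05,
                     force_garch = FALSE, constrained = TRUE) {
  if (is.null(p)) p <- select_ar_order(series, p_max = 5, criterion = "bic")
  ar <- fit_ar(series, p)
  lm_test <- arch_lm_test(ar$residuals, arch_lags)
  gated <- lm_test$p_value <= alpha
  out <- list(arch_lm_p = lm_test$p_value, gated_garch = gated,
              delta_aic = NA_real_, delta_bic = NA_real_,
              residual_vol_removed = NA, ar_fit = ar, garch_fit = NULL,
              garch_error = NULL)
  if (gated || force_garch) {
    g <- tryCatch(fit_ar_garch(series, p = p, constrained = constrained),
                  error = function(e) e)
    if (inherits(g, "error")) {
      out$garch_error <- conditionMessage(g)
    } else {
      m <- length(ar$residuals)
      k_ar <- ar$order_p + 2
      k_g <- g$n_params
      aic_ar <- -2 * ar$loglik + 2 * k_ar
      aic_g <- -2 * g$loglik + 2 * k_g
      bic_ar <- -2 * ar$loglik + k_ar * log(m)
      bic_g <- -2 * g$loglik + k_g * log(m)
      out$delta_aic <- aic_ar - aic_g
      out$delta_bic <- bic_ar - bic_g
      out$residual_vol_removed <-
        ljung_box_squared(g$std_resid, arch_lags)$p_value > alpha
      out$garch_fit <- g
    }
  }
  class(out) <- "utility_report"
  out
}

#' @export
print.utility_report <- function(x, ...) {
  cat(sprintf("ARCH-LM p = %.3g -> GARCH %s\n", x$arch_lm_p,
              if (x$gated_garch) "gated in" else "not indicated"))
  if (!is.null(x$garch_fit))
    cat(sprintf("  delta AIC = %.3f, delta BIC = %.3f (positive favours GARCH); residual volatility removed: %s\n",
                x$delta_aic, x$delta_bic, x$residual_vol_removed))
  if (!is.null(x$garch_error)) cat("  GARCH estimation failed:", x$garch_error, "\n")
  invisible(x)
}

#' Incremental validity of volatility metrics beyond session means
#'
#' Nested participant-level linear models fitted by maximum likelihood:
#' `M0: outcome ~ means` versus `M1: outcome ~ means + volatility`, with
#' the likelihood-ratio statistic (chi-squared, df = number of
#' linearly independent added predictors), `delta_aic = AIC(M0) - AIC(M1)`
#' and `delta_r2 = R2(M1) - R2(M0)`. Collinear added predictors are
#' dropped by the fit and the LR df adjusted accordingly.
#'
#' @param cohort Data frame, one row per participant.
#' @param outcome_col Name of the outcome column (e.g. a pre-post change
#'   score).
#' @param mean_cols Character vector of session-mean predictor columns.
#' @param vol_cols Character vector of volatility predictor columns (may be
#'   empty: then `M1 = M0`, LR = 0, `delta_r2` = 0).
#' @return A list of class `"incremental_report"` with `lr_stat`, `lr_df`,
#'   `lr_p`, `delta_aic`, `delta_r2`, `n`, and the two `lm` fits.
#' @export
incremental_validity <- function(cohort, outcome_col, mean_cols, vol_cols) {
  need <- c(outcome_col, mean_cols, vol_cols)
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols))
    stop("columns not in cohort: ", paste(missing_cols, collapse = ", "))
  rhs0 <- if (length(mean_cols)) paste(mean_cols, collapse = " + ") else "1"
  f0 <- stats::as.formula(paste(outcome_col, "~", rhs0))
  m0 <- stats::lm(f0, data = cohort)
  if (length(vol_cols) == 0L) {
    out <- list(lr_stat = 0, lr_df = 0L, lr_p = NA_real_, delta_aic = 0,
                delta_r2 = 0, n = stats::nobs(m0), m0 = m0, m1 = m0)
    class(out) <- "incremental_report"
    return(out)
  }
  f1 <- stats::as.formula(paste(outcome_col, "~", rhs0, "+",
                                paste(vol_cols, collapse = " + ")))
  m1 <- stats::lm(f1, data = cohort)
  df_added <- m1$rank - m0$rank
  if (df_added < length(vol_cols))
    message("collinear added predictors: LR df adjusted to ", df_added)
  lr <- max(0, 2 * (as.numeric(stats::logLik(m1)) - as.numeric(stats::logLik(m0))))
  out <- list(
    lr_stat = lr, lr_df = df_added,
    lr_p = if (df_added > 0) stats::pchisq(lr, df_added, lower.tail = FALSE) else NA_real_,
    delta_aic = stats::AIC(m0) - stats::AIC(m1),
    delta_r2 = summary(m1)$r.squared - summary(m0)$r.squared,
    n = stats::nobs(m1), m0 = m0, m1 = m1)
  class(out) <- "incremental_report"
  out
}

#' @export
print.incremental_report <- function(x, ...) {
  cat(sprintf("LR = %.3f on %d df (p = %.3g); delta AIC = %.3f; delta R2 = %.4f; n = %d\n",
              x$lr_stat, x$lr_df,
              if (is.na(x$lr_p)) NA else x$lr_p,
              x$delta_aic, x$delta_r2, x$n))
  invisible(x)
}

#' Serialize a utility report to JSON
#'
#' @param report A `"utility_report"` or `"incremental_report"`.
#' @param path Optional output file.
#' @return JSON string (invisibly when written).
#' @export
utility_to_json <- function(report, path = NULL) {
  obj <- if (inherits(report, "utility_report")) {
    list(arch_lm_p = report$arch_lm_p, gated_garch = report$gated_garch,
         delta_aic = report$delta_aic, delta_bic = report$delta_bic,
         residual_vol_removed = report$residual_vol_removed,
         garch_error = report$garch_error)
  } else if (inherits(report, "incremental_report")) {
    report[c("lr_stat", "lr_df", "lr_p", "delta_aic", "delta_r2", "n")]
  } else stop("unsupported report type")
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
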