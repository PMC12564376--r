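#' Forecast-accuracy scores: MAE, MAPE, RMSE, Theil's U
#'
#' With errors \eqn{\epsilon_t = Z_t - g_t} (actual minus forecast):
#' MAE is the mean absolute error, MAPE the mean absolute percentage error
#' (in percent; undefined when any actual is zero), RMSE the root mean
#' squared error, and Theil's U the normalised statistic
#' \deqn{U_1 = \sqrt{\overline{\epsilon^2}} \big/ \left(
#'   \sqrt{\overline{g^2}} + \sqrt{\overline{Z^2}} \right) \in [0, 1],}
#' which is 0 exactly when forecasts equal actuals. `u_variant = "raw_ratio"`
#' instead returns the unnormalised ratio
#' \eqn{\sqrt{\overline{\epsilon^2}} / \sqrt{\overline{g^2} \cdot \overline{Z^2}}}
#' for comparison; it is not bounded by 1.
#'
#' @param actual,forecast Numeric vectors of equal length >= 1.
#' @param u_variant `"u1"` (default, bounded) or `"raw_ratio"`.
#' @return A list of class `"forecast_scores"` with `mae`, `mape` (percent,
#'   `NA` if undefined), `rmse`, `theils_u`, `n`.
#' @export
#' @examples
#' score_forecasts(c(10, 20), c(11, 22))  # MAPE 10%
score_forecasts <- function(actual, forecast, u_variant = c("u1", "raw_ratio")) {
  u_variant <- match.arg(u_variant)
  if (length(actual) != length(forecast)) stop("'actual' and 'forecast' lengths differ")
  if (length(actual) < 1) stop("need at least one observation")
  if (!all(is.finite(actual)) || !all(is.finite(forecast))) stop("inputs must be finite")
  e <- actual - forecast
  mae <- mean(abs(e))
  rmse <- sqrt(mean(e^2))
  mape <- if (any(actual == 0)) NA_real_ else mean(abs(e / actual)) * 100
  denom_a <- sqrt(mean(actual^2))
  denom_f <- sqrt(mean(forecast^2))
  u <- if (u_variant == "u1") {
    if (denom_a + denom_f == 0) 0 else rmse / (denom_f + denom_a)
  } else {
    if (denom_a * denom_f == 0) NA_real_ else rmse / sqrt(mean(forecast^2) * mean(actual^2))
  }
  structure(list(mae = mae, mape = mape, rmse = rmse, theils_u = u,
                 n = length(actual)),
            class = "forecast_scores")
}

#' @export
print.forecast_scores <- function(x, ...) {
  cat(sprintf("n=%d  RMSE=%.4g  MAE=%.4g  MAPE=%s  Theil's U=%.4g\n",
              x$n, x$rmse, x$mae,
              if (is.na(x$mape)) "undefined (zero actuals)" else sprintf("%.4g%%", x$mape),
              x$theils_u))
  invisible(x)
}
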