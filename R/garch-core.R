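#' Fit an AR(p) mean model by conditional least squares
#'
#' Estimates the autoregressive mean model
#' \deqn{Z_t = c + \alpha_1 Z_{t-1} + \dots + \alpha_p Z_{t-p} + \tau_t}
#' by conditional least squares (OLS on the lag design, conditioning on the
#' first `p` observations). For `p = 0` the intercept is the sample mean and
#' the residuals are the demeaned series.
#'
#' @param series Numeric vector, finite, length `> p + 2`.
#' @param p Non-negative integer lag order.
#'
#' @return An object of class `"ar_fit"`: a list with elements `order_p`,
#'   `coeffs` (named `ar1...arp`), `intercept`, `fitted`, `residuals`
#'   (length `length(series) - p`), `sigma2` (maximum-likelihood residual
#'   variance), `loglik` (Gaussian conditional log-likelihood), `n_used`.
#' @export
#' @examples
#' z <- as.numeric(arima.sim(list(ar = 0.7), n = 500))
#' fit <- fit_ar(z, p = 1)
#' fit$coeffs
fit_ar <- function(series, p) {
  series <- as.numeric(series)
  if (!all(is.finite(series))) stop("'series' must be finite")
  if (length(p) != 1L || p < 0 || p != round(p)) stop("'p' must be a single non-negative integer")
  p <- as.integer(p)
  n <- length(series)
  if (n <= p + 2L) stop("series too short for AR(", p, "): need length > p + 2")

  if (p == 0L) {
    mu <- mean(series)
    res <- series - mu
    sigma2 <- mean(res^2)
    if (sigma2 <= 0) {
      # constant series: degenerate but well-defined for p = 0
      loglik <- Inf
    } else {
      loglik <- -0.5 * n * (log(2 * pi * sigma2) + 1)
    }
    out <- list(order_p = 0L, coeffs = numeric(0), intercept = mu,
                fitted = rep(mu, n), residuals = res, sigma2 = sigma2,
                loglik = loglik, n_used = n)
    class(out) <- "ar_fit"
    return(out)
  }

  if (stats::sd(series) == 0) stop("constant series: singular lag design for p >= 1")
  y <- series[(p + 1L):n]
  X <- cbind(1, stats::embed(series, p + 1L)[, -1L, drop = FALSE])
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("singular lag design: series does not identify AR(", p, ")")
  beta <- qr.coef(qrX, y)
  fitted <- drop(X %*% beta)
  res <- y - fitted
  m <- length(res)
  sigma2 <- mean(res^2)
  loglik <- if (sigma2 > 0) -0.5 * m * (log(2 * pi * sigma2) + 1) else Inf
  out <- list(order_p = p,
              coeffs = stats::setNames(beta[-1L], paste0("ar", seq_len(p))),
              intercept = unname(beta[1L]),
              fitted = fitted, residuals = res, sigma2 = sigma2,
              loglik = loglik, n_used = m)
  class(out) <- "ar_fit"
  out
}

#' @export
print.ar_fit <- function(x, ...) {
  cat("AR(", x$order_p, ") fit by conditional least squares\n", sep = "")
  cat("  intercept:", format(x$intercept, digits = 4), "\n")
  if (x$order_p > 0L)
    cat("  coefficients:", paste(format(x$coeffs, digits = 4), collapse = " "), "\n")
  cat("  residual variance:", format(x$sigma2, digits = 4),
      " log-likelihood:", format(x$loglik, digits = 6), "\n")
  invisible(x)
}

#' Select the AR lag order by information criterion
#'
#' Fits AR(0)...AR(p_max) on a common conditioning sample (the first `p_max`
#' observations are dropped for every candidate so likelihoods are
#' comparable) and returns the order minimising the requested criterion.
#' Ties break toward the smaller order. Textbook criterion forms are used
#' here (AIC `-2ll + 2k`, BIC `-2ll + k log m`, HQC `-2ll + 2k log log m`,
#' with `k = p + 2` counting intercept, AR coefficients and the innovation
#' variance).
#'
#' @param series Numeric vector.
#' @param p_max Maximum order considered (`>= 1`); reduced with a warning if
#'   the series is too short.
#' @param criterion One of `"bic"` (default), `"aic"`, `"hqc"`.
#' @return Integer, the selected order.
#' @export
select_ar_order <- function(series, p_max, criterion = c("bic", "aic", "hqc")) {
  criterion <- match.arg(criterion)
  series <- as.numeric(series)
  if (!all(is.finite(series))) stop("'series' must be finite")
  if (p_max < 1) stop("'p_max' must be >= 1")
  p_max <- as.integer(p_max)
  n <- length(series)
  usable <- floor((n - 4L) / 2L)  # keep a conditioning sample of reasonable size
  if (usable < 1L) stop("series too short for order selection")
  if (p_max > usable) {
    warning("'p_max' reduced from ", p_max, " to ", usable, " (series too short)")
    p_max <- usable
  }
  y_full <- series[(p_max + 1L):n]
  m <- length(y_full)
  lags <- stats::embed(series, p_max + 1L)[, -1L, drop = FALSE]
  crit <- vapply(0:p_max, function(p) {
    X <- if (p == 0L) matrix(1, m, 1L) else cbind(1, lags[, seq_len(p), drop = FALSE])
    qrX <- qr(X)
    res <- qr.resid(qrX, y_full)
    sigma2 <- mean(res^2)
    if (sigma2 <= 0) return(-Inf)  # perfect fit wins
    ll <- -0.5 * m * (log(2 * pi * sigma2) + 1)
    k <- p + 2
    switch(criterion,
           aic = -2 * ll + 2 * k,
           bic = -2 * ll + k * log(m),
           hqc = -2 * ll + 2 * k * log(log(m)))
  }, numeric(1))
  (0:p_max)[which.min(crit)]
}

## GARCH(1,1) conditional-variance recursion, vectorised via the linear
## recursive filter: sigma2_t = delta + beta*tau2_{t-1} + gamma*sigma2_{t-1}.
.garch_recursion <- function(delta, beta, gamma, tau2, sigma2_1) {
  n <- length(tau2)
  if (n == 1L) return(sigma2_1)
  rest <- stats::filter(delta + beta * tau2[-n], filter = gamma,
                        method = "recursive", init = sigma2_1)
  c(sigma2_1, as.numeric(rest))
}

#' Conditional-variance path of a GARCH(1,1) recursion
#'
#' Evaluates \eqn{\sigma^2_t = \delta + \beta \tau^2_{t-1} + \gamma
#' \sigma^2_{t-1}} over a residual series. By default the recursion starts at
#' the unconditional variance \eqn{\delta/(1-\beta-\gamma)} when
#' \eqn{\beta+\gamma<1} (the sample mean square of the residuals otherwise).
#' Supplying both `sigma2_init` and `tau2_init` makes the first element
#' \eqn{\sigma^2_1 = \delta + \beta \tau^2_0 + \gamma \sigma^2_0}; supplying
#' only `sigma2_init` uses it directly as \eqn{\sigma^2_1}.
#'
#' @param delta,beta,gamma GARCH(1,1) parameters.
#' @param residuals Numeric vector of mean-model residuals \eqn{\tau_t}.
#' @param sigma2_init,tau2_init Optional pre-sample values (see above).
#' @param constrained If `TRUE` (default) reject `delta <= 0` or negative
#'   `beta`/`gamma`.
#' @return Numeric vector, same length as `residuals`, the \eqn{\sigma^2_t} path.
#' @export
#' @examples
#' conditional_variance_path(0.5, 0.2, 0.3, rep(0, 5), sigma2_init = 1, tau2_init = 1)
conditional_variance_path <- function(delta, beta, gamma, residuals,
                                      sigma2_init = NULL, tau2_init = NULL,
                                      constrained = TRUE) {
  if (!all(is.finite(residuals))) stop("'residuals' must be finite")
  if (constrained) {
    if (delta <= 0) stop("'delta' must be > 0 when constrained = TRUE")
    if (beta < 0 || gamma < 0) stop("'beta' and 'gamma' must be >= 0 when constrained = TRUE")
  }
  tau2 <- residuals^2
  if (is.null(sigma2_init)) {
    sigma2_init <- if (beta + gamma < 1) delta / (1 - beta - gamma) else mean(tau2)
  }
  sigma2_1 <- if (!is.null(tau2_init)) delta + beta * tau2_init + gamma * sigma2_init
              else sigma2_init
  .garch_recursion(delta, beta, gamma, tau2, sigma2_1)
}

## Negative Gaussian quasi-log-likelihood of residuals under GARCH(1,1).
.garch_nll <- function(delta, beta, gamma, tau2, s2) {
  if (!is.finite(delta) || !is.finite(beta) || !is.finite(gamma)) return(1e10)
  sigma2_1 <- if (beta + gamma < 1 && delta > 0) delta / (1 - beta - gamma) else s2
  sig2 <- .garch_recursion(delta, beta, gamma, tau2, sigma2_1)
  if (any(!is.finite(sig2)) || any(sig2 <= 0)) return(1e10)
  0.5 * sum(log(2 * pi) + log(sig2) + tau2 / sig2)
}

## Gaussian QMLE of GARCH(1,1) on a residual series. Deterministic:
## Nelder-Mead from two fixed starts (volatile and near-homoskedastic) on a
## transformed scale enforcing delta > 0, beta, gamma >= 0, beta+gamma <= 0.999.
.garch_qmle <- function(tau, constrained = TRUE, maxit = 500, reltol = 1e-8) {
  tau2 <- tau^2
  s2 <- mean(tau2)
  if (s2 <= 0) stop("residual series has zero variance")

  if (constrained) {
    cap <- 0.999
    untransform <- function(par) {
      rho <- cap * stats::plogis(par[2L])
      u <- stats::plogis(par[3L])
      c(delta = exp(par[1L]), beta = rho * u, gamma = rho * (1 - u))
    }
    nll_t <- function(par) {
      th <- untransform(par)
      .garch_nll(th[1L], th[2L], th[3L], tau2, s2)
    }
    starts <- list(
      c(log(0.10 * s2), stats::qlogis(0.90 / cap), stats::qlogis(0.05 / 0.90)),
      c(log(0.98 * s2), stats::qlogis(0.02 / cap), stats::qlogis(0.5))
    )
    best <- NULL
    for (st in starts) {
      opt <- stats::optim(st, nll_t, method = "Nelder-Mead",
                          control = list(maxit = maxit, reltol = reltol))
      if (is.null(best) || opt$value < best$value) best <- opt
    }
    th <- untransform(best$par)
    # never report a fit worse than the nested homoskedastic model
    hom <- c(delta = s2, beta = 0, gamma = 0)
    if (.garch_nll(hom[1L], hom[2L], hom[3L], tau2, s2) < best$value) {
      th <- hom
      best$value <- .garch_nll(th[1L], th[2L], th[3L], tau2, s2)
      best$convergence <- 0L
    }
  } else {
    warning("unconstrained GARCH estimation: positivity/stationarity constraints not enforced")
    nll_t <- function(par) .garch_nll(par[1L], par[2L], par[3L], tau2, s2)
    starts <- list(c(0.10 * s2, 0.05, 0.85), c(0.98 * s2, 0.01, 0.01))
    best <- NULL
    for (st in starts) {
      opt <- stats::optim(st, nll_t, method = "Nelder-Mead",
                          control = list(maxit = maxit, reltol = reltol))
      if (is.null(best) || opt$value < best$value) best <- opt
    }
    th <- c(delta = best$par[1L], beta = best$par[2L], gamma = best$par[3L])
  }

  sigma2_1 <- if (th[2L] + th[3L] < 1 && th[1L] > 0) th[1L] / (1 - th[2L] - th[3L]) else s2
  sig2 <- .garch_recursion(th[1L], th[2L], th[3L], tau2, sigma2_1)
  list(delta = unname(th[1L]), beta = unname(th[2L]), gamma = unname(th[3L]),
       cond_var = sig2, loglik = -best$value,
       converged = identical(best$convergence, 0L) || best$convergence == 0)
}

#' Fit an AR(p)-GARCH(1,1) model by two-stage Gaussian QMLE
#'
#' Stage one estimates the AR(p) mean model by conditional least squares
#' ([fit_ar()]); stage two maximises the Gaussian quasi-likelihood of the
#' GARCH(1,1) recursion on the AR residuals. Estimation is deterministic
#' (fixed optimiser starts, no randomness), so refitting identical input
#' yields identical parameters.
#'
#' @param series Numeric vector, length `>= 50`, non-constant.
#' @param p AR order; if `NULL`, selected by [select_ar_order()].
#' @param constrained If `TRUE` (default) enforce `delta > 0`,
#'   `beta, gamma >= 0`, `beta + gamma <= 0.999`; if `FALSE`, unconstrained
#'   QMLE (can reproduce published fits with negative coefficients), with a
#'   warning.
#' @param p_max,criterion Passed to [select_ar_order()] when `p` is `NULL`.
#' @param maxit,reltol Optimiser budget and convergence tolerance.
#'
#' @return An object of class `"ar_garch_fit"`: list with `ar` (the
#'   `"ar_fit"`), `delta`, `beta`, `gamma`, `cond_var_path`
#'   (\eqn{\sigma^2_t}, same length as the AR residuals), `std_resid`
#'   (\eqn{\epsilon_t = \tau_t/\sigma_t}), `loglik` (GARCH-stage Gaussian
#'   log-likelihood of the residuals), `loglik_const_var` (same mean model
#'   with variance fixed at the residual sample variance, for nesting
#'   comparisons), `n_params` (`p + 4`), `converged`, `constrained`.
#' @export
fit_ar_garch <- function(series, p = NULL, constrained = TRUE,
                         p_max = 5, criterion = "bic",
                         maxit = 500, reltol = 1e-8) {
  series <- as.numeric(series)
  if (length(series) < 50L) stop("series too short for GARCH QMLE: need length >= 50")
  if (stats::sd(series) == 0) stop("series has zero variance")
  if (is.null(p)) p <- select_ar_order(series, p_max, criterion)
  ar <- fit_ar(series, p)
  g <- .garch_qmle(ar$residuals, constrained = constrained,
                   maxit = maxit, reltol = reltol)
  m <- length(ar$residuals)
  s2 <- mean(ar$residuals^2)
  ll_const <- -0.5 * m * (log(2 * pi * s2) + 1)
  out <- list(ar = ar, delta = g$delta, beta = g$beta, gamma = g$gamma,
              cond_var_path = g$cond_var,
              std_resid = ar$residuals / sqrt(g$cond_var),
              loglik = g$loglik, loglik_const_var = ll_const,
              n_params = ar$order_p + 1L + 3L,  # mean: intercept + p coeffs; variance: delta, beta, gamma
              converged = g$converged, constrained = constrained)
  class(out) <- "ar_garch_fit"
  out
}

#' @export
print.ar_garch_fit <- function(x, ...) {
  cat("AR(", x$ar$order_p, ")-GARCH(1,1) fit by Gaussian QMLE",
      if (!x$constrained) " (unconstrained)", "\n", sep = "")
  cat(sprintf("  variance equation: sigma2_t = %.4g + %.4g tau2_{t-1} + %.4g sigma2_{t-1}\n",
              x$delta, x$beta, x$gamma))
  vs <- volatility_summary(x)
  cat(sprintf("  persistence %.4g, half-life %.4g steps, log-likelihood %.6g%s\n",
              vs$persistence, vs$half_life_steps, x$loglik,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  invisible(x)
}

#' Volatility persistence, half-life and unconditional variance
#'
#' For a GARCH(1,1) variance equation, persistence is \eqn{\beta+\gamma};
#' the unconditional variance is \eqn{\delta/(1-\beta-\gamma)} when
#' persistence is below one; and the volatility half-life (steps for a
#' variance shock to decay by half) is \eqn{\log(0.5)/\log(\beta+\gamma)}
#' for persistence in (0, 1), infinite at or above one, and not applicable
#' (`NA`) at or below zero.
#'
#' @param object An `"ar_garch_fit"`, or the `beta` value when calling with
#'   explicit numeric parameters.
#' @param ... Passed on to methods.
#' @return A list of class `"volatility_summary"` with `persistence`,
#'   `half_life_steps`, `uncond_var`.
#' @export
volatility_summary <- function(object, ...) UseMethod("volatility_summary")

#' @rdname volatility_summary
#' @param gamma,delta GARCH coefficients for the default (numeric) method;
#'   `delta` may be `NA` if only persistence quantities are needed.
#' @export
volatility_summary.default <- function(object, gamma, delta = NA_real_, ...) {
  beta <- as.numeric(object)
  rho <- beta + gamma
  half <- if (rho > 0 && rho < 1) log(0.5) / log(rho)
          else if (rho >= 1) Inf else NA_real_
  uv <- if (!is.na(delta) && rho < 1) delta / (1 - rho) else NA_real_
  structure(list(persistence = rho, half_life_steps = half, uncond_var = uv),
            class = "volatility_summary")
}

#' @rdname volatility_summary
#' @export
volatility_summary.ar_garch_fit <- function(object, ...) {
  volatility_summary(object$beta, gamma = object$gamma, delta = object$delta)
}

#' @export
print.volatility_summary <- function(x, ...) {
  cat(sprintf("persistence %.4g | half-life %s steps | unconditional variance %s\n",
              x$persistence,
              if (is.na(x$half_life_steps)) "n/a" else format(x$half_life_steps, digits = 4),
              if (is.na(x$uncond_var)) "undefined" else format(x$uncond_var, digits = 4)))
  invisible(x)
}

#' One-step-ahead in-sample forecasts from an AR(p)-GARCH fit
#'
#' The mean forecast for each retained observation is the AR fitted value;
#' returned together with the actual values they predict (the series with
#' the first `p` conditioning observations dropped).
#'
#' @param fit An `"ar_garch_fit"` or `"ar_fit"`.
#' @return A list with `actual` and `forecast` vectors of equal length.
#' @export
one_step_forecasts <- function(fit) {
  ar <- if (inherits(fit, "ar_garch_fit")) fit$ar else fit
  if (!inherits(ar, "ar_fit")) stop("'fit' must be an ar_fit or ar_garch_fit")
  list(actual = ar$fitted + ar$residuals, forecast = ar$fitted)
}

#' Serialize a fit object to JSON
#'
#' @param fit An `"ar_garch_fit"`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
ar_garch_to_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "ar_garch_fit"))
  vs <- volatility_summary(fit)
  obj <- list(
    mean_model = list(order_p = fit$ar$order_p, intercept = fit$ar$intercept,
                      coeffs = as.list(fit$ar$coeffs)),
    variance_model = list(delta = fit$delta, beta = fit$beta, gamma = fit$gamma),
    persistence = vs$persistence, half_life_steps = vs$half_life_steps,
    uncond_var = vs$uncond_var,
    loglik = fit$loglik, n_params = fit$n_params,
    converged = fit$converged, constrained = fit$constrained)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
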