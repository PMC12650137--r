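# Non-neural reference forecasters: persistence, a local-linear (level +
# trend) Kalman filter, and a causal IIR smoother with level-trend
# extrapolation.  The Kalman/IIR internals are documented reconstructions of
# standard designs, univariate in glucose.

#' Persistence forecast
#'
#' The naive clinical baseline: repeat the last observed glucose value
#' across the horizon.
#'
#' @param history Numeric vector of past glucose values (mmol/L).
#' @param horizon Number of steps ahead.
#' @return Numeric vector of length `horizon`.
#' @export
persistence_forecast <- function(history, horizon) {
  if (length(history) < 1L) abort("persistence needs at least one observation.")
  rep(history[length(history)], horizon)
}

#' Local-linear Kalman filter forecast
#'
#' Level + trend state-space model with the standard predict/update
#' recursion over the history, followed by `h`-step extrapolation
#' `level + h * trend`.
#'
#' @inheritParams persistence_forecast
#' @param q_level,q_trend Process noise variances of level and trend.
#' @param r_obs Observation noise variance.
#' @return Numeric vector of length `horizon`.
#' @export
kalman_forecast <- function(history, horizon, q_level = 1e-4,
                            q_trend = 1e-5, r_obs = 0.01) {
  n <- length(history)
  if (n < 2L) abort("Kalman forecast needs at least two observations.")
  if (q_level <= 0 || q_trend <= 0 || r_obs <= 0) abort("variances must be > 0.")
  l <- history[1]; b <- 0
  p11 <- 1; p12 <- 0; p22 <- 1
  for (t in 2:n) {
    # predict
    l <- l + b
    n11 <- p11 + 2 * p12 + p22 + q_level
    n12 <- p12 + p22
    n22 <- p22 + q_trend
    # update
    s <- n11 + r_obs
    k1 <- n11 / s; k2 <- n12 / s
    innov <- history[t] - l
    l <- l + k1 * innov
    b <- b + k2 * innov
    p11 <- (1 - k1) * n11
    p12 <- (1 - k1) * n12
    p22 <- n22 - k2 * n12
  }
  l + seq_len(horizon) * b
}

#' Causal IIR smoothing forecast
#'
#' Smooths the history with a causal IIR filter (by default a low-pass
#' Butterworth of the given order and normalized cutoff; custom `b`/`a`
#' coefficient vectors may be supplied) and extrapolates the filtered
#' endpoint linearly: `level + h * trend` with trend the last filtered
#' increment.  The filter must be stable (poles strictly inside the unit
#' circle).
#'
#' @inheritParams persistence_forecast
#' @param cutoff Normalized cutoff (fraction of Nyquist) of the default
#'   Butterworth design.
#' @param order Filter order of the default design.
#' @param b,a Optional custom transfer-function coefficients.
#' @return Numeric vector of length `horizon`.
#' @export
iir_forecast <- function(history, horizon, cutoff = 0.3, order = 2,
                         b = NULL, a = NULL) {
  if (length(history) < 2L) abort("IIR forecast needs at least two observations.")
  if (is.null(b) || is.null(a)) {
    bf <- signal::butter(order, cutoff)
    b <- bf$b; a <- bf$a
  }
  if (length(a) > 1L) {
    poles <- polyroot(rev(a))
    if (any(Mod(poles) >= 1 - 1e-12)) abort("unstable filter: poles must lie inside the unit circle.")
  }
  f <- as.numeric(signal::filter(signal::Arma(b = b, a = a), history))
  level <- f[length(f)]
  trend <- f[length(f)] - f[length(f) - 1L]
  level + seq_len(horizon) * trend
}

#' Evaluate a reference forecaster on a window set
#'
#' Applies the chosen baseline to the glucose look-back of every window and
#' scores it with the same metric report as the neural model, so baseline
#' and model comparisons share one path.
#'
#' @param windows A [make_windows()] object (raw mmol/L).
#' @param method One of `"persistence"`, `"kalman"`, `"iir"`.
#' @param ... Passed to the forecaster.
#' @return A metric tibble (per patient plus pooled), with a `model` column.
#' @export
evaluate_baseline <- function(windows,
                              method = c("persistence", "kalman", "iir"),
                              ...) {
  method <- match.arg(method)
  fc <- switch(method, persistence = persistence_forecast,
               kalman = kalman_forecast, iir = iir_forecast)
  H <- windows$horizon
  y_hat <- matrix(0, windows$n, H)
  for (i in seq_len(windows$n)) {
    y_hat[i, ] <- fc(windows$x[i, , 1L], H, ...)
  }
  out <- metric_report(windows$y, y_hat, windows$patient_id, H)
  out$model <- method
  out
}
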