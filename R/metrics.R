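# Clinical forecast-evaluation metrics.  All operate in mmol/L space.

#' Mean absolute error
#'
#' @param y,y_hat Numeric vectors (or matrices) of actual and predicted
#'   glucose, mmol/L.
#' @return MAE in mmol/L.
#' @export
metric_mae <- function(y, y_hat) {
  if (length(y) == 0L) abort("empty input.")
  stopifnot(length(y) == length(y_hat))
  mean(abs(y - y_hat))
}

#' Mean absolute relative difference (MARD)
#'
#' The standard CGM accuracy metric:
#' \eqn{\mathrm{MARD} = \frac{100}{n}\sum_i |y_i - \hat y_i| / y_i}.
#'
#' @inheritParams metric_mae
#' @return MARD in percent.
#' @export
metric_mard <- function(y, y_hat) {
  if (length(y) == 0L) abort("empty input.")
  if (any(y <= 0)) abort("MARD requires strictly positive reference values.")
  mean(abs(y - y_hat) / y) * 100
}

#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - \sum(y_i-\hat y_i)^2 / \sum(y_i-\bar y)^2}.  Undefined for
#' constant reference values; returns `NA` with a warning in that case.
#'
#' @inheritParams metric_mae
#' @return Dimensionless, at most 1.
#' @export
metric_r2 <- function(y, y_hat) {
  if (length(y) < 2L) abort("need at least two observations.")
  sstot <- sum((y - mean(y))^2)
  if (sstot == 0) {
    warning("constant reference values: R^2 undefined, returning NA.")
    return(NA_real_)
  }
  1 - sum((y - y_hat)^2) / sstot
}

#' Forecast accuracy at a clinical tolerance
#'
#' Percentage of forecasts whose absolute error is strictly below `tol`
#' (default 0.5 mmol/L; the strict inequality means an error of exactly
#' 0.5 mmol/L does not count as accurate).
#'
#' @inheritParams metric_mae
#' @param tol Tolerance in mmol/L.
#' @return Accuracy in percent, in `[0, 100]`.
#' @export
metric_accuracy <- function(y, y_hat, tol = 0.5) {
  if (length(y) == 0L) abort("empty input.")
  mean(abs(y - y_hat) < tol) * 100
}

#' Weighted intermediate-supervision loss
#'
#' The training objective: both forecast heads are scored by mean absolute
#' error against the same target and combined as
#' `total = w1 * MAE_layer1 + w2 * MAE_final` (defaults 0.3 / 0.7).
#'
#' @param y_hat_int,y_hat_fin Intermediate and final head forecasts.
#' @param y Target values.
#' @param w1,w2 Non-negative head weights summing to 1.
#' @return A list with `mae_layer1`, `mae_final` and `total`.
#' @export
composite_loss <- function(y_hat_int, y_hat_fin, y, w1 = 0.3, w2 = 0.7) {
  if (anyNA(y_hat_int) || anyNA(y_hat_fin) || anyNA(y)) abort("NA inputs.")
  if (abs(w1 + w2 - 1) > 1e-12 || w1 < 0 || w2 < 0) {
    abort("weights must be non-negative and sum to 1.")
  }
  m1 <- metric_mae(y, y_hat_int)
  m2 <- metric_mae(y, y_hat_fin)
  list(mae_layer1 = m1, mae_final = m2, total = w1 * m1 + w2 * m2)
}

# one MetricReport row
metric_row <- function(y, y_hat, patient, horizon) {
  tibble(
    patient = as.character(patient),
    horizon = horizon,
    n = length(y),
    mae = metric_mae(y, y_hat),
    mard = metric_mard(y, y_hat),
    r2 = suppressWarnings(metric_r2(y, y_hat)),
    accuracy = metric_accuracy(y, y_hat)
  )
}

# per-patient rows plus the window-weighted pooled row
metric_report <- function(y, y_hat, patient_id, horizon) {
  rows <- lapply(split(seq_along(patient_id), patient_id), function(i) {
    metric_row(as.vector(y[i, , drop = FALSE]),
               as.vector(y_hat[i, , drop = FALSE]),
               patient_id[i][1], horizon)
  })
  pooled <- metric_row(as.vector(y), as.vector(y_hat), "pooled", horizon)
  dplyr::bind_rows(c(rows, list(pooled)))
}
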