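# broom-style accessors and ggplot2 methods for fitted forecasters.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the training history of a fitted forecaster
#'
#' @param x A `ds_scinet_fit`.
#' @param ... Unused.
#' @return The per-epoch history tibble (`epoch`, `train_loss`, `val_loss`,
#'   `val_mae1`, `val_mae2`, `best_val`; losses in normalized space).
#' @method tidy ds_scinet_fit
#' @export
tidy.ds_scinet_fit <- function(x, ...) {
  x$history
}

#' One-row summary of a fitted forecaster
#'
#' @param x A `ds_scinet_fit`.
#' @param ... Unused.
#' @return A one-row tibble: geometry, parameter count, epochs run, best
#'   epoch and best validation loss.
#' @method glance ds_scinet_fit
#' @export
glance.ds_scinet_fit <- function(x, ...) {
  tibble(
    lookback = x$config$lookback,
    horizon = x$config$horizon,
    layers = x$config$layers,
    levels = x$config$levels,
    n_parameters = sum(vapply(x$params, length, numeric(1))),
    epochs_run = x$stopped_epoch,
    best_epoch = x$best_epoch,
    best_val_loss = x$best_val
  )
}

#' @export
print.ds_scinet <- function(x, ...) {
  cat(sprintf("<%s> lookback %d -> horizon %d, %d layer(s) x %d levels, %d parameters\n",
              class(x)[1], x$config$lookback, x$config$horizon,
              x$config$layers, x$config$levels,
              sum(vapply(x$params, length, numeric(1)))))
  invisible(x)
}

#' Plot the training history
#'
#' @param object A `ds_scinet_fit`.
#' @param ... Unused.
#' @return A ggplot of training and validation loss per epoch.
#' @method autoplot ds_scinet_fit
#' @export
autoplot.ds_scinet_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history[, c("epoch", "train_loss", "val_loss")],
                           -"epoch", names_to = "series", values_to = "loss")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "composite MAE loss (normalized)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a covariate screening result
#'
#' @param object A [screen_covariates()] tibble.
#' @param ... Unused.
#' @return A ggplot bar chart of correlations with glucose.
#' @method autoplot cgm_screening
#' @export
autoplot.cgm_screening <- function(object, ...) {
  d <- object[object$reason != "constant", ]
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$channel,
                                                     abs(.data$correlation)),
                                  y = .data$correlation, fill = .data$keep)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Pearson correlation with glucose") +
    ggplot2::theme_minimal()
}

#' Predicted versus actual glucose curves
#'
#' Draws the actual test-partition glucose curve of one patient against the
#' model's forecasts made `step` minutes ahead.
#'
#' @param fit A `ds_scinet_fit`.
#' @param windows Test windows.
#' @param patient Patient id (defaults to the first in `windows`).
#' @param step Horizon step to display (defaults to the full horizon).
#' @return A ggplot.
#' @export
plot_forecast <- function(fit, windows, patient = NULL, step = NULL) {
  pred <- stats::predict(fit, windows)
  patient <- patient %||% pred$patient[1]
  step <- step %||% fit$config$horizon
  d <- pred[pred$patient == as.character(patient) & pred$step == step, ]
  d$t <- d$t0 + step
  dl <- tidyr::pivot_longer(d[, c("t", "actual", "predicted")], -"t",
                            names_to = "series", values_to = "glucose")
  ggplot2::ggplot(dl, ggplot2::aes(x = .data$t, y = .data$glucose,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = "glucose (mmol/L)", colour = NULL,
                  title = sprintf("patient %s, %d-min-ahead forecast",
                                  patient, step)) +
    ggplot2::theme_minimal()
}
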