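# Minibatch Adam training with validation-based early stopping.

# Warm-start both forecast decoders with the ridge-regression solution of
# (normalized glucose look-back -> horizon), the penalty selected by
# validation MAE.  Training then refines the whole network; with the trees
# zero-initialised the warm start is exactly the model's initial function.
ridge_decoder_init <- function(params, model, tr, va,
                               lambdas = c(1e-4, 1e-2, 1, 100)) {
  Tlb <- model$config$lookback
  Tp <- model$Tp
  X <- cbind(1, matrix(tr$x[, , 1L], dim(tr$x)[1], Tlb))
  Xva <- cbind(1, matrix(va$x[, , 1L], dim(va$x)[1], Tlb))
  xtx <- crossprod(X)
  xty <- crossprod(X, tr$y)
  best <- NULL; best_val <- Inf
  for (lam in lambdas) {
    beta <- tryCatch(solve(xtx + lam * diag(Tlb + 1L), xty, tol = 1e-30),
                     error = function(e) NULL)
    if (is.null(beta)) next
    v <- mean(abs(Xva %*% beta - va$y))
    if (v < best_val) { best_val <- v; best <- beta }
  }
  if (is.null(best)) return(params)
  W <- matrix(0, Tp, model$config$horizon)
  W[(Tp - Tlb + 1L):Tp, ] <- best[-1L, , drop = FALSE]
  for (nm in intersect(c("dec.W", "dec1.W", "dec2.W"), names(params))) {
    params[[nm]] <- W
  }
  for (nm in intersect(c("dec.b", "dec1.b", "dec2.b"), names(params))) {
    params[[nm]] <- as.numeric(best[1L, ])
  }
  params
}

adam_init <- function(params) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(params, function(p) array(0, dim(p) %||% length(p)))
  st$v <- st$m
  st$t <- 0L
  st
}

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  params
}

# composite loss of a forward result in normalized space
batch_loss <- function(out, y, w1, w2) {
  if (!all(is.finite(out$yhat2))) abort("non-finite loss: training diverged.")
  composite_loss(out$yhat1, out$yhat2, y, w1, w2)
}

eval_loss <- function(model, x, y, w1, w2, chunk = 512L) {
  n <- dim(x)[1]
  s1 <- 0; s2 <- 0
  for (i0 in seq(1L, n, chunk)) {
    i1 <- min(i0 + chunk - 1L, n)
    out <- ds_scinet_forward(model, x[i0:i1, , , drop = FALSE])
    yb <- y[i0:i1, , drop = FALSE]
    s1 <- s1 + sum(abs(out$yhat1 - yb))
    s2 <- s2 + sum(abs(out$yhat2 - yb))
  }
  m1 <- s1 / length(y); m2 <- s2 / length(y)
  list(mae_layer1 = m1, mae_final = m2, total = w1 * m1 + w2 * m2)
}

#' Train a DS-SCINet forecaster
#'
#' Minibatch Adam on the weighted intermediate-supervision loss (see
#' [composite_loss()]), computed in normalized space.  After every epoch the
#' composite loss on the validation windows is evaluated; the
#' best-validation parameters are retained and training stops once
#' `patience` epochs pass without an improvement of at least `min_delta`.
#'
#' @param model A `ds_scinet` model from [init_ds_scinet()]; its config
#'   carries all training hyperparameters.
#' @param train,val [make_windows()] objects (raw, mmol/L); the normalizer
#'   must have been fitted on the training partition only.
#' @param normalizer A [fit_normalizer()] result.
#' @param verbose Print per-epoch progress.
#' @return An object of class `ds_scinet_fit` (a trained `ds_scinet` plus
#'   `history` tibble, `normalizer`, `best_val`, `best_epoch` and
#'   `stopped_epoch`).
#' @export
train_ds_scinet <- function(model, train, val, normalizer, verbose = FALSE) {
  cfg <- model$config
  if (train$n == 0L || val$n == 0L) abort("empty training or validation partition.")
  tr <- normalize_windows(train, normalizer)
  va <- normalize_windows(val, normalizer)

  params <- model$params
  if (cfg$decoder_init == "ridge") {
    params <- ridge_decoder_init(params, model, tr, va)
    model$params <- params
  }
  st <- adam_init(params)
  # the initial state (persistence read-out) is the epoch-0 checkpoint
  # candidate: training can only improve on it in validation loss
  v0 <- eval_loss(model, va$x, va$y, cfg$w1, cfg$w2)
  best <- v0$total; best_params <- params; best_epoch <- 0L; since <- 0L
  hist <- vector("list", cfg$max_epochs)
  n <- dim(tr$x)[1]
  epoch <- 0L
  withr::with_seed(cfg$seed + 1L, {
    for (epoch in seq_len(cfg$max_epochs)) {
      idx <- sample.int(n)
      tl <- 0; nb <- 0L
      for (i0 in seq(1L, n, cfg$batch)) {
        i1 <- min(i0 + cfg$batch - 1L, n)
        ib <- idx[i0:i1]
        xb <- tr$x[ib, , , drop = FALSE]
        yb <- tr$y[ib, , drop = FALSE]
        if (cfg$augment_sd > 0) {
          xb <- xb + array(stats::rnorm(length(xb), 0, cfg$augment_sd), dim(xb))
        }
        gr <- new.env(parent = emptyenv())
        ctx <- new_nn_ctx(grads = gr, training = TRUE, dropout = cfg$dropout)
        m <- model; m$params <- params
        out <- ds_scinet_forward(m, xb, ctx)
        lb <- batch_loss(out, yb, cfg$w1, cfg$w2)
        k <- 1 / length(yb)
        out$pb(cfg$w1 * sign(out$yhat1 - yb) * k,
               cfg$w2 * sign(out$yhat2 - yb) * k)
        params <- adam_step(params, gr, st, cfg$lr)
        tl <- tl + lb$total; nb <- nb + 1L
      }
      m <- model; m$params <- params
      vl <- eval_loss(m, va$x, va$y, cfg$w1, cfg$w2)
      improved <- vl$total < best - cfg$min_delta
      if (improved) {
        best <- vl$total; best_params <- params
        best_epoch <- epoch; since <- 0L
      } else {
        since <- since + 1L
      }
      hist[[epoch]] <- tibble(
        epoch = epoch, train_loss = tl / nb, val_loss = vl$total,
        val_mae1 = vl$mae_layer1, val_mae2 = vl$mae_final, best_val = best
      )
      if (verbose) {
        message(sprintf("epoch %3d  train %.5f  val %.5f  best %.5f",
                        epoch, tl / nb, vl$total, best))
      }
      if (since >= cfg$patience) break
    }
  })

  fit <- model
  fit$params <- best_params
  fit$history <- dplyr::bind_rows(hist[!vapply(hist, is.null, logical(1))])
  fit$normalizer <- normalizer
  fit$best_val <- best
  fit$best_epoch <- best_epoch
  fit$stopped_epoch <- epoch
  class(fit) <- c("ds_scinet_fit", "ds_scinet")
  fit
}

#' Forecasts of a trained model on a window set
#'
#' @param object A `ds_scinet_fit`.
#' @param windows A [make_windows()] object (raw mmol/L).
#' @param ... Unused.
#' @return A tibble with one row per window and horizon step: `patient`,
#'   `t0`, `step`, `actual`, `predicted`, `predicted_intermediate`
#'   (mmol/L; heads denormalized with the stored normalizer).
#' @export
predict.ds_scinet_fit <- function(object, windows, ...) {
  nw <- normalize_windows(windows, object$normalizer)
  n <- dim(nw$x)[1]
  H <- object$config$horizon
  y1 <- matrix(0, n, H); y2 <- matrix(0, n, H)
  for (i0 in seq(1L, n, 512L)) {
    i1 <- min(i0 + 511L, n)
    out <- ds_scinet_forward(object, nw$x[i0:i1, , , drop = FALSE])
    y1[i0:i1, ] <- out$yhat1
    y2[i0:i1, ] <- out$yhat2
  }
  g <- glucose_stats(object$normalizer)
  tibble(
    patient = rep(as.character(windows$patient_id), each = H),
    t0 = rep(windows$t0, each = H),
    step = rep.int(seq_len(H), n),
    actual = as.vector(t(windows$y)),
    predicted = as.vector(t(y2 * g$scale + g$center)),
    predicted_intermediate = as.vector(t(y1 * g$scale + g$center))
  )
}

#' Evaluate a trained model on test windows
#'
#' Denormalizes the final-head forecasts and reports MAE, MARD,
#' R-squared and accuracy (strict 0.5 mmol/L tolerance) per patient plus a
#' pooled row (window-weighted, i.e. computed over the concatenated
#' residuals of all patients).
#'
#' @param fit A `ds_scinet_fit`.
#' @param windows Test windows (raw, mmol/L).
#' @return A tibble of metric rows; `patient == "pooled"` is the cohort row.
#' @export
evaluate_forecasts <- function(fit, windows) {
  if (windows$horizon != fit$config$horizon) {
    abort("window horizon does not match the model horizon.")
  }
  nw <- normalize_windows(windows, fit$normalizer)
  n <- dim(nw$x)[1]
  H <- fit$config$horizon
  y2 <- matrix(0, n, H)
  for (i0 in seq(1L, n, 512L)) {
    i1 <- min(i0 + 511L, n)
    out <- ds_scinet_forward(fit, nw$x[i0:i1, , , drop = FALSE])
    y2[i0:i1, ] <- out$yhat2
  }
  g <- glucose_stats(fit$normalizer)
  metric_report(windows$y, y2 * g$scale + g$center, windows$patient_id,
                fit$config$horizon)
}
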