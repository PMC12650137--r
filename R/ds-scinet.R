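# Double-layer stacked SCINet: two binary trees (kernels 3 then 5) composed
# with residual connections, a covariate mapping layer conditioning the
# gating operators, and affine forecast decoders for the intermediate- and
# final-supervision heads.

#' Configuration of a DS-SCINet forecaster
#'
#' @param lookback Look-back window length in steps (default 30, i.e. 30 min
#'   at 1-min resolution — chosen to cover the 15-20 min interstitial lag).
#' @param horizon Forecast horizon in steps; 15/30/45/60 min are the
#'   standard clinical horizons.  One model is trained per horizon (direct
#'   multi-step forecasting).
#' @param levels Tree levels per SCINet layer (each layer holds
#'   `2^levels - 1` SCI-Blocks).
#' @param layers Number of stacked SCINet layers: 2 (the double-layer model,
#'   default) or 1 (a plain single SCINet, for comparison runs).
#' @param kernel1,kernel2 Kernel sizes of the first (short-term) and second
#'   (long-term) layer; the hierarchy requires `kernel1 < kernel2`
#'   (defaults 3 and 5).
#' @param hidden Hidden channels of each interaction operator.
#' @param embed_width Width of the covariate mapping layer (0 disables
#'   covariate conditioning).
#' @param dropout Dropout fraction inside interaction operators (default 0).
#' @param signs Recombination signs of the interactor, see [interact()].
#' @param clamp Gating exponent clamp bound.
#' @param w1,w2 Weights of the intermediate and final mean-absolute-error
#'   loss heads; must be non-negative and sum to 1 (defaults 0.3 / 0.7).
#' @param residual Keep the identity path around each SCINet layer
#'   (`output = layer(input) + input`); turning this off exists only for
#'   ablation.
#' @param variant `"composed"` (default): the second layer refines the first
#'   layer's residual features.  `"independent"`: both layers read the raw
#'   window (stacked-forecast reading), provided for comparison.
#' @param share_decoders Use one affine decoder for both heads.
#' @param decoder_init `"ridge"` (default): before training, both decoders
#'   are warm-started with the ridge-regression solution mapping the
#'   normalized glucose look-back to the horizon, with the penalty chosen on
#'   the validation partition — training then refines it.  `"persistence"`:
#'   decoders start as the last-value read-out.
#' @param augment_sd Standard deviation (normalized units) of Gaussian
#'   input jitter added to training windows; a standard time-series
#'   augmentation that keeps the network from memorising sensor-noise
#'   realisations (0 disables).
#' @param lr,batch Adam learning rate and minibatch size.
#' @param max_epochs,patience,min_delta Training length cap, early-stopping
#'   patience (epochs without a validation improvement of at least
#'   `min_delta`), and the improvement threshold.
#' @param seed Integer seed controlling initialisation and batch order.
#' @return A list of class `ds_scinet_config`.
#' @export
ds_scinet_config <- function(lookback = 30, horizon = 15, levels = 2,
                             layers = 2, kernel1 = 3, kernel2 = 5, hidden = 8,
                             embed_width = 4, dropout = 0,
                             signs = c(1, -1), clamp = 10,
                             w1 = 0.3, w2 = 0.7, residual = TRUE,
                             variant = c("composed", "independent"),
                             share_decoders = FALSE,
                             decoder_init = c("ridge", "persistence"),
                             augment_sd = 0.05,
                             lr = 1e-3, batch = 64, max_epochs = 200,
                             patience = 10, min_delta = 1e-5, seed = 1L) {
  variant <- match.arg(variant)
  decoder_init <- match.arg(decoder_init)
  if (kernel1 >= kernel2) abort("`kernel1` must be smaller than `kernel2`.")
  if (w1 < 0 || w2 < 0 || abs(w1 + w2 - 1) > 1e-12) {
    abort("loss weights must be non-negative and sum to 1.")
  }
  if (levels < 1) abort("`levels` must be >= 1.")
  if (!layers %in% c(1, 2)) abort("`layers` must be 1 or 2.")
  structure(
    list(lookback = as.integer(lookback), horizon = as.integer(horizon),
         levels = as.integer(levels), layers = as.integer(layers),
         kernel1 = as.integer(kernel1),
         kernel2 = as.integer(kernel2), hidden = as.integer(hidden),
         embed_width = as.integer(embed_width), dropout = dropout,
         signs = signs, clamp = clamp, w1 = w1, w2 = w2,
         residual = isTRUE(residual), variant = variant,
         share_decoders = isTRUE(share_decoders),
         decoder_init = decoder_init,
         augment_sd = augment_sd,
         lr = lr, batch = as.integer(batch),
         max_epochs = as.integer(max_epochs), patience = as.integer(patience),
         min_delta = min_delta, seed = as.integer(seed)),
    class = "ds_scinet_config"
  )
}

padded_lookback <- function(lookback, levels) {
  m <- 2L^levels
  as.integer(ceiling(lookback / m) * m)
}

#' Initialise a DS-SCINet model
#'
#' @param config A [ds_scinet_config()].
#' @param channels Character vector of window channel names, glucose first
#'   (the layout produced by [make_windows()]).
#' @return A list of class `ds_scinet` holding the configuration, channel
#'   layout and parameter arrays.  Both trees start at the identity and both
#'   decoders start as the persistence read-out (forecast = last observed
#'   value), so a freshly initialised model is the persistence forecaster.
#' @export
init_ds_scinet <- function(config, channels) {
  stopifnot(inherits(config, "ds_scinet_config"))
  if (channels[1] != "glucose") abort("first window channel must be glucose.")
  Tp <- padded_lookback(config$lookback, config$levels)
  C <- length(channels) + 1L  # + padding flag channel
  cov_idx <- setdiff(seq_along(channels), 1L)
  P <- length(cov_idx)
  E <- if (P > 0L) config$embed_width else 0L
  params <- withr::with_seed(config$seed, {
    p <- list()
    t1 <- scinet_tree_params(C, config$levels, config$kernel1, config$hidden,
                             cov_width = E)
    names(t1) <- paste0("l1.", names(t1))
    p <- c(p, t1)
    # zero-initialised pointwise output projection of each layer: the layer
    # contributes nothing at initialisation, so the residual path makes the
    # whole stack start as the persistence read-out
    p[["l1.out.W"]] <- matrix(0, C, C)
    p[["l1.out.b"]] <- numeric(C)
    if (config$layers == 2L) {
      t2 <- scinet_tree_params(C, config$levels, config$kernel2, config$hidden,
                               cov_width = E)
      names(t2) <- paste0("l2.", names(t2))
      p <- c(p, t2)
      p[["l2.out.W"]] <- matrix(0, C, C)
      p[["l2.out.b"]] <- numeric(C)
    }
    if (E > 0L) {
      p[["emb.W"]] <- matrix(stats::rnorm(P * E, 0, 1 / sqrt(P)), P, E)
      p[["emb.b"]] <- numeric(E)
    }
    dW <- matrix(0, Tp, config$horizon)
    dW[Tp, ] <- 1  # persistence read-out at initialisation
    if (config$share_decoders) {
      p[["dec.W"]] <- dW; p[["dec.b"]] <- numeric(config$horizon)
    } else {
      p[["dec1.W"]] <- dW; p[["dec1.b"]] <- numeric(config$horizon)
      p[["dec2.W"]] <- dW; p[["dec2.b"]] <- numeric(config$horizon)
    }
    p
  })
  structure(list(config = config, channels = channels, params = params,
                 Tp = Tp, cov_idx = cov_idx, embed_width = E),
            class = "ds_scinet")
}

# left replicate-padding to the tree-divisible length plus a flag channel
# marking padded steps
pad_window_block <- function(x, Tp) {
  d <- dim(x)
  pl <- Tp - d[2]
  out <- array(0, c(d[1], Tp, d[3] + 1L))
  idx <- c(rep(1L, pl), seq_len(d[2]))
  out[, , seq_len(d[3])] <- x[, idx, , drop = FALSE]
  if (pl > 0L) out[, seq_len(pl), d[3] + 1L] <- 1
  out
}

# full forward pass; returns both heads and a pullback over the decoders'
# output gradients.  x: (B, lookback, C_window) normalized window block.
ds_scinet_forward <- function(model, x, ctx = NULL) {
  cfg <- model$config
  if (is.null(ctx)) ctx <- new_nn_ctx()
  p <- model$params
  xp <- pad_window_block(x, model$Tp)
  B <- dim(xp)[1]; Tp <- model$Tp; C <- dim(xp)[3]

  cov <- NULL; emb <- NULL
  if (model$embed_width > 0L) {
    cov_raw <- bt_mat(xp[, , model$cov_idx, drop = FALSE])
    emb <- affine_forward(cov_raw, p, "emb", ctx)
    cov <- bt_arr(emb$y, B, Tp)
  }

  t1 <- scinet_tree_forward(xp, p, "l1.", cfg$levels, ctx, cfg$signs,
                            cfg$clamp, cov)
  o1 <- affine_forward(bt_mat(t1$y), p, "l1.out", ctx)
  lay1 <- bt_arr(o1$y, B, Tp)
  r1 <- if (cfg$residual) lay1 + xp else lay1
  d1name <- if (cfg$share_decoders) "dec" else "dec1"
  d2name <- if (cfg$share_decoders) "dec" else "dec2"
  dec1 <- affine_forward(matrix(r1[, , 1L], B, Tp), p, d1name, ctx)

  if (cfg$layers == 2L) {
    x2 <- if (cfg$variant == "composed") r1 else xp
    t2 <- scinet_tree_forward(x2, p, "l2.", cfg$levels, ctx, cfg$signs,
                              cfg$clamp, cov)
    o2 <- affine_forward(bt_mat(t2$y), p, "l2.out", ctx)
    lay2 <- bt_arr(o2$y, B, Tp)
    r2 <- if (cfg$residual) lay2 + x2 else lay2
  } else {
    t2 <- NULL; o2 <- NULL; lay2 <- NULL
    r2 <- r1
  }
  dec2 <- affine_forward(matrix(r2[, , 1L], B, Tp), p, d2name, ctx)

  pb <- function(g1, g2) {
    gr2glu <- dec2$pb(g2)
    gr2 <- array(0, c(B, Tp, C))
    gr2[, , 1L] <- gr2glu
    if (!is.null(t2)) {
      bt2 <- t2$pb(bt_arr(o2$pb(bt_mat(gr2)), B, Tp))
      gx2 <- bt2$gx
      if (cfg$residual) gx2 <- gx2 + gr2
    } else {
      bt2 <- NULL
      gx2 <- gr2
    }
    gr1 <- array(0, c(B, Tp, C))
    gr1[, , 1L] <- dec1$pb(g1)
    if (is.null(t2) || cfg$variant == "composed") gr1 <- gr1 + gx2
    bt1 <- t1$pb(bt_arr(o1$pb(bt_mat(gr1)), B, Tp))
    if (!is.null(emb)) {
      gcov <- bt1$gcov
      if (!is.null(bt2) && !is.null(bt2$gcov)) gcov <- gcov + bt2$gcov
      emb$pb(bt_mat(gcov))
    }
    invisible(NULL)
  }

  list(yhat1 = dec1$y, yhat2 = dec2$y, r1 = r1, r2 = r2,
       layer1 = lay1, layer2 = lay2, pb = pb)
}

#' Forecast with a DS-SCINet model
#'
#' Runs the forward pass on a batch of normalized look-back windows.
#'
#' @param model A `ds_scinet` model (see [init_ds_scinet()]).
#' @param x A `(B, lookback, C)` array of normalized window blocks (or a
#'   single `lookback x C` matrix).
#' @return A list with `yhat1` (intermediate head) and `yhat2` (final head),
#'   each a `B x horizon` matrix in normalized glucose units.
#' @export
ds_scinet_predict <- function(model, x) {
  if (length(dim(x)) == 2L) dim(x) <- c(1L, dim(x))
  out <- ds_scinet_forward(model, x)
  if (!all(is.finite(out$yhat2))) {
    abort("non-finite activations in forward pass; check input scaling.")
  }
  list(yhat1 = out$yhat1, yhat2 = out$yhat2)
}

# ---- checkpoints ------------------------------------------------------------

ckpt_version <- "dscinet-checkpoint-1"

#' Save / load model checkpoints
#'
#' A checkpoint bundles the configuration (with its hash), parameter arrays,
#' channel layout and — so that inference is self-contained — the
#' normalizer fitted on the training partition (with its hash, used to
#' refuse evaluation against mismatched window sets).  Round-trips restore
#' bit-identical forecasts.
#'
#' @param model A `ds_scinet` model or `ds_scinet_fit` object.
#' @param path File path.
#' @param normalizer Optional [fit_normalizer()] result to embed (taken from
#'   the fit object if present).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the model (a `ds_scinet` or `ds_scinet_fit`).
#' @export
save_checkpoint <- function(model, path, normalizer = NULL) {
  normalizer <- normalizer %||% model$normalizer
  obj <- list(
    version = ckpt_version,
    config = model$config,
    config_hash = rlang::hash(model$config),
    object = model,
    normalizer = normalizer,
    normalizer_hash = if (!is.null(normalizer)) rlang::hash(normalizer)
  )
  saveRDS(obj, path, version = 3)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param expected_config Optional `ds_scinet_config`; loading errors if the
#'   checkpoint's configuration hash differs.
#' @export
load_checkpoint <- function(path, expected_config = NULL) {
  obj <- readRDS(path)
  if (!identical(obj$version, ckpt_version)) {
    abort(sprintf("checkpoint version %s not supported.", obj$version %||% "<none>"))
  }
  if (!identical(obj$config_hash, rlang::hash(obj$config))) {
    abort("corrupt checkpoint: configuration hash mismatch.")
  }
  if (!is.null(expected_config) &&
      !identical(rlang::hash(expected_config), obj$config_hash)) {
    abort("checkpoint configuration hash does not match the expected config.")
  }
  model <- obj$object
  model$normalizer <- obj$normalizer
  model
}
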