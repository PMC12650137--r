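# Batched neural-network primitives on (batch, time, channel) arrays.
#
# Each forward function returns the output together with a pullback closure
# that maps the gradient of a scalar loss w.r.t. the output to the gradient
# w.r.t. the input, accumulating parameter gradients into the training
# context along the way.  Arrays of dim c(B, T, C) flatten to (B*T, C)
# matrices column-compatibly, which keeps every convolution a handful of
# matrix products.

# training context: gradient store, op counter, dropout state
new_nn_ctx <- function(grads = NULL, training = FALSE, dropout = 0) {
  ctx <- new.env(parent = emptyenv())
  ctx$gr <- grads
  ctx$training <- training
  ctx$dropout <- dropout
  ctx$n_ops <- 0L
  ctx
}

acc_grad <- function(ctx, name, g) {
  if (is.null(ctx$gr)) return(invisible(NULL))
  cur <- ctx$gr[[name]]
  ctx$gr[[name]] <- if (is.null(cur)) g else cur + g
  invisible(NULL)
}

bt_mat <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1] * d[2], d[3])
  x
}

bt_arr <- function(m, B, T) {
  dim(m) <- c(B, T, ncol(m))
  m
}

# Two-layer convolution operator conv -> tanh -> (dropout) -> conv with
# length-preserving replicate padding.  This is one interaction operator
# (phi/psi/rho/eta); the final convolution is zero-initialised so a fresh
# operator is the zero map.  The heavy lifting lives in src/conv1d.cpp; the
# dropout mask is drawn here so all randomness stays under R's RNG.
convmod_forward <- function(x, params, prefix, ctx) {
  ctx$n_ops <- ctx$n_ops + 1L
  if (.dscinet_state$counting) {
    .dscinet_state$n_ops <- .dscinet_state$n_ops + 1L
  }
  d <- dim(x)
  B <- d[1]; T <- d[2]
  W1 <- params[[paste0(prefix, ".W1")]]
  b1 <- params[[paste0(prefix, ".b1")]]
  W2 <- params[[paste0(prefix, ".W2")]]
  b2 <- params[[paste0(prefix, ".b2")]]
  mask <- NULL
  if (ctx$training && ctx$dropout > 0) {
    h <- dim(W1)[3]
    mask <- matrix(stats::rbinom(B * T * h, 1L, 1 - ctx$dropout) /
                     (1 - ctx$dropout), B * T, h)
  }
  out <- cpp_convmod_fwd(bt_mat(x), B, T, W1, b1, W2, b2, mask)
  pb <- function(g) {
    r <- cpp_convmod_bwd(out$cache, bt_mat(g), W1, W2)
    acc_grad(ctx, paste0(prefix, ".W2"), r$gW2)
    acc_grad(ctx, paste0(prefix, ".b2"), as.numeric(r$gb2))
    acc_grad(ctx, paste0(prefix, ".W1"), r$gW1)
    acc_grad(ctx, paste0(prefix, ".b1"), as.numeric(r$gb1))
    bt_arr(r$gx, B, T)
  }
  list(y = bt_arr(out$y, B, T), pb = pb)
}

# per-timestep affine map (the covariate mapping layer / forecast decoders)
affine_forward <- function(x, params, prefix, ctx) {
  W <- params[[paste0(prefix, ".W")]]
  b <- params[[paste0(prefix, ".b")]]
  y <- x %*% W + matrix(rep(b, each = nrow(x)), nrow(x), length(b))
  pb <- function(g) {
    acc_grad(ctx, paste0(prefix, ".W"), crossprod(x, g))
    acc_grad(ctx, paste0(prefix, ".b"), colSums(g))
    g %*% t(W)
  }
  list(y = y, pb = pb)
}

ch_cat <- function(x, y) {
  d <- dim(x)
  out <- array(0, c(d[1], d[2], d[3] + dim(y)[3]))
  out[, , seq_len(d[3])] <- x
  out[, , d[3] + seq_len(dim(y)[3])] <- y
  out
}
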