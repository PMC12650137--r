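#' @keywords internal
"_PACKAGE"

## usethis namespace: start
#' @importFrom rlang .data %||% abort
#' @importFrom tibble tibble as_tibble
#' @importFrom Rcpp sourceCpp
#' @useDynLib dscinet, .registration = TRUE
## usethis namespace: end
NULL

# coerce vector / (T x C) matrix / (B,T,C) array to the batched 3-D layout
as_btc <- function(x) {
  if (is.null(dim(x))) {
    structure(array(x, c(1L, length(x), 1L)), restore = "vector")
  } else if (length(dim(x)) == 2L) {
    structure(array(x, c(1L, nrow(x), ncol(x))), restore = "matrix")
  } else if (length(dim(x)) == 3L) {
    structure(x, restore = "array")
  } else {
    abort("`x` must be a vector, a T x C matrix, or a (B, T, C) array.")
  }
}

restore_btc <- function(x, restore) {
  switch(restore,
    vector = as.vector(x),
    matrix = matrix(x, dim(x)[2], dim(x)[3]),
    array  = x
  )
}

#' Split a sequence into its odd- and even-position sub-sequences
#'
#' The downsampling step of a SCI-Block: the sequence
#' \eqn{[X_1, X_2, \dots, X_{2n}]} is split by parity of position into
#' \eqn{[X_1, X_3, \dots, X_{2n-1}]} (the "odd" arm) and
#' \eqn{[X_2, X_4, \dots, X_{2n}]} (the "even" arm).  Pure reindexing; no
#' arithmetic is performed.
#'
#' @param x A numeric vector, a `T x C` matrix, or a `(B, T, C)` array with
#'   even time length `T`.
#' @return A list with elements `odd` and `even`, each half the time length
#'   of `x` and of the same class.
#' @seealso [realign()], the exact inverse.
#' @examples
#' split_even_odd(c(1, 2, 3, 4, 5, 6))
#' @export
split_even_odd <- function(x) {
  xb <- as_btc(x)
  r <- attr(xb, "restore")
  T <- dim(xb)[2]
  if (T %% 2L != 0L) abort("time length must be even to split.")
  list(
    odd  = restore_btc(xb[, seq(1L, T, 2L), , drop = FALSE], r),
    even = restore_btc(xb[, seq(2L, T, 2L), , drop = FALSE], r)
  )
}

#' Interleave two sub-sequences back into temporal order
#'
#' Inverse of [split_even_odd()]: element `i` of the odd arm is placed at
#' position `2i - 1`, element `i` of the even arm at position `2i`.
#'
#' @param odd,even Two sequences of equal time length (vectors, matrices or
#'   `(B, T, C)` arrays of matching shape).
#' @return The interleaved sequence, same class as the inputs.
#' @examples
#' realign(c(1, 3), c(2, 4))
#' @export
realign <- function(odd, even) {
  ob <- as_btc(odd); eb <- as_btc(even)
  r <- attr(ob, "restore")
  if (!identical(dim(ob)[2], dim(eb)[2])) abort("arm lengths differ.")
  d <- dim(ob)
  out <- array(0, c(d[1], 2L * d[2], d[3]))
  out[, seq(1L, 2L * d[2], 2L), ] <- ob
  out[, seq(2L, 2L * d[2], 2L), ] <- eb
  restore_btc(out, r)
}

# split for internal (B,T,C) arrays without coercion overhead
split3 <- function(x) {
  T <- dim(x)[2]
  list(odd = x[, seq(1L, T, 2L), , drop = FALSE],
       even = x[, seq(2L, T, 2L), , drop = FALSE])
}

realign3 <- function(odd, even) {
  d <- dim(odd)
  out <- array(0, c(d[1], 2L * d[2], d[3]))
  out[, seq(1L, 2L * d[2], 2L), ] <- odd
  out[, seq(2L, 2L * d[2], 2L), ] <- even
  out
}

# ---- parameter construction -------------------------------------------------

init_convmod_params <- function(k, cin, hidden, cout, prefix, init_sd = NULL) {
  if (k %% 2L == 0L || k < 1L) abort("kernel size must be odd and >= 1.")
  sd1 <- init_sd %||% (1 / sqrt(k * cin))
  p <- list()
  p[[paste0(prefix, ".W1")]] <- array(stats::rnorm(k * cin * hidden, 0, sd1),
                                      c(k, cin, hidden))
  p[[paste0(prefix, ".b1")]] <- numeric(hidden)
  # zero-initialised final convolution: a fresh operator is the zero map, so
  # every SCI-Block (and the whole tree) starts as the identity
  p[[paste0(prefix, ".W2")]] <- array(0, c(k, hidden, cout))
  p[[paste0(prefix, ".b2")]] <- numeric(cout)
  p
}

#' Create the parameters of one SCI-Block
#'
#' A SCI-Block holds four one-dimensional convolutional operators
#' \eqn{\phi, \psi, \rho, \eta}, each implemented as a two-layer stack
#' (conv, tanh, conv) with length-preserving replicate padding.  The gating
#' operators \eqn{\phi} and \eqn{\psi} may additionally receive `cov_width`
#' covariate-feature channels (the covariate mapping layer of the
#' double-layer model).  The final convolution of every operator is
#' zero-initialised, so a freshly created block computes the identity.
#'
#' @param channels Number of sequence channels `C` the block transforms.
#' @param kernel Odd convolution kernel size (time axis).
#' @param hidden Hidden channel count of each two-layer operator.
#' @param cov_width Number of covariate embedding channels concatenated to
#'   the inputs of \eqn{\phi} and \eqn{\psi} (0 = unconditioned block).
#' @param seed Optional integer seed for the first-layer weights.
#' @param init_sd Standard deviation of the first-layer weight
#'   initialisation; defaults to `1/sqrt(kernel * input_channels)`.
#' @return A named list of parameter arrays (class `sci_block_params`).
#' @export
sci_block_params <- function(channels, kernel = 3, hidden = 8, cov_width = 0,
                             seed = NULL, init_sd = NULL) {
  make <- function() {
    c(
      init_convmod_params(kernel, channels + cov_width, hidden, channels, "phi", init_sd),
      init_convmod_params(kernel, channels + cov_width, hidden, channels, "psi", init_sd),
      init_convmod_params(kernel, channels, hidden, channels, "rho", init_sd),
      init_convmod_params(kernel, channels, hidden, channels, "eta", init_sd)
    )
  }
  p <- if (is.null(seed)) make() else withr::with_seed(seed, make())
  structure(p, class = "sci_block_params",
            meta = list(channels = channels, kernel = kernel, hidden = hidden,
                        cov_width = cov_width))
}

zero_block_params <- function(params) {
  for (nm in names(params)) params[[nm]][] <- 0
  params
}

# ---- interactive learning ---------------------------------------------------

# core of Eqs (1)-(2): exponential gating by the opposing arm, then signed
# recombination.  Fo/Fe are (B, n, C); cov_o/cov_e optional (B, n, E).
interact_forward <- function(Fo, Fe, params, prefix, ctx,
                             signs = c(1, -1), clamp = 10,
                             cov_o = NULL, cov_e = NULL) {
  C <- dim(Fo)[3]
  in_phi <- if (is.null(cov_e)) Fe else ch_cat(Fe, cov_e)
  in_psi <- if (is.null(cov_o)) Fo else ch_cat(Fo, cov_o)
  phi <- convmod_forward(in_phi, params, paste0(prefix, "phi"), ctx)
  psi <- convmod_forward(in_psi, params, paste0(prefix, "psi"), ctx)
  a <- pmin(pmax(phi$y, -clamp), clamp)
  b <- pmin(pmax(psi$y, -clamp), clamp)
  ea <- exp(a); eb <- exp(b)
  mask_a <- (phi$y > -clamp & phi$y < clamp)
  mask_b <- (psi$y > -clamp & psi$y < clamp)
  Fos <- Fo * ea
  Fes <- Fe * eb
  rho <- convmod_forward(Fes, params, paste0(prefix, "rho"), ctx)
  eta <- convmod_forward(Fos, params, paste0(prefix, "eta"), ctx)
  yo <- Fos + signs[1] * rho$y
  ye <- Fes + signs[2] * eta$y
  pb <- function(go, ge) {
    gFos <- go + eta$pb(signs[2] * ge)
    gFes <- ge + rho$pb(signs[1] * go)
    gFo <- gFos * ea
    gFe <- gFes * eb
    g_a <- gFos * Fo * ea * mask_a
    g_b <- gFes * Fe * eb * mask_b
    g_in_phi <- phi$pb(g_a)
    g_in_psi <- psi$pb(g_b)
    gco <- NULL; gce <- NULL
    if (!is.null(cov_e)) {
      gFe <- gFe + g_in_phi[, , seq_len(C), drop = FALSE]
      gce <- g_in_phi[, , -seq_len(C), drop = FALSE]
      gFo <- gFo + g_in_psi[, , seq_len(C), drop = FALSE]
      gco <- g_in_psi[, , -seq_len(C), drop = FALSE]
    } else {
      gFe <- gFe + g_in_phi
      gFo <- gFo + g_in_psi
    }
    list(gFo = gFo, gFe = gFe, gco = gco, gce = gce)
  }
  list(yo = yo, ye = ye, pb = pb)
}

#' Interactive learning between two sub-sequences
#'
#' Applies the SCI-Block interaction: each arm is element-wise scaled by the
#' exponential of a convolution of the opposing arm (data augmentation by
#' exponential gating), then recombined with signed convolutional terms:
#' \deqn{F^s_{odd} = F_{odd} \odot \exp(\phi(F_{even})), \quad
#'       F^s_{even} = F_{even} \odot \exp(\psi(F_{odd}))}
#' \deqn{F'_{odd} = F^s_{odd} + s_1\,\rho(F^s_{even}), \quad
#'       F'_{even} = F^s_{even} + s_2\,\eta(F^s_{odd})}
#' When covariate feature sequences are supplied, \eqn{\phi} and \eqn{\psi}
#' receive the channel-wise concatenation of the opposing arm and its
#' covariate features (the covariate-conditioned interactor); \eqn{\rho} and
#' \eqn{\eta} are unchanged.
#'
#' @param f_odd,f_even The two arms (vectors, `T x C` matrices or
#'   `(B, T, C)` arrays of equal shape).
#' @param params A [sci_block_params()] object.
#' @param signs Length-2 vector in \{-1, +1\}: the signs of the
#'   \eqn{\rho}/\eqn{\eta} recombination terms.  The default `c(1, -1)`
#'   follows the original SCINet convention.
#' @param clamp Gating exponents are clamped to `[-clamp, clamp]`.
#' @param cov_odd,cov_even Optional covariate feature sequences aligned to
#'   each arm (same time length, `cov_width` channels).
#' @return A list with elements `odd` and `even`, same shape as the inputs.
#' @export
interact <- function(f_odd, f_even, params, signs = c(1, -1), clamp = 10,
                     cov_odd = NULL, cov_even = NULL) {
  stopifnot(all(signs %in% c(-1, 1)))
  ob <- as_btc(f_odd); eb <- as_btc(f_even)
  if (!identical(dim(ob), dim(eb))) abort("arm shapes differ.")
  r <- attr(ob, "restore")
  co <- if (!is.null(cov_odd)) as_btc(cov_odd)
  ce <- if (!is.null(cov_even)) as_btc(cov_even)
  ctx <- new_nn_ctx()
  out <- interact_forward(ob, eb, params, "", ctx, signs, clamp, co, ce)
  list(odd = restore_btc(out$yo, r), even = restore_btc(out$ye, r))
}

#' Apply one SCI-Block
#'
#' The unit of the SCINet tree: [split_even_odd()] followed by [interact()].
#'
#' @param f Input sequence (vector, `T x C` matrix or `(B, T, C)` array)
#'   with even time length.
#' @inheritParams interact
#' @param cov Optional covariate feature sequence aligned to `f`; it is
#'   split with the same even/odd indexing so each arm of the interactor
#'   receives time-aligned covariate features.
#' @return A list with elements `odd` and `even`, each of time length `T/2`.
#' @export
sci_block <- function(f, params, signs = c(1, -1), clamp = 10, cov = NULL) {
  s <- split_even_odd(f)
  cs <- if (!is.null(cov)) split_even_odd(cov) else list(odd = NULL, even = NULL)
  interact(s$odd, s$even, params, signs, clamp, cs$odd, cs$even)
}

# ---- binary tree ------------------------------------------------------------

# parameter set for a full tree: one block per node, named by parity path
tree_paths <- function(levels) {
  paths <- ""
  out <- character(0)
  for (l in seq_len(levels)) {
    out <- c(out, paths)
    paths <- as.vector(t(outer(paths, c("o", "e"), paste0)))
  }
  out
}

#' Create parameters for a SCINet binary tree
#'
#' A tree of `levels` levels contains `2^levels - 1` SCI-Blocks (level `l`
#' has `2^(l-1)` blocks), each with its own parameters.  Block parameter
#' names are prefixed by the parity path from the root (`""`, `"o"`, `"e"`,
#' `"oo"`, ...).
#'
#' @inheritParams sci_block_params
#' @param levels Number of tree levels `L >= 1`.
#' @return A named list of parameter arrays (class `scinet_tree_params`).
#' @export
scinet_tree_params <- function(channels, levels = 2, kernel = 3, hidden = 8,
                               cov_width = 0, seed = NULL, init_sd = NULL) {
  stopifnot(levels >= 1)
  make <- function() {
    out <- list()
    for (path in tree_paths(levels)) {
      blk <- sci_block_params(channels, kernel, hidden, cov_width,
                              seed = NULL, init_sd = init_sd)
      names(blk) <- paste0("blk.", path, ".", names(blk))
      out <- c(out, blk)
    }
    out
  }
  p <- if (is.null(seed)) make() else withr::with_seed(seed, make())
  structure(p, class = "scinet_tree_params",
            meta = list(channels = channels, levels = levels, kernel = kernel,
                        hidden = hidden, cov_width = cov_width))
}

scinet_tree_forward <- function(x, params, prefix, levels, ctx,
                                signs = c(1, -1), clamp = 10, cov = NULL) {
  rec <- function(x, cov, depth, path) {
    s <- split3(x)
    cs <- if (!is.null(cov)) split3(cov) else list(odd = NULL, even = NULL)
    it <- interact_forward(s$odd, s$even, params,
                           paste0(prefix, "blk.", path, "."),
                           ctx, signs, clamp, cs$odd, cs$even)
    if (depth < levels) {
      no <- rec(it$yo, cs$odd, depth + 1L, paste0(path, "o"))
      ne <- rec(it$ye, cs$even, depth + 1L, paste0(path, "e"))
      yo <- no$y; ye <- ne$y
    } else {
      no <- NULL; ne <- NULL
      yo <- it$yo; ye <- it$ye
    }
    y <- realign3(yo, ye)
    pb <- function(g) {
      gs <- split3(g)
      if (!is.null(no)) {
        sub_o <- no$pb(gs$odd)
        sub_e <- ne$pb(gs$even)
        go <- sub_o$gx; ge <- sub_e$gx
      } else {
        sub_o <- NULL; sub_e <- NULL
        go <- gs$odd; ge <- gs$even
      }
      gi <- it$pb(go, ge)
      gx <- realign3(gi$gFo, gi$gFe)
      gcov <- NULL
      if (!is.null(cov)) {
        gco <- gi$gco; gce <- gi$gce
        if (!is.null(sub_o) && !is.null(sub_o$gcov)) gco <- gco + sub_o$gcov
        if (!is.null(sub_e) && !is.null(sub_e$gcov)) gce <- gce + sub_e$gcov
        gcov <- realign3(gco, gce)
      }
      list(gx = gx, gcov = gcov)
    }
    list(y = y, pb = pb)
  }
  rec(x, cov, 1L, "")
}

#' Apply a SCINet binary tree
#'
#' Recursively applies SCI-Blocks for `levels` levels
#' (downsample-convolve-interact), then realigns the leaf sub-sequences
#' bottom-up by inverse interleaving so the output is a sequence of the
#' original length in original temporal order.  With freshly created
#' (zero-final-conv) parameters the tree is the identity map.
#'
#' @param f Input sequence; time length must be divisible by `2^levels`.
#' @param params A [scinet_tree_params()] object.
#' @inheritParams interact
#' @param cov Optional covariate feature sequence aligned to `f`.
#' @return A sequence of the same shape as `f`.
#' @export
scinet_tree <- function(f, params, signs = c(1, -1), clamp = 10, cov = NULL) {
  levels <- attr(params, "meta")$levels
  xb <- as_btc(f)
  r <- attr(xb, "restore")
  if (dim(xb)[2] %% (2L^levels) != 0L) {
    abort(sprintf("time length %d is not divisible by 2^%d.", dim(xb)[2], levels))
  }
  cb <- if (!is.null(cov)) as_btc(cov)
  ctx <- new_nn_ctx()
  out <- scinet_tree_forward(xb, params, "", levels, ctx, signs, clamp, cb)
  restore_btc(out$y, r)
}

#' Leaf ordering of the SCINet tree
#'
#' Tracks original time indices through `levels` rounds of even/odd
#' splitting and returns them in leaf concatenation order (odd branch
#' first).  Useful for verifying that realignment restores temporal order:
#' the mapping is the bit-reversal permutation of the low `levels` bits of
#' the 0-based time index.
#'
#' @param n Sequence length (divisible by `2^levels`).
#' @param levels Number of split rounds.
#' @return Integer vector: 1-based original indices in leaf order.
#' @export
tree_leaf_order <- function(n, levels) {
  rec <- function(idx, depth) {
    if (depth == 0L) return(idx)
    odd <- idx[seq(1L, length(idx), 2L)]
    even <- idx[seq(2L, length(idx), 2L)]
    c(rec(odd, depth - 1L), rec(even, depth - 1L))
  }
  rec(seq_len(n), levels)
}

#' Count interaction-operator applications
#'
#' Evaluates `expr` while counting how many times a convolutional
#' interaction operator (any of \eqn{\phi,\psi,\rho,\eta}) is applied.  A
#' single forward pass through an `L`-level tree applies `4 * (2^L - 1)`
#' operators.
#'
#' @param expr Expression to evaluate.
#' @return The count (invisible attribute `value` holds the result).
#' @export
count_conv_ops <- function(expr) {
  old <- .dscinet_state$counting
  .dscinet_state$counting <- TRUE
  .dscinet_state$n_ops <- 0L
  on.exit({
    .dscinet_state$counting <- old
  })
  force(expr)
  .dscinet_state$n_ops
}

.dscinet_state <- new.env(parent = emptyenv())
.dscinet_state$counting <- FALSE
.dscinet_state$n_ops <- 0L
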