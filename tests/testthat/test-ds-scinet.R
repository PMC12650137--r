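test_that("configuration invariants are enforced", {
  expect_error(ds_scinet_config(kernel1 = 5, kernel2 = 3), "smaller")
  expect_error(ds_scinet_config(w1 = 0.5, w2 = 0.6), "sum to 1")
  expect_error(ds_scinet_config(w1 = -0.1, w2 = 1.1), "sum to 1")
  expect_error(ds_scinet_config(levels = 0), "levels")
  cfg <- ds_scinet_config(lookback = 30, levels = 2)
  expect_identical(dscinet:::padded_lookback(30, 2), 32L)
  expect_identical(dscinet:::padded_lookback(32, 2), 32L)
})

test_that("a freshly initialised model is the persistence forecaster", {
  cfg <- ds_scinet_config(lookback = 30, horizon = 15, seed = 4)
  m <- init_ds_scinet(cfg, c("glucose", "WE1", "age"))
  x <- array(rnorm(6 * 30 * 3), c(6, 30, 3))
  out <- dscinet:::ds_scinet_forward(m, x)
  # both heads equal the same affine read-out of the raw window, and the
  # residual path passes the input through unchanged
  expect_identical(out$yhat1, out$yhat2)
  expect_equal(unname(out$yhat2), matrix(x[, 30, 1], 6, 15))
  xp <- dscinet:::pad_window_block(x, m$Tp)
  expect_identical(out$r1, xp)
  expect_identical(out$r2, xp)
  expect_identical(ncol(out$yhat2), 15L)
})

test_that("the residual identity path is preserved exactly", {
  cfg <- ds_scinet_config(lookback = 16, horizon = 4, hidden = 3,
                          embed_width = 2, seed = 7)
  m <- init_ds_scinet(cfg, c("glucose", "WE1", "age"))
  withr::with_seed(1, {
    m$params <- lapply(m$params, function(p)
      p + array(rnorm(length(p), 0, 0.1), dim(p) %||% length(p)))
    x <- array(rnorm(4 * 16 * 3), c(4, 16, 3))
  })
  out <- dscinet:::ds_scinet_forward(m, x)
  xp <- dscinet:::pad_window_block(x, m$Tp)
  # r1 = layer1(x) + x, asserted against the separately returned addends
  expect_identical(out$r1, out$layer1 + xp)
  expect_identical(out$r2, out$layer2 + out$r1)
  expect_equal(out$r1 - xp, out$layer1)
})

test_that("without the residual path a zero-initialised stack decodes zeros", {
  cfg <- ds_scinet_config(lookback = 16, horizon = 4, residual = FALSE, seed = 2)
  m <- init_ds_scinet(cfg, c("glucose", "WE1"))
  x <- array(rnorm(3 * 16 * 2), c(3, 16, 2))
  out <- dscinet:::ds_scinet_forward(m, x)
  expect_true(all(out$r2 == 0))
  expect_true(all(out$yhat2 == 0))
})

test_that("covariate conditioning reduces to the plain interactor when inactive", {
  C <- 2; E <- 3
  pc <- random_block_params(C, kernel = 3, hidden = 2, cov_width = E, seed = 11)
  # plain parameters share the sequence-channel weights of the gating ops
  pp <- pc
  for (op in c("phi", "psi")) {
    nm <- paste0(op, ".W1")
    pp[[nm]] <- pc[[nm]][, seq_len(C), , drop = FALSE]
  }
  attr(pp, "meta")$cov_width <- 0
  withr::with_seed(3, {
    fo <- matrix(rnorm(16), 8, 2); fe <- matrix(rnorm(16), 8, 2)
    cov_r <- matrix(rnorm(8 * E), 8, E)
  })
  plain <- interact(fo, fe, pp)
  # (i) zero covariate features: conditioning contributes nothing
  z <- matrix(0, 8, E)
  expect_equal(interact(fo, fe, pc, cov_odd = z, cov_even = z), plain,
               tolerance = 1e-12)
  # (ii) zero extra input-channel weights: any covariates are ignored
  pz <- pc
  for (op in c("phi", "psi")) {
    nm <- paste0(op, ".W1")
    pz[[nm]][, C + seq_len(E), ] <- 0
  }
  expect_equal(interact(fo, fe, pz, cov_odd = cov_r, cov_even = cov_r), plain,
               tolerance = 1e-12)
  # zero operators are the identity regardless of covariates
  p0 <- dscinet:::zero_block_params(pc)
  out0 <- interact(fo, fe, p0, cov_odd = cov_r, cov_even = cov_r)
  expect_identical(out0$odd, fo)
  expect_identical(out0$even, fe)
})

test_that("conditioned interaction matches the extended scalar oracle", {
  for (case in 1:40) {
    withr::with_seed(100 + case, {
      p <- random_block_params(2, kernel = 3, hidden = 2, cov_width = 2,
                               seed = case)
      fo <- matrix(rnorm(16), 8, 2); fe <- matrix(rnorm(16), 8, 2)
      co <- matrix(rnorm(16), 8, 2); ce <- matrix(rnorm(16), 8, 2)
    })
    got <- interact(fo, fe, p, cov_odd = co, cov_even = ce)
    want <- oracle_interact(fo, fe, p, co = co, ce = ce)
    expect_equal(got$odd, want$odd, tolerance = 1e-6)
    expect_equal(got$even, want$even, tolerance = 1e-6)
  }
})

test_that("the covariate embedding is equivariant to channel permutation", {
  cfg <- ds_scinet_config(lookback = 16, horizon = 4, hidden = 3,
                          embed_width = 2, seed = 9)
  ch <- c("glucose", "WE1", "Temperature", "age")
  m <- init_ds_scinet(cfg, ch)
  withr::with_seed(5, {
    m$params <- lapply(m$params, function(p)
      p + array(rnorm(length(p), 0, 0.1), dim(p) %||% length(p)))
    x <- array(rnorm(4 * 16 * 4), c(4, 16, 4))
  })
  base <- dscinet:::ds_scinet_forward(m, x)$yhat2
  # swap covariate channels 2 and 3 of the window together with every
  # parameter dimension indexed by those channels (conv inputs and outputs,
  # the layer projections, the embedding rows); the forecast must not change
  sw <- c(2L, 3L)
  m2 <- m
  m2$params[["emb.W"]] <- m$params[["emb.W"]][c(2, 1, 3), ]
  for (nm in names(m$params)) {
    W <- m$params[[nm]]
    if (grepl("(phi|psi|rho|eta)\\.W1$", nm)) {
      W[, sw, ] <- W[, rev(sw), ]
    } else if (grepl("\\.W2$", nm)) {
      W[, , sw] <- W[, , rev(sw)]
    } else if (grepl("\\.b2$", nm)) {
      W[sw] <- W[rev(sw)]
    } else if (grepl("out\\.W$", nm)) {
      W <- W[c(1, 3, 2, 4, 5), c(1, 3, 2, 4, 5)]
    } else if (grepl("out\\.b$", nm)) {
      W[sw] <- W[rev(sw)]
    } else {
      next
    }
    m2$params[[nm]] <- W
  }
  x2 <- x[, , c(1, 3, 2, 4)]
  out2 <- dscinet:::ds_scinet_forward(m2, x2)$yhat2
  expect_equal(out2, base, tolerance = 1e-10)
})

test_that("a double-layer model with an inert second layer equals one layer", {
  ch <- c("glucose", "WE1")
  cfg2 <- ds_scinet_config(lookback = 16, horizon = 4, hidden = 3,
                           embed_width = 2, layers = 2, seed = 13)
  m2 <- init_ds_scinet(cfg2, ch)
  withr::with_seed(2, {
    for (nm in grep("^(l1|emb|dec)", names(m2$params), value = TRUE)) {
      m2$params[[nm]] <- m2$params[[nm]] +
        array(rnorm(length(m2$params[[nm]]), 0, 0.1),
              dim(m2$params[[nm]]) %||% length(m2$params[[nm]]))
    }
    x <- array(rnorm(4 * 16 * 2), c(4, 16, 2))
  })
  cfg1 <- ds_scinet_config(lookback = 16, horizon = 4, hidden = 3,
                           embed_width = 2, layers = 1, seed = 13)
  m1 <- init_ds_scinet(cfg1, ch)
  m1$params <- m2$params[names(m1$params)]
  expect_equal(dscinet:::ds_scinet_forward(m1, x)$yhat2,
               dscinet:::ds_scinet_forward(m2, x)$yhat2, tolerance = 1e-12)
})

test_that("checkpoints round-trip bit-identically and verify hashes", {
  d <- toy_channels(200)
  w <- make_windows(d, 16, 4, c("glucose", "WE1", "age"))
  sp <- chronological_split(w)
  nz <- fit_normalizer(sp$train)
  cfg <- ds_scinet_config(lookback = 16, horizon = 4, hidden = 3,
                          max_epochs = 2, patience = 1, batch = 32, seed = 1)
  fit <- train_ds_scinet(init_ds_scinet(cfg, w$channels), sp$train, sp$val, nz)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fit, path)
  back <- load_checkpoint(path)
  nw <- normalize_windows(sp$test, nz)
  expect_identical(dscinet:::ds_scinet_forward(back, nw$x)$yhat2,
                   dscinet:::ds_scinet_forward(fit, nw$x)$yhat2)
  expect_identical(back$normalizer, nz)
  # mismatched expected config is refused
  other <- ds_scinet_config(lookback = 16, horizon = 4, hidden = 5)
  expect_error(load_checkpoint(path, expected_config = other), "hash")
  # corrupting the stored config breaks the integrity hash
  obj <- readRDS(path)
  obj$config$hidden <- 99L
  saveRDS(obj, path)
  expect_error(load_checkpoint(path), "hash")
})
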