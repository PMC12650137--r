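test_that("forward imputation carries the last observation forward", {
  d <- toy_series(c(5.0, NA, NA, 6.0))
  expect_equal(forward_impute(d)$glucose, c(5, 5, 5, 6))
  d2 <- toy_series(c(5, 6, 7))
  expect_identical(forward_impute(d2), d2)
  expect_error(forward_impute(toy_series(c(NA, 5))), "leading missing")
  expect_error(forward_impute(toy_series(numeric(0))), "empty")
})

test_that("outlier exclusion uses the closed physiological interval", {
  d <- toy_series(c(2.5, 5.0, 23.0, 10.0))
  out <- exclude_outliers(d)
  expect_identical(out$n_excluded, 2L)
  expect_equal(out$data$glucose, c(NA, 5, NA, 10))

  ok <- toy_series(c(3, 10, 20))
  out2 <- exclude_outliers(ok)
  expect_identical(out2$n_excluded, 0L)
  expect_identical(out2$data, ok)

  # boundary readings are retained
  bd <- exclude_outliers(toy_series(c(2.8, 22.2, 5)))
  expect_identical(bd$n_excluded, 0L)
  expect_error(exclude_outliers(d, low = 5, high = 5), "below")

  # survivor count identity on arbitrary input
  withr::with_seed(8, {
    x <- runif(500, 0, 30)
    r <- exclude_outliers(toy_series(x))
    expect_identical(sum(!is.na(r$data$glucose)) + r$n_excluded, 500L)
  })
})

test_that("resampling forward-fills onto the uniform grid", {
  d <- toy_series(5 + seq_len(20) / 10)
  expect_equal(resample_uniform(d)$glucose, d$glucose)

  gap <- toy_series(c(5, 6))
  gap$minute <- c(0, 10)
  gap$time <- gap$time[1] + gap$minute * 60
  rs <- resample_uniform(gap)
  expect_equal(rs$minute, 0:10)
  expect_equal(rs$glucose, c(rep(5, 10), 6))

  # one simulated day (1-min day / 10-min night) lands on 1441 grid points
  g <- simulate_glucose_trace(quiet_profile(), one_day_config())
  rs2 <- resample_uniform(g)
  expect_identical(nrow(rs2), 1441L)
  # every original observation appears unchanged at its grid timestamp
  expect_equal(rs2$glucose[match(g$minute, rs2$minute)], g$glucose)
  expect_error(resample_uniform(g[0, ]), "empty")
})

test_that("low-pass filtering passes DC exactly and crushes high frequencies", {
  const <- toy_series(rep(7.7, 256))
  expect_equal(lowpass_filter(const, 0.1)$glucose, rep(7.7, 256),
               tolerance = 1e-9)
  expect_equal(lowpass_filter(const, 0.1, method = "butterworth")$glucose,
               rep(7.7, 256), tolerance = 1e-6)
  # sinusoid at 0.8 Nyquist against a 0.1 Nyquist cutoff: >= 20x attenuation
  # (for the forward-backward Butterworth, away from its edge transients)
  n <- 512
  mid <- (n / 4):(3 * n / 4)
  hf <- sin(2 * pi * 0.4 * seq_len(n))  # 0.4 cycles/sample = 0.8 Nyquist
  filt <- lowpass_filter(toy_series(5 + hf), 0.1)$glucose - 5
  expect_lt(max(abs(filt)), 1 / 20)
  filt_b <- lowpass_filter(toy_series(5 + hf), 0.1,
                           method = "butterworth")$glucose - 5
  expect_lt(max(abs(filt_b[mid])), 1 / 20)
  # slow trend + high-frequency spike train: output recovers the trend
  trend <- 6 + 1.5 * sin(2 * pi * seq_len(n) / n)
  spikes <- rep(c(0.4, -0.4), n / 2)
  filt <- lowpass_filter(toy_series(trend + spikes), 0.1)$glucose
  expect_lt(max(abs(filt - trend)), 0.1)
  # mean preserved on stationary input
  withr::with_seed(2, x <- 8 + rnorm(n, 0, 0.3))
  for (m in c("fft", "butterworth")) {
    f <- lowpass_filter(toy_series(x), 0.1, method = m)$glucose
    expect_lt(abs(mean(f) - mean(x)) / mean(x), 0.01)
  }
  expect_error(lowpass_filter(const, 0), "cutoff")
  expect_error(lowpass_filter(toy_series(c(5, NA, 6))), "imputed")
  nonuni <- toy_series(c(5, 6, 7)); nonuni$minute <- c(0, 1, 5)
  expect_error(lowpass_filter(nonuni), "uniform")
})

test_that("the repair pipeline is idempotent", {
  cfg <- sim_config(n_patients = 2, wear_days = 2, seed = 6)
  raw <- simulate_cohort(cfg)
  once <- repair_cgm(raw)
  twice <- repair_cgm(once)
  expect_equal(twice$glucose, once$glucose, tolerance = 1e-9)
  expect_true(all(once$glucose >= 2.8 & once$glucose <= 22.2))
  expect_false(anyNA(once$glucose))
  # every injected out-of-range value is excluded; forward-fill can copy an
  # out-of-range value into an adjacent missing slot, so >= not ==
  expect_gte(attr(once, "n_excluded"), sum(raw$is_outlier))
})

test_that("covariate screening ranks by correlation and drops constants", {
  d <- toy_channels(300)
  d$self <- d$glucose
  d$flat <- 3.3
  scr <- screen_covariates(d, channels = c("self", "WE1", "flat"))
  expect_identical(scr$channel[1], "self")
  expect_equal(scr$correlation[1], 1.0)
  flat_row <- scr[scr$channel == "flat", ]
  expect_identical(flat_row$reason, "constant")
  expect_false(flat_row$keep)
  expect_true(is.na(flat_row$correlation))
  d$flat2 <- 0
  expect_error(screen_covariates(d, channels = c("flat", "flat2")), "constant")
})

test_that("screening on the synthetic cohort keeps WE1 over WE2", {
  rep <- repair_cgm(simulate_cohort(sim_config(n_patients = 2, wear_days = 1,
                                               seed = 2)))
  scr <- screen_covariates(rep)
  r <- function(ch) abs(scr$correlation[scr$channel == ch])
  expect_gt(r("WE1"), r("WE2"))
  expect_true(scr$keep[scr$channel == "WE1"])
  expect_false(scr$keep[scr$channel == "WE2"])
})

test_that("window extraction yields N - T - H + 1 aligned windows", {
  d <- toy_channels(100)
  w <- make_windows(d, lookback = 30, horizon = 15,
                    channels = c("glucose", "WE1", "age"))
  expect_identical(w$n, 56L)
  expect_identical(dim(w$x), c(56L, 30L, 3L))
  expect_identical(w$channels[1], "glucose")
  # a window's target is the series immediately after its look-back
  i <- 10
  t0 <- w$t0[i]
  expect_equal(w$x[i, , 1], d$glucose[(t0 - 29):t0])
  expect_equal(w$y[i, ], d$glucose[(t0 + 1):(t0 + 15)])
  # minimal series gives exactly one window
  w1 <- make_windows(toy_channels(45), 30, 15, c("glucose", "WE1"))
  expect_identical(w1$n, 1L)
  expect_error(make_windows(toy_channels(44), 30, 15, c("glucose", "WE1")),
               "too short")
  expect_error(make_windows(d, 30, 15, channels = c("WE1", "glucose")),
               "glucose")
})

test_that("chronological split puts boundaries at 70% and 85% of the timeline", {
  d <- toy_channels(1000)
  w <- make_windows(d, 30, 15, c("glucose", "WE1"))
  sp <- chronological_split(w)
  # boundaries at points 700 and 850; no window spans a boundary
  expect_identical(max(sp$train$t0) + w$horizon, 700)
  expect_true(min(sp$val$t0) - w$lookback + 1 > 700)
  expect_identical(max(sp$val$t0) + w$horizon, 850)
  expect_true(min(sp$test$t0) - w$lookback + 1 > 850)
  expect_lt(max(sp$train$t0), min(sp$val$t0))
  expect_lt(max(sp$val$t0), min(sp$test$t0))
  # all windows in train under a (1, 0, 0) spec
  all_train <- chronological_split(w, 1, 0, 0)
  expect_identical(all_train$train$n, w$n)
  expect_identical(all_train$test$n, 0L)
  expect_error(chronological_split(w, 0.7, 0.2, 0.2), "sum to 1")
})

test_that("the normalizer standardizes, inverts, and is fitted on train only", {
  d <- toy_channels(400)
  w <- make_windows(d, 30, 15, c("glucose", "WE1", "age"))
  sp <- chronological_split(w)
  nz <- fit_normalizer(sp$train)
  tr <- normalize_windows(sp$train, nz)
  # training channels have mean 0 after standardization
  for (ci in 1:2) expect_lt(abs(mean(tr$x[, , ci])), 1e-9)
  # constant channel falls back to centering only
  expect_equal(unname(nz$scale["age"]), 1)
  expect_equal(unname(nz$center["age"]), 60)
  # apply then invert is the identity
  expect_equal(denormalize_glucose(tr$y, nz), sp$train$y, tolerance = 1e-9)
  # normalizer depends only on the training partition: corrupting every
  # reading after the train boundary (floor(0.7 * 400) = 280) changes nothing
  d3 <- d
  d3$glucose[281:400] <- 21
  d3$WE1[281:400] <- 0
  w3 <- make_windows(d3, 30, 15, c("glucose", "WE1", "age"))
  nz3 <- fit_normalizer(chronological_split(w3)$train)
  expect_identical(nz3, nz)
  # mismatched channel layout is refused
  expect_error(normalize_windows(make_windows(d, 30, 15, c("glucose", "WE1")),
                                 nz), "match")
})
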