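test_that("the composite loss weights the two heads 0.3 / 0.7", {
  lb <- composite_loss(c(1, 2), c(1.5, 3.5), c(0, 0), w1 = 0.3, w2 = 0.7)
  expect_equal(lb$mae_layer1, 1.5)
  expect_equal(lb$mae_final, 2.5)
  expect_equal(lb$total, 0.3 * 1.5 + 0.7 * 2.5)
  # the printed arithmetic case: MAE heads 1.0 and 2.0 combine to 1.7
  y <- c(0, 0); i1 <- c(1, 1); i2 <- c(2, 2)
  expect_equal(composite_loss(i1, i2, y)$total, 1.7)
  # perfect heads give zero; equal heads collapse to the common value
  expect_equal(composite_loss(y, y, y)$total, 0)
  expect_equal(composite_loss(i1, i1, y)$total, 1)
  expect_error(composite_loss(i1, i2, y, w1 = 0.5, w2 = 0.6), "sum to 1")
  expect_error(composite_loss(c(1, NA), i2, y), "NA")
})

test_that("the composite loss is 1-homogeneous in the error scale", {
  withr::with_seed(4, {
    y <- rnorm(20); a <- rnorm(20); b <- rnorm(20)
    base <- composite_loss(y + a, y + b, y)$total
    for (c in c(0.5, 2, 10)) {
      expect_equal(composite_loss(y + c * a, y + c * b, y)$total, c * base)
    }
  })
})

test_that("MAE, MARD, R2 and accuracy match their closed forms", {
  expect_equal(metric_mae(c(5, 6), c(5.5, 6.5)), 0.5)
  expect_equal(metric_mae(c(5, 6), c(5, 6)), 0)
  expect_equal(metric_mae(4.0, 6.5), 2.5)
  expect_error(metric_mae(numeric(0), numeric(0)), "empty")

  expect_equal(metric_mard(c(5, 10), c(5.5, 9)), 10)
  expect_equal(metric_mard(c(5, 10), c(5, 10)), 0)
  expect_equal(metric_mard(4, 5), 25)
  expect_error(metric_mard(c(0, 5), c(1, 5)), "positive")

  expect_equal(metric_r2(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(metric_r2(c(1, 2, 3), rep(2, 3)), 0)
  expect_equal(metric_r2(c(1, 2, 3), c(1, 2, 5)), -1)
  expect_warning(r <- metric_r2(c(2, 2, 2), c(1, 2, 3)), "constant")
  expect_true(is.na(r))

  # strict < at the 0.5 mmol/L tolerance: an error of exactly 0.5 is out
  expect_equal(metric_accuracy(c(0, 0, 0), c(0.4, 0.5, 0.6)), 100 / 3)
  expect_equal(metric_accuracy(1:5, 1:5), 100)
  expect_equal(metric_accuracy(c(0, 0), c(0.5, 2)), 0)
})

test_that("metric reports pool patients by concatenated residuals", {
  withr::with_seed(6, {
    y <- matrix(runif(40, 4, 9), 10, 4)
    yh <- y + matrix(rnorm(40, 0, 0.3), 10, 4)
    pid <- rep(c(1, 2), c(3, 7))
  })
  rep <- dscinet:::metric_report(y, yh, pid, horizon = 4)
  pooled <- rep[rep$patient == "pooled", ]
  per <- rep[rep$patient != "pooled", ]
  expect_equal(pooled$mae, sum(per$mae * per$n) / sum(per$n))
  expect_equal(pooled$n, 40L)
  # a perfect forecaster maxes every metric
  perf <- dscinet:::metric_report(y, y, pid, 4)
  expect_true(all(perf$mae == 0 & perf$mard == 0 & perf$accuracy == 100))
  expect_true(all(perf$r2 == 1))
})

test_that("training stops by patience and retains the best checkpoint", {
  d <- toy_channels(260)
  d$glucose <- d$glucose + 0.3 * sin(seq_len(260) / 3)
  w <- make_windows(d, 16, 4, c("glucose", "WE1", "age"))
  sp <- chronological_split(w)
  nz <- fit_normalizer(sp$train)
  cfg0 <- ds_scinet_config(lookback = 16, horizon = 4, hidden = 3,
                           max_epochs = 30, patience = 0, batch = 32, seed = 2)
  fit0 <- train_ds_scinet(init_ds_scinet(cfg0, w$channels), sp$train, sp$val, nz)
  expect_identical(nrow(fit0$history), 1L)

  cfg <- ds_scinet_config(lookback = 16, horizon = 4, hidden = 3,
                          max_epochs = 12, patience = 3, batch = 32, seed = 2)
  fit <- train_ds_scinet(init_ds_scinet(cfg, w$channels), sp$train, sp$val, nz)
  h <- fit$history
  # best-so-far validation loss never increases, and the returned model's
  # validation loss is its minimum (epoch 0 = warm start included)
  expect_true(all(diff(h$best_val) <= 0))
  expect_equal(fit$best_val, min(h$best_val))
  expect_lte(fit$best_val, min(h$val_loss))
  g <- glance(fit)
  expect_identical(g$best_epoch, fit$best_epoch)
  expect_identical(nrow(tidy(fit)), nrow(h))
  none <- dscinet:::subset_windows(sp$train, rep(FALSE, sp$train$n))
  expect_error(train_ds_scinet(init_ds_scinet(cfg, w$channels),
                               none, sp$val, nz), "empty")
})

test_that("training on a constant series reaches near-zero validation MAE", {
  d <- toy_channels(200)
  d$glucose <- 6.5
  w <- make_windows(d, 16, 4, c("glucose", "WE1", "age"))
  sp <- chronological_split(w)
  nz <- fit_normalizer(sp$train)
  cfg <- ds_scinet_config(lookback = 16, horizon = 4, hidden = 3,
                          max_epochs = 50, patience = 5, batch = 32, seed = 3)
  fit <- train_ds_scinet(init_ds_scinet(cfg, w$channels), sp$train, sp$val, nz)
  met <- evaluate_forecasts(fit, sp$val)
  expect_lt(met$mae[met$patient == "pooled"], 0.05)
})

test_that("evaluation refuses a horizon mismatch and inverts to mmol/L", {
  d <- toy_channels(240)
  w <- make_windows(d, 16, 4, c("glucose", "WE1", "age"))
  sp <- chronological_split(w)
  nz <- fit_normalizer(sp$train)
  cfg <- ds_scinet_config(lookback = 16, horizon = 4, hidden = 3,
                          max_epochs = 2, patience = 1, batch = 32, seed = 1)
  fit <- train_ds_scinet(init_ds_scinet(cfg, w$channels), sp$train, sp$val, nz)
  w8 <- make_windows(d, 16, 8, c("glucose", "WE1", "age"))
  expect_error(evaluate_forecasts(fit, w8), "horizon")
  met <- evaluate_forecasts(fit, sp$test)
  expect_true(all(met$mae < 1))  # mmol/L scale, smooth toy signal
  pred <- predict(fit, sp$test)
  expect_identical(nrow(pred), sp$test$n * 4L)
  expect_true(all(abs(pred$actual - pred$predicted) < 5))
})

test_that("persistence error grows with the horizon on synthetic data", {
  g <- repair_cgm(simulate_cohort(sim_config(n_patients = 1, wear_days = 1,
                                             seed = 5)))
  maes <- vapply(c(5, 15, 30), function(H) {
    w <- make_windows(g, 30, H, c("glucose", "WE1"), stride = 5)
    m <- evaluate_baseline(w, "persistence")
    m$mae[m$patient == "pooled"]
  }, numeric(1))
  expect_true(all(diff(maes) > 0))
})
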