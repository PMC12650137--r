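# End-to-end pipeline stages.  Every stage writes a serialized copy of its
# configuration and the hashes of its inputs into its output directory, so
# any artifact directory is reproducible from config + seed alone.

write_stage_config <- function(out_dir, stage, config) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(config, file.path(out_dir, paste0(stage, "_config.yaml")))
}

log_stage <- function(out_dir, stage, ...) {
  rec <- c(list(stage = stage), list(...),
           list(elapsed_s = round(proc.time()[["elapsed"]], 3)))
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE),
      file = file.path(out_dir, "log.jsonl"), sep = "\n", append = TRUE)
}

#' Simulate a cohort and write it to disk
#'
#' @param out_dir Output directory.
#' @param n_patients,wear_days,seed Cohort size, wear period (days), seed.
#' @param ... Further [sim_config()] arguments.
#' @return The dataset manifest, invisibly.
#' @export
run_simulate <- function(out_dir, n_patients = 3, wear_days = 3, seed = 1L, ...) {
  config <- sim_config(n_patients = n_patients, wear_days = wear_days,
                       seed = seed, ...)
  data <- simulate_cohort(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_stage_config(out_dir, "simulate",
                     config[setdiff(names(config), "start")])
  manifest <- write_cgm_dataset(data, out_dir, seed = seed)
  log_stage(out_dir, "simulate", n_patients = n_patients,
            n_readings = nrow(data))
  invisible(manifest)
}

#' Preprocess a dataset into windowed arrays
#'
#' Reads the CSV dataset, screens covariates, repairs and resamples each
#' series, cuts windows, splits chronologically and fits the normalizer on
#' the training partition.  The windows and a JSON sidecar (channel order,
#' normalizer parameters and hash, split sizes) are written to `out_dir`.
#'
#' @param data_dir Dataset directory (see [write_cgm_dataset()]).
#' @param out_dir Output directory.
#' @param lookback,horizon Window geometry in steps.
#' @param stride Window stride.
#' @param threshold Covariate screening threshold.
#' @param train_frac,val_frac,test_frac Chronological split fractions.
#' @return A list `(split, normalizer, screening)`, invisibly.
#' @export
run_preprocess <- function(data_dir, out_dir, lookback = 30, horizon = 15,
                           stride = 1, threshold = 0.2, train_frac = 0.70,
                           val_frac = 0.15, test_frac = 0.15) {
  data <- read_cgm_dataset(data_dir)
  repaired <- repair_cgm(data)
  screening <- screen_covariates(repaired, threshold = threshold)
  keep <- screening$channel[screening$keep]
  channels <- c("glucose", intersect(
    c("sensor_k", "WE1", "WE2", "ratio", "sensor_r", "Temperature",
      "Battery Voltage"), keep), "age", "sex", "type")
  windows <- make_windows(repaired, lookback, horizon, channels, stride)
  split <- chronological_split(windows, train_frac, val_frac, test_frac)
  normalizer <- fit_normalizer(split$train)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_stage_config(out_dir, "preprocess",
                     list(data_dir = data_dir, lookback = lookback,
                          horizon = horizon, stride = stride,
                          threshold = threshold,
                          fractions = c(train_frac, val_frac, test_frac)))
  saveRDS(list(split = split, normalizer = normalizer, screening = screening),
          file.path(out_dir, "windows.rds"), version = 3)
  sidecar <- list(
    channels = channels,
    lookback = lookback, horizon = horizon,
    normalizer = list(center = as.list(normalizer$center),
                      scale = as.list(normalizer$scale)),
    normalizer_hash = rlang::hash(normalizer),
    n_windows = list(train = split$train$n, val = split$val$n,
                     test = split$test$n),
    screening = list(channel = screening$channel,
                     correlation = screening$correlation,
                     keep = screening$keep)
  )
  jsonlite::write_json(sidecar, file.path(out_dir, "sidecar.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  readr::write_csv(as_tibble(screening), file.path(out_dir, "screening.csv"))
  log_stage(out_dir, "preprocess", n_train = split$train$n,
            n_val = split$val$n, n_test = split$test$n)
  invisible(list(split = split, normalizer = normalizer, screening = screening))
}

#' Train a forecaster on preprocessed windows
#'
#' @param prep_dir Directory written by [run_preprocess()].
#' @param out_dir Output directory for checkpoint, history and model card.
#' @param config A [ds_scinet_config()]; its lookback/horizon must match the
#'   preprocessed windows.
#' @return The fitted model, invisibly.
#' @export
run_train <- function(prep_dir, out_dir, config = ds_scinet_config()) {
  prep <- readRDS(file.path(prep_dir, "windows.rds"))
  split <- prep$split
  if (config$horizon != split$train$horizon ||
      config$lookback != split$train$lookback) {
    abort("config lookback/horizon do not match the preprocessed windows.")
  }
  model <- init_ds_scinet(config, split$train$channels)
  fit <- train_ds_scinet(model, split$train, split$val, prep$normalizer)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_stage_config(out_dir, "train", unclass(config))
  save_checkpoint(fit, file.path(out_dir, "checkpoint.rds"))
  readr::write_csv(fit$history, file.path(out_dir, "history.csv"))
  card <- c(
    sprintf("dscinet model card"),
    sprintf("horizon_steps: %d", config$horizon),
    sprintf("lookback_steps: %d", config$lookback),
    sprintf("seed: %d", config$seed),
    sprintf("normalizer_hash: %s", rlang::hash(prep$normalizer)),
    sprintf("best_epoch: %d", fit$best_epoch),
    sprintf("best_val_loss: %.6f", fit$best_val)
  )
  writeLines(card, file.path(out_dir, "model_card.txt"))
  log_stage(out_dir, "train", best_epoch = fit$best_epoch,
            stopped_epoch = fit$stopped_epoch, best_val = fit$best_val)
  invisible(fit)
}

#' Evaluate a checkpoint on the test partition
#'
#' Refuses to run if the checkpoint's normalizer hash does not match the
#' preprocessing sidecar (preventing silent train/test contamination).
#'
#' @param ckpt_path Checkpoint file from [run_train()].
#' @param prep_dir Directory written by [run_preprocess()].
#' @param out_dir Output directory.
#' @return The metric tibble, invisibly.
#' @export
run_evaluate <- function(ckpt_path, prep_dir, out_dir) {
  fit <- load_checkpoint(ckpt_path)
  prep <- readRDS(file.path(prep_dir, "windows.rds"))
  sidecar <- jsonlite::read_json(file.path(prep_dir, "sidecar.json"))
  if (!identical(rlang::hash(fit$normalizer), sidecar$normalizer_hash)) {
    abort("normalizer hash mismatch between checkpoint and window sidecar.")
  }
  metrics <- evaluate_forecasts(fit, prep$split$test)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(metrics, file.path(out_dir, "metrics.csv"))
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_stage(out_dir, "evaluate", n_test = prep$split$test$n)
  invisible(metrics)
}

#' Compare the model against reference forecasters
#'
#' Trains the double-layer model and a single-layer SCINet on the
#' preprocessed windows and evaluates them, together with the Kalman, IIR
#' and persistence baselines, on the test partition — one comparison grid of
#' pooled test MAE per model and horizon.
#'
#' @param prep_dirs Named list/vector of [run_preprocess()] directories, one
#'   per horizon (names are the horizon minutes).
#' @param out_dir Output directory.
#' @param base_config A [ds_scinet_config()] supplying hyperparameters; its
#'   horizon is overridden per entry of `prep_dirs`.
#' @return The comparison tibble, invisibly.
#' @export
run_compare <- function(prep_dirs, out_dir, base_config = ds_scinet_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (h in names(prep_dirs)) {
    prep <- readRDS(file.path(prep_dirs[[h]], "windows.rds"))
    split <- prep$split
    cfgs <- list(
      `DS-SCINet` = modify_config(base_config, horizon = split$train$horizon,
                                  lookback = split$train$lookback, layers = 2),
      SCINet = modify_config(base_config, horizon = split$train$horizon,
                             lookback = split$train$lookback, layers = 1,
                             w1 = 0, w2 = 1)
    )
    for (nm in names(cfgs)) {
      model <- init_ds_scinet(cfgs[[nm]], split$train$channels)
      fit <- train_ds_scinet(model, split$train, split$val, prep$normalizer)
      met <- evaluate_forecasts(fit, split$test)
      pooled <- met[met$patient == "pooled", ]
      rows[[length(rows) + 1L]] <-
        tibble(model = nm, horizon = as.integer(h), mae = pooled$mae,
               mard = pooled$mard, r2 = pooled$r2, accuracy = pooled$accuracy)
    }
    for (bl in c("kalman", "iir", "persistence")) {
      met <- evaluate_baseline(split$test, bl)
      pooled <- met[met$patient == "pooled", ]
      rows[[length(rows) + 1L]] <-
        tibble(model = bl, horizon = as.integer(h), mae = pooled$mae,
               mard = pooled$mard, r2 = pooled$r2, accuracy = pooled$accuracy)
    }
  }
  cmp <- dplyr::bind_rows(rows)
  readr::write_csv(cmp, file.path(out_dir, "comparison.csv"))
  wide <- tidyr::pivot_wider(cmp[, c("model", "horizon", "mae")],
                             names_from = "horizon", values_from = "mae",
                             names_prefix = "mae_")
  readr::write_csv(wide, file.path(out_dir, "comparison_mae_grid.csv"))
  log_stage(out_dir, "compare", n_models = length(unique(cmp$model)))
  invisible(cmp)
}

modify_config <- function(config, ...) {
  args <- utils::modifyList(unclass(config), list(...))
  do.call(ds_scinet_config, args[names(formals(ds_scinet_config))])
}
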