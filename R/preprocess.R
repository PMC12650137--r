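# Preprocessing chain for CGM records: covariate screening, repair (forward
# imputation, physiological-range outlier exclusion, zero-phase low-pass
# filtering), uniform resampling, windowing, chronological splitting and
# train-partition normalization.  All verbs take the cohort tibble first and
# handle multiple patients by grouping on `patient_id`.

per_patient <- function(data, f) {
  if (!"patient_id" %in% names(data)) return(f(data))
  dplyr::bind_rows(lapply(split(data, data$patient_id, drop = TRUE), f))
}

#' Rank covariates by correlation with glucose
#'
#' Pearson correlation of each non-constant dynamic channel with the glucose
#' target, ranked by absolute correlation, with a keep/drop recommendation
#' at `|r| >= threshold`.  Constant channels exert no influence within the
#' dataset and are excluded from the ranking with reason `"constant"`.
#'
#' @param data Cohort tibble with a repaired glucose column.
#' @param channels Dynamic channels to screen.
#' @param target Target column (default `"glucose"`).
#' @param threshold Absolute-correlation keep threshold.
#' @return A tibble of class `cgm_screening`: `channel`, `correlation`,
#'   `keep`, `reason`, ranked channels first.
#' @export
screen_covariates <- function(data,
                              channels = c("sensor_r", "sensor_k", "WE1",
                                           "WE2", "ratio", "Temperature",
                                           "Battery Voltage"),
                              target = "glucose", threshold = 0.2) {
  channels <- intersect(channels, names(data))
  g <- data[[target]]
  ok <- !is.na(g)
  rows <- lapply(channels, function(ch) {
    x <- data[[ch]][ok]
    if (stats::sd(x) == 0) {
      tibble(channel = ch, correlation = NA_real_, keep = FALSE,
             reason = "constant")
    } else {
      r <- stats::cor(x, g[ok])
      tibble(channel = ch, correlation = r, keep = abs(r) >= threshold,
             reason = if (abs(r) >= threshold) "correlated" else "weak")
    }
  })
  out <- dplyr::bind_rows(rows)
  if (all(out$reason == "constant")) abort("all screened channels are constant.")
  out <- dplyr::arrange(out, .data$reason == "constant",
                        dplyr::desc(abs(.data$correlation)))
  class(out) <- c("cgm_screening", class(out))
  out
}

#' Forward-impute missing glucose readings
#'
#' Replaces each missing value by the most recent observed value (per
#' patient).  Glucose changes little minute-to-minute, which makes
#' last-observation-carried-forward the appropriate repair for short sensor
#' dropouts.  Errors if a patient's first reading is missing.
#'
#' @param data Cohort tibble.
#' @param col Column to impute.
#' @return The tibble with `col` imputed and `is_missing` cleared.
#' @export
forward_impute <- function(data, col = "glucose") {
  if (nrow(data) == 0L) abort("empty series.")
  per_patient(data, function(d) {
    if (is.na(d[[col]][1])) {
      abort(sprintf("leading missing value for patient %s.",
                    d$patient_id[1] %||% "<unknown>"))
    }
    d[[col]] <- zoo::na.locf(d[[col]])
    if ("is_missing" %in% names(d)) d$is_missing <- FALSE
    d
  })
}

#' Mark physiologically implausible readings as missing
#'
#' Readings outside the closed interval `[low, high]` (defaults
#' 2.8-22.2 mmol/L; boundary values are retained) are set to `NA` for
#' re-imputation by the caller.
#'
#' @param data Cohort tibble.
#' @param low,high Plausibility bounds, mmol/L.
#' @param col Column to screen.
#' @return A list: `data` (readings outside the range set to `NA`) and
#'   `n_excluded`.
#' @export
exclude_outliers <- function(data, low = 2.8, high = 22.2, col = "glucose") {
  if (low >= high) abort("`low` must be below `high`.")
  x <- data[[col]]
  bad <- !is.na(x) & (x < low | x > high)
  data[[col]][bad] <- NA_real_
  list(data = data, n_excluded = sum(bad))
}

# forward-backward Butterworth with odd-reflection end padding (filtfilt
# alone starts from zero initial conditions, which leaves large edge
# transients); the padding is cropped after filtering
butter_filtfilt <- function(x, cutoff_fraction, order = 2) {
  n <- length(x)
  bf <- signal::butter(order, cutoff_fraction)
  pad <- min(n - 1L, ceiling(6 / cutoff_fraction))
  xe <- c(2 * x[1] - rev(x[2:(pad + 1L)]), x,
          2 * x[n] - rev(x[(n - pad):(n - 1L)]))
  f <- as.numeric(signal::filtfilt(bf, xe))
  f[pad + seq_len(n)]
}

fft_lowpass <- function(x, cutoff_fraction) {
  n <- length(x)
  kmax <- floor(cutoff_fraction * n / 2)
  keep <- c(seq_len(kmax + 1L), if (kmax > 0L) (n - kmax + 1L):n)
  X <- stats::fft(x)
  mask <- rep(0, n)
  mask[unique(pmin(keep, n))] <- 1
  Re(stats::fft(X * mask, inverse = TRUE)) / n
}

#' Zero-phase low-pass filtering of a uniformly sampled series
#'
#' Removes high-frequency sensor noise while preserving hypo-/hyperglycemic
#' excursions.  The cutoff is expressed as a fraction of the Nyquist
#' frequency of the sampled series (at 1-min sampling, Nyquist is
#' ~0.0083 Hz, so absolute cutoffs in Hz are not meaningful).  The default
#' method is an ideal frequency-domain truncation: zero-phase, exactly
#' mean-preserving, and a projection — so the repair pipeline is idempotent.
#' A zero-phase (forward-backward) second-order Butterworth filter is
#' available as an alternative.
#'
#' @param data Cohort tibble, uniformly resampled, no missing values.
#' @param cutoff_fraction Cutoff as a fraction of Nyquist, in (0, 1).
#' @param col Column to filter.
#' @param method `"fft"` (default) or `"butterworth"`.
#' @return The tibble with `col` filtered.
#' @export
lowpass_filter <- function(data, cutoff_fraction = 0.1, col = "glucose",
                           method = c("fft", "butterworth")) {
  method <- match.arg(method)
  if (cutoff_fraction <= 0 || cutoff_fraction >= 1) {
    abort("`cutoff_fraction` must be in (0, 1).")
  }
  per_patient(data, function(d) {
    x <- d[[col]]
    if (anyNA(x)) abort("filtering requires a fully imputed series.")
    if ("minute" %in% names(d) && nrow(d) > 2L &&
        length(unique(round(diff(d$minute), 9))) != 1L) {
      abort("filtering requires uniform sampling; resample first.")
    }
    d[[col]] <- if (method == "fft") {
      fft_lowpass(x, cutoff_fraction)
    } else {
      butter_filtfilt(x, cutoff_fraction)
    }
    d
  })
}

#' Resample a series onto a uniform grid
#'
#' Places every channel on a uniform `interval`-minute grid spanning each
#' patient's wear period.  Gaps (e.g. the 10-min night spacing) are filled
#' by forward-fill of the latest observation; original observations appear
#' unchanged at their grid-aligned timestamps.
#'
#' @param data Cohort tibble with a `minute` column (strictly increasing per
#'   patient).
#' @param interval Grid interval in minutes.
#' @return The resampled tibble.
#' @export
resample_uniform <- function(data, interval = 1) {
  if (nrow(data) == 0L) abort("empty series.")
  per_patient(data, function(d) {
    m <- d$minute
    if (any(diff(m) <= 0)) abort("timestamps must be strictly increasing.")
    grid <- seq(m[1], m[length(m)], by = interval)
    idx <- findInterval(grid, m)
    out <- d[idx, ]
    out$minute <- grid
    out$time <- d$time[1] + (grid - m[1]) * 60
    out
  })
}

#' Full repair pipeline
#'
#' Forward imputation, closed-interval outlier exclusion, re-imputation of
#' the excluded readings, uniform resampling and zero-phase low-pass
#' filtering, per patient.  Applying the pipeline twice equals applying it
#' once (the filter is a projection).
#'
#' @inheritParams exclude_outliers
#' @inheritParams lowpass_filter
#' @inheritParams resample_uniform
#' @return The repaired tibble, with attribute `n_excluded`.
#' @export
repair_cgm <- function(data, low = 2.8, high = 22.2, cutoff_fraction = 0.1,
                       interval = 1, method = "fft") {
  d <- forward_impute(data)
  ex <- exclude_outliers(d, low, high)
  d <- forward_impute(ex$data)
  d <- resample_uniform(d, interval)
  d <- lowpass_filter(d, cutoff_fraction, method = method)
  attr(d, "n_excluded") <- ex$n_excluded
  d
}

# ---- windowing --------------------------------------------------------------

#' Cut sliding look-back/horizon windows
#'
#' Stride-1 (by default) sliding windows per patient: each window pairs a
#' `lookback x channels` block (glucose first, dynamic covariates, then
#' static covariates broadcast as constant channels) with the next `horizon`
#' glucose values as the target.  A patient with `N` readings yields
#' `N - lookback - horizon + 1` windows at stride 1.
#'
#' @param data Repaired, uniformly resampled cohort tibble.
#' @param lookback Look-back length in steps (default 30).
#' @param horizon Forecast horizon in steps.
#' @param channels Window channels; must start with `"glucose"`.
#' @param stride Step between consecutive window origins.
#' @return An object of class `cgm_windows`: arrays `x` `(n, lookback, C)`
#'   and `y` `(n, horizon)` plus per-window `t0` (index of the last observed
#'   step in the patient's series) and `patient_id`.
#' @export
make_windows <- function(data, lookback = 30, horizon = 15,
                         channels = c("glucose", "sensor_k", "WE1",
                                      "Temperature", "Battery Voltage",
                                      "age", "sex", "type"),
                         stride = 1) {
  channels <- intersect(channels, names(data))
  if (channels[1] != "glucose") abort("`channels` must start with \"glucose\".")
  parts <- lapply(split(data, data$patient_id, drop = TRUE), function(d) {
    N <- nrow(d)
    if (N < lookback + horizon) {
      abort(sprintf("patient %s series too short (%d < lookback + horizon).",
                    d$patient_id[1], N))
    }
    if (anyNA(d[, channels])) abort("windows require fully repaired channels.")
    t0 <- seq(lookback, N - horizon, by = stride)
    nw <- length(t0)
    x <- array(0, c(nw, lookback, length(channels)))
    look_idx <- outer(t0 - lookback, seq_len(lookback), "+")
    for (ci in seq_along(channels)) {
      x[, , ci] <- matrix(d[[channels[ci]]][look_idx], nw, lookback)
    }
    y <- matrix(d$glucose[outer(t0, seq_len(horizon), "+")], nw, horizon)
    list(x = x, y = y, t0 = t0, patient_id = rep(d$patient_id[1], nw), N = N)
  })
  x <- do.call(abind1, lapply(parts, `[[`, "x"))
  y <- do.call(rbind, lapply(parts, `[[`, "y"))
  structure(
    list(x = x, y = y,
         t0 = unlist(lapply(parts, `[[`, "t0"), use.names = FALSE),
         patient_id = unlist(lapply(parts, `[[`, "patient_id"), use.names = FALSE),
         series_n = vapply(parts, `[[`, numeric(1), "N"),
         channels = channels, lookback = as.integer(lookback),
         horizon = as.integer(horizon), n = nrow(y)),
    class = "cgm_windows"
  )
}

abind1 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  n <- sum(vapply(parts, function(p) dim(p)[1], numeric(1)))
  out <- array(0, c(n, d[2], d[3]))
  at <- 0L
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}

subset_windows <- function(w, sel) {
  structure(
    list(x = w$x[sel, , , drop = FALSE], y = w$y[sel, , drop = FALSE],
         t0 = w$t0[sel], patient_id = w$patient_id[sel],
         series_n = w$series_n, channels = w$channels,
         lookback = w$lookback, horizon = w$horizon, n = sum(sel)),
    class = "cgm_windows"
  )
}

#' @export
print.cgm_windows <- function(x, ...) {
  cat(sprintf("<cgm_windows> %d windows (lookback %d, horizon %d, %d channels, %d patients)\n",
              x$n, x$lookback, x$horizon, length(x$channels),
              length(unique(x$patient_id))))
  invisible(x)
}

#' Chronological train / validation / test split
#'
#' Per patient, the first `train_frac` of the timeline feeds the training
#' partition, the next `val_frac` the validation partition and the remainder
#' the test partition (boundaries at `floor(frac * N)` timeline points; for
#' 1000 points and 70/15/15 that is points 700 and 850).  The split is never
#' shuffled, and a window whose look-back or target spans a boundary is
#' dropped from the later partition so no reading leaks across partitions.
#'
#' @param windows A [make_windows()] object.
#' @param train_frac,val_frac,test_frac Fractions summing to 1.
#' @return A list of class `cgm_split` with `cgm_windows` elements `train`,
#'   `val`, `test`.
#' @export
chronological_split <- function(windows, train_frac = 0.70, val_frac = 0.15,
                                test_frac = 0.15) {
  if (abs(train_frac + val_frac + test_frac - 1) > 1e-9) {
    abort("split fractions must sum to 1.")
  }
  N <- windows$series_n[as.character(windows$patient_id)]
  b1 <- floor(train_frac * N)
  b2 <- floor((train_frac + val_frac) * N)
  lo <- windows$t0 - windows$lookback + 1
  hi <- windows$t0 + windows$horizon
  structure(
    list(train = subset_windows(windows, hi <= b1),
         val = subset_windows(windows, lo > b1 & hi <= b2),
         test = subset_windows(windows, lo > b2)),
    class = "cgm_split"
  )
}

# ---- normalization ----------------------------------------------------------

#' Fit a per-channel normalizer on training windows
#'
#' Affine standardization (center by the mean, scale by the standard
#' deviation) per window channel, fitted on the training partition only.  A
#' zero-variance channel falls back to centering only (scale 1).
#'
#' @param windows Training-partition [make_windows()] object.
#' @return An object of class `cgm_normalizer`.
#' @export
fit_normalizer <- function(windows) {
  C <- length(windows$channels)
  center <- numeric(C); scale <- numeric(C)
  for (ci in seq_len(C)) {
    v <- windows$x[, , ci]
    center[ci] <- mean(v)
    s <- stats::sd(v)
    scale[ci] <- if (is.na(s) || s == 0) 1 else s
  }
  structure(list(center = stats::setNames(center, windows$channels),
                 scale = stats::setNames(scale, windows$channels),
                 channels = windows$channels),
            class = "cgm_normalizer")
}

glucose_stats <- function(normalizer) {
  list(center = unname(normalizer$center["glucose"]),
       scale = unname(normalizer$scale["glucose"]))
}

#' Apply / invert a normalizer
#'
#' @param windows A [make_windows()] object (raw mmol/L).
#' @param normalizer A [fit_normalizer()] result.
#' @return `normalize_windows`: a list with standardized `x` and `y` (target
#'   standardized with the glucose channel statistics).
#'   `denormalize_glucose`: values mapped back to mmol/L.
#' @export
normalize_windows <- function(windows, normalizer) {
  if (!identical(windows$channels, normalizer$channels)) {
    abort("window channels do not match the normalizer.")
  }
  x <- windows$x
  for (ci in seq_along(normalizer$channels)) {
    x[, , ci] <- (x[, , ci] - normalizer$center[ci]) / normalizer$scale[ci]
  }
  g <- glucose_stats(normalizer)
  list(x = x, y = (windows$y - g$center) / g$scale)
}

#' @rdname normalize_windows
#' @param y_norm Normalized glucose values.
#' @export
denormalize_glucose <- function(y_norm, normalizer) {
  g <- glucose_stats(normalizer)
  y_norm * g$scale + g$center
}
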