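# Seeded synthetic CGM cohort generator.
#
# The generator is constraint-driven, not a pharmacokinetic model: glucose is
# baseline + diurnal oscillation + log-normal-shaped meal responses +
# exponential-decay insulin declines + AR(1) sensor noise, hard-bounded to
# the physiological plausibility range 2.8-22.2 mmol/L.  Sampling follows
# the clinical wear schedule: 1-min readings 08:00-20:00 and 10-min readings
# overnight, for 7-14 day wear periods.

GLUCOSE_LOW <- 2.8
GLUCOSE_HIGH <- 22.2

#' Simulation configuration
#'
#' @param n_patients Number of patients in the cohort.
#' @param wear_days Sensor wear period in days.  Clinical wear is 7-14 days
#'   (the default 7); values from 1 day are accepted for scaled-down
#'   experiments.
#' @param day_interval,night_interval Sampling intervals in minutes during
#'   the day (08:00-20:00, default 1) and night (default 10);
#'   `day_interval` must divide `night_interval`.
#' @param start Wear start (ISO datetime, must fall at `day_start`).
#' @param day_start,day_end Day-period boundaries as minutes of the clock
#'   day (defaults 08:00 and 20:00).
#' @param covariate_noise Multiplier on covariate drift/noise amplitudes;
#'   0 makes the working current an exact linear map of glucose.
#' @param seed Integer master seed; every patient derives an independent
#'   stream from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 3, wear_days = 7, day_interval = 1,
                       night_interval = 10, start = "2025-04-01 08:00:00",
                       day_start = 480, day_end = 1200,
                       covariate_noise = 1, seed = 1L) {
  if (day_interval <= 0 || night_interval <= 0) abort("intervals must be positive.")
  if (night_interval %% day_interval != 0) {
    abort("`day_interval` must divide `night_interval`.")
  }
  if (wear_days < 1 || wear_days > 14) {
    abort("`wear_days` must be in [1, 14] (clinical wear is 7-14 days).")
  }
  start_ct <- as.POSIXct(start, tz = "UTC")
  start_min <- as.integer(format(start_ct, "%H")) * 60L +
    as.integer(format(start_ct, "%M"))
  if (start_min != day_start) abort("wear must start at `day_start`.")
  structure(list(n_patients = as.integer(n_patients),
                 wear_days = as.integer(wear_days),
                 day_interval = as.integer(day_interval),
                 night_interval = as.integer(night_interval),
                 start = start_ct, day_start = as.integer(day_start),
                 day_end = as.integer(day_end),
                 covariate_noise = covariate_noise, seed = as.integer(seed)),
            class = "sim_config")
}

#' Patient profile for the synthetic generator
#'
#' @param patient_id Integer id.
#' @param age Age in years.
#' @param sex_code 0 = male, 1 = female.
#' @param type_code 0 = healthy, 1 = type-1 diabetes, 2 = type-2 diabetes.
#' @param sensor_k Sensor sensitivity (nA per mmol/L).
#' @param baseline_glucose Basal glucose, mmol/L.
#' @param meal_schedule Tibble with columns `clock` (minute of day) and
#'   `amplitude` (peak glucose rise, mmol/L), applied every wear day.
#' @param insulin_events Tibble with columns `clock` and `amplitude`
#'   (glucose drop, mmol/L), applied every wear day.
#' @param diurnal_amp Amplitude of the circadian oscillation, mmol/L.
#' @param noise_sd Sensor noise standard deviation, mmol/L.
#' @param noise_ar Lag-1 autocorrelation of the sensor noise.
#' @param missing_rate Fraction of readings dropped, in `[0, 0.10]`.
#' @param outlier_rate Fraction of readings replaced by out-of-range values,
#'   in `[0, 0.01]`.
#' @return A list of class `patient_profile`.
#' @export
patient_profile <- function(patient_id, age = 55, sex_code = 0, type_code = 0,
                            sensor_k = 2.5, baseline_glucose = 5.5,
                            meal_schedule = default_meals(type_code),
                            insulin_events = default_insulin(type_code),
                            diurnal_amp = 0.3, noise_sd = 0.15,
                            noise_ar = 0.7, missing_rate = 0.02,
                            outlier_rate = 0.003) {
  if (!sex_code %in% c(0, 1)) abort("`sex_code` must be 0 (male) or 1 (female).")
  if (!type_code %in% c(0, 1, 2)) {
    abort("`type_code` must be 0 (healthy), 1 (type 1) or 2 (type 2).")
  }
  if (missing_rate < 0 || missing_rate > 0.10) {
    abort("`missing_rate` must be in [0, 0.10].")
  }
  if (outlier_rate < 0 || outlier_rate > 0.01) {
    abort("`outlier_rate` must be in [0, 0.01].")
  }
  structure(list(patient_id = as.integer(patient_id), age = age,
                 sex_code = sex_code, type_code = type_code,
                 sensor_k = sensor_k, baseline_glucose = baseline_glucose,
                 meal_schedule = meal_schedule,
                 insulin_events = insulin_events,
                 diurnal_amp = diurnal_amp, noise_sd = noise_sd,
                 noise_ar = noise_ar, missing_rate = missing_rate,
                 outlier_rate = outlier_rate),
            class = "patient_profile")
}

default_meals <- function(type_code) {
  amp <- if (type_code == 0) 2 else 3.2
  tibble(clock = c(7.5, 12, 18.5) * 60, amplitude = amp * c(1, 1.15, 1.25))
}

default_insulin <- function(type_code) {
  if (type_code == 0) return(tibble(clock = numeric(0), amplitude = numeric(0)))
  tibble(clock = c(12.5, 19) * 60, amplitude = c(1.2, 1.5))
}

#' Draw a cohort of patient profiles
#'
#' Demographics follow the composition of a mixed inpatient CGM cohort:
#' 60% healthy / 4% type-1 / 36% type-2, ages ~ N(56, 13) within 28-78,
#' 60/40 male/female; a minority of patients carries an elevated missing
#' rate (5.2-7.8%) while the rest stay below 2%; out-of-range artifact
#' rates stay below 0.5%.
#'
#' @param n Number of patients.
#' @param seed Integer seed.
#' @return A list of [patient_profile()] objects.
#' @export
sim_profiles <- function(n, seed = 1L) {
  withr::with_seed(seed, {
    lapply(seq_len(n) - 1L, function(id) {
      type <- sample(c(0, 1, 2), 1, prob = c(0.60, 0.04, 0.36))
      base <- switch(as.character(type), "0" = stats::runif(1, 4.8, 6.0),
                     "1" = stats::runif(1, 6.5, 9.0),
                     "2" = stats::runif(1, 6.0, 8.5))
      high_missing <- stats::runif(1) < 0.12
      patient_profile(
        patient_id = id,
        age = round(min(78, max(28, stats::rnorm(1, 56.3, 12.7)))),
        sex_code = stats::rbinom(1, 1, 0.4),
        type_code = type,
        sensor_k = stats::runif(1, 1.8, 3.4),
        baseline_glucose = base,
        diurnal_amp = stats::runif(1, 0.2, 0.5),
        noise_sd = stats::runif(1, 0.10, 0.20),
        missing_rate = if (high_missing) stats::runif(1, 0.052, 0.078)
                       else stats::runif(1, 0.005, 0.02),
        outlier_rate = stats::runif(1, 0.002, 0.005)
      )
    })
  })
}

# sampling schedule in minutes since wear start (endpoint included so a
# k-day wear spans exactly k*1440 minutes)
schedule_minutes <- function(config) {
  per_day <- function(d0) {
    day <- seq(0L, config$day_end - config$day_start - 1L, config$day_interval)
    night <- seq(config$day_end - config$day_start,
                 1439L, config$night_interval)
    d0 + c(day, night)
  }
  mins <- unlist(lapply((seq_len(config$wear_days) - 1L) * 1440L, per_day))
  c(mins, config$wear_days * 1440L)
}

# log-normal-shaped meal response, peak at `peak` minutes, unit amplitude.
# Its 15-min value is ~0.05 of the peak, so the post-meal 15-min increment
# stays well under the 5 mmol/L physiological cap for any realistic peak.
meal_kernel <- function(tau, peak = 45, sigma = 0.55) {
  out <- numeric(length(tau))
  pos <- tau > 0
  out[pos] <- exp(-(log(tau[pos] / peak))^2 / (2 * sigma^2))
  out
}

insulin_kernel <- function(tau, onset = 20, decay = 90) {
  out <- numeric(length(tau))
  pos <- tau > 0
  out[pos] <- (1 - exp(-tau[pos] / onset)) * exp(-tau[pos] / decay)
  out
}

#' Simulate one patient's glucose trace
#'
#' Latent glucose is baseline + circadian oscillation + daily meal responses
#' + daily insulin declines; additive AR(1) sensor noise is applied on top
#' and the result is bounded to the 2.8-22.2 mmol/L plausibility range.
#' Readings follow the day/night sampling schedule of `config`.  Identical
#' `(profile, config)` produce bitwise-identical traces.
#'
#' @param profile A [patient_profile()].
#' @param config A [sim_config()].
#' @return A tibble: `time` (POSIXct), `minute` (since wear start),
#'   `glucose` (mmol/L), `patient_id`.
#' @export
simulate_glucose_trace <- function(profile, config) {
  stopifnot(inherits(profile, "patient_profile"), inherits(config, "sim_config"))
  mins <- schedule_minutes(config)
  clock <- (config$day_start + mins) %% 1440
  g <- rep(profile$baseline_glucose, length(mins))
  g <- g + profile$diurnal_amp * sin(2 * pi * (clock - 180) / 1440)
  for (d in seq_len(config$wear_days) - 1L) {
    off <- d * 1440
    ms <- profile$meal_schedule
    for (i in seq_len(nrow(ms))) {
      tau <- mins - (off + (ms$clock[i] - config$day_start) %% 1440)
      g <- g + ms$amplitude[i] * meal_kernel(tau)
    }
    ie <- profile$insulin_events
    for (i in seq_len(nrow(ie))) {
      tau <- mins - (off + (ie$clock[i] - config$day_start) %% 1440)
      g <- g - ie$amplitude[i] * insulin_kernel(tau)
    }
  }
  if (profile$noise_sd > 0) {
    withr::with_seed(config$seed * 1000L + profile$patient_id, {
      z <- stats::rnorm(length(mins))
      e <- numeric(length(mins))
      e[1] <- profile$noise_sd * z[1]
      a <- profile$noise_ar
      s <- profile$noise_sd * sqrt(1 - a^2)
      for (t in seq_along(mins)[-1]) e[t] <- a * e[t - 1] + s * z[t]
      g <- g + e
    })
  }
  g <- pmin(pmax(g, GLUCOSE_LOW), GLUCOSE_HIGH)
  tibble(time = config$start + mins * 60, minute = mins, glucose = g,
         patient_id = profile$patient_id)
}

#' Simulate sensor and demographic covariates for a glucose trace
#'
#' The working current `WE1` is `sensor_k * glucose` plus slow drift and
#' noise (positively correlated with glucose by construction); the contrast
#' current `WE2` is glucose-independent noise; `Temperature` is a bounded
#' diurnal oscillation; `Battery Voltage` declines monotonically.  Static
#' fields (`age`, `sex`, `type`, `sensor_r`, `sensor_k`, ids) are copied
#' from the profile.  All drift/noise amplitudes scale with
#' `config$covariate_noise`; at 0 the working current is an exact linear
#' map of glucose.
#'
#' @param glucose Output of [simulate_glucose_trace()].
#' @param profile,config The same profile and config.
#' @return The glucose tibble extended with the full sensor-record columns.
#' @export
simulate_covariates <- function(glucose, profile, config) {
  if (nrow(glucose) == 0L) abort("empty glucose series.")
  if (!identical(glucose$patient_id[1], profile$patient_id)) {
    abort("profile / series patient mismatch.")
  }
  n <- nrow(glucose)
  mins <- glucose$minute
  cn <- config$covariate_noise
  total <- max(mins)
  withr::with_seed(config$seed * 1000L + profile$patient_id * 7L + 3L, {
    drift <- cn * 0.4 * sin(2 * pi * mins / (2.5 * 1440)) +
      cn * 0.2 * (mins / max(total, 1))
    we1 <- profile$sensor_k * glucose$glucose + drift +
      cn * 0.3 * stats::rnorm(n)
    z <- stats::rnorm(n)
    we2 <- numeric(n)
    we2[1] <- z[1]
    for (t in seq_len(n)[-1]) we2[t] <- 0.9 * we2[t - 1] + sqrt(1 - 0.81) * z[t]
    we2 <- 2 + cn * 0.5 * we2
    temp <- 36.4 + 0.6 * sin(2 * pi * (((config$day_start + mins) %% 1440) - 240) / 1440) +
      cn * 0.05 * stats::rnorm(n)
    temp <- pmin(pmax(temp, 34), 39)
    batt <- 4.2 - 0.5 * mins / (14 * 1440) -
      cumsum(abs(cn * 1e-4 * stats::rnorm(n)))
    glucose$age <- profile$age
    glucose$sex <- profile$sex_code
    glucose$type <- profile$type_code
    glucose$sensor_r <- 0.995
    glucose$sensor_k <- profile$sensor_k
    glucose$needle_id <- 1000L + profile$patient_id
    glucose$sensor_id <- 2000L + profile$patient_id
    glucose$WE1 <- we1
    glucose$WE2 <- we2
    glucose$ratio <- we1 / we2
    glucose$Temperature <- temp
    glucose$`Battery Voltage` <- batt
  })
  glucose
}

#' Inject missingness and out-of-range artifacts
#'
#' Marks a deterministic quota `round(missing_rate * n)` of readings missing
#' and replaces `round(outlier_rate * n)` readings with values outside the
#' 2.8-22.2 mmol/L range.  Positions are drawn without replacement from a
#' seeded permutation (never the first reading, which forward imputation
#' requires observed); flags `is_missing` / `is_outlier` record them.
#'
#' @param data A per-patient sensor tibble (from [simulate_covariates()]).
#' @param profile The patient's [patient_profile()] (carries the rates).
#' @param seed Integer seed.
#' @return `data` with artifacts applied and flag columns added.
#' @export
inject_artifacts <- function(data, profile, seed) {
  n <- nrow(data)
  n_miss <- round(profile$missing_rate * n)
  n_out <- round(profile$outlier_rate * n)
  data$is_missing <- FALSE
  data$is_outlier <- FALSE
  if (n_miss + n_out == 0L) return(data)
  withr::with_seed(seed, {
    pos <- sample(2:n, n_miss + n_out)
    miss <- pos[seq_len(n_miss)]
    out <- pos[n_miss + seq_len(n_out)]
    data$glucose[miss] <- NA_real_
    data$is_missing[miss] <- TRUE
    if (n_out > 0L) {
      hi <- stats::runif(n_out) < 0.5
      data$glucose[out] <- ifelse(hi, stats::runif(n_out, 23, 30),
                                  stats::runif(n_out, 0.5, 2.5))
      data$is_outlier[out] <- TRUE
    }
  })
  data
}

#' Simulate a full synthetic CGM cohort
#'
#' Convenience wrapper: draws profiles (unless supplied), simulates each
#' patient's glucose trace and covariates, and injects artifacts.
#'
#' @param config A [sim_config()].
#' @param profiles Optional list of [patient_profile()]s (defaults to
#'   [sim_profiles()] drawn from `config$seed`).
#' @param artifacts Apply missingness/outlier artifacts (default TRUE).
#' @return A tibble with one row per reading across all patients.
#' @export
simulate_cohort <- function(config, profiles = NULL, artifacts = TRUE) {
  profiles <- profiles %||% sim_profiles(config$n_patients, config$seed)
  dplyr::bind_rows(lapply(profiles, function(pr) {
    g <- simulate_glucose_trace(pr, config)
    d <- simulate_covariates(g, pr, config)
    if (artifacts) {
      d <- inject_artifacts(d, pr, config$seed * 1000L + pr$patient_id * 13L + 5L)
    } else {
      d$is_missing <- FALSE
      d$is_outlier <- FALSE
    }
    d
  }))
}
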