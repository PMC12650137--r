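# Shared fixtures, all generated in code.

quiet_profile <- function(id = 0L, ...) {
  patient_profile(patient_id = id,
                  meal_schedule = tibble::tibble(clock = numeric(0),
                                                 amplitude = numeric(0)),
                  insulin_events = tibble::tibble(clock = numeric(0),
                                                  amplitude = numeric(0)),
                  diurnal_amp = 0, noise_sd = 0, missing_rate = 0,
                  outlier_rate = 0, ...)
}

one_day_config <- function(seed = 1L, ...) {
  sim_config(n_patients = 1, wear_days = 1, seed = seed, ...)
}

# minimal single-patient tibble on a uniform 1-min grid, for preprocessing
# tests that need full control over the glucose values
toy_series <- function(glucose, patient_id = 0L, interval = 1) {
  n <- length(glucose)
  tibble::tibble(
    time = as.POSIXct("2025-04-01 08:00:00", tz = "UTC") +
      (seq_len(n) - 1L) * 60 * interval,
    minute = (seq_len(n) - 1L) * interval,
    glucose = glucose,
    patient_id = as.integer(patient_id)
  )
}

# small repaired multi-channel series for windowing tests
toy_channels <- function(n, patient_id = 0L) {
  d <- toy_series(5 + sin(seq_len(n) / 10), patient_id)
  d$WE1 <- 2.5 * d$glucose
  d$age <- 60
  d
}

# scalar-loop oracle for the two-layer convolution operator: replicate
# padding, conv, tanh, conv -- written element-by-element, independently of
# the package's matrix implementation
oracle_convmod <- function(x, W1, b1, W2, b2) {
  conv_ref <- function(x, W, b) {
    k <- dim(W)[1]; cin <- dim(W)[2]; cout <- dim(W)[3]
    T <- nrow(x); p <- (k - 1) %/% 2
    y <- matrix(0, T, cout)
    for (t in seq_len(T)) {
      for (o in seq_len(cout)) {
        acc <- b[o]
        for (j in seq_len(k)) {
          s <- min(max(t + j - 1 - p, 1), T)
          for (ci in seq_len(cin)) acc <- acc + x[s, ci] * W[j, ci, o]
        }
        y[t, o] <- acc
      }
    }
    y
  }
  conv_ref(tanh(conv_ref(x, W1, b1)), W2, b2)
}

# scalar-loop oracle for the interaction equations, optionally with
# covariate conditioning of the gating operators
oracle_interact <- function(fo, fe, params, signs = c(1, -1), clamp = 10,
                            co = NULL, ce = NULL) {
  g <- function(prefix, x) {
    oracle_convmod(x, params[[paste0(prefix, ".W1")]],
                   params[[paste0(prefix, ".b1")]],
                   params[[paste0(prefix, ".W2")]],
                   params[[paste0(prefix, ".b2")]])
  }
  in_phi <- if (is.null(ce)) fe else cbind(fe, ce)
  in_psi <- if (is.null(co)) fo else cbind(fo, co)
  fos <- fo * exp(pmin(pmax(g("phi", in_phi), -clamp), clamp))
  fes <- fe * exp(pmin(pmax(g("psi", in_psi), -clamp), clamp))
  list(odd = fos + signs[1] * g("rho", fes),
       even = fes + signs[2] * g("eta", fos))
}

# random non-degenerate SCI-Block parameters (the constructor zero-inits the
# final conv; tests that need a generic block randomize it)
random_block_params <- function(channels, kernel = 3, hidden = 2,
                                cov_width = 0, seed = 1) {
  p <- sci_block_params(channels, kernel, hidden, cov_width, seed = seed)
  withr::with_seed(seed + 1000, {
    for (nm in names(p)) {
      p[[nm]] <- array(stats::rnorm(length(p[[nm]]), 0, 0.4),
                       dim(p[[nm]]) %||% length(p[[nm]]))
    }
  })
  p
}

`%||%` <- rlang::`%||%`
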