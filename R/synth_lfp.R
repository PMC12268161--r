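#' Parameters of the stimulation-dependent LFP plant
#'
#' The plant emulates an STN LFP channel whose beta bursts shorten with
#' stimulation amplitude: a 1/f^alpha Gaussian background, a beta oscillation
#' gated by bursts with Poisson-like onsets and gamma-distributed durations
#' whose mean follows `max(d_floor_s, d0_s - k_s_per_ma * amplitude)`,
#' band-limited high-frequency (45-65 Hz) noise that sets the detection
#' threshold floor, and an additive exponential artifact transient after each
#' stimulation step.
#'
#' @param rate Sampling rate in Hz (default 500).
#' @param one_over_f_exponent Power-law exponent alpha of the background
#'   (default 1).
#' @param beta_center_hz Beta oscillation frequency (default 15).
#' @param burst_rate_hz Mean burst rate in bursts/s (default 1).
#' @param d0_s Mean burst duration at 0 mA (default 0.4 s).
#' @param k_s_per_ma Duration shortening per mA (default 0.08 s/mA).
#' @param d_floor_s Floor of the mean duration (default 0.1 s).
#' @param shape Gamma shape of the duration distribution (default 3).
#' @param burst_amp Beta oscillation amplitude during bursts (default 1).
#' @param bg_sd Standard deviation of the broadband background (default 0.25).
#' @param gamma_sd Standard deviation of the extra 45-65 Hz noise that sets
#'   the detection floor (default 1.2; the resulting power threshold is about
#'   0.07 for the default background, so the default burst SNR
#'   `burst_amp^2 / threshold` is roughly 14).
#' @param artifact_peak Peak of the stimulation-change artifact (default 10).
#' @param artifact_tau_s Exponential decay constant of the artifact
#'   (default 0.1 s).
#' @param min_gap_s Minimum gap between consecutive bursts (default 0.1 s).
#' @param edge_s Raised-cosine burst edge duration (default 0.05 s).
#' @return A `plant_params` list.
#' @export
plant_params <- function(rate = 500, one_over_f_exponent = 1,
                         beta_center_hz = 15, burst_rate_hz = 1,
                         d0_s = 0.4, k_s_per_ma = 0.08, d_floor_s = 0.1,
                         shape = 3, burst_amp = 1, bg_sd = 0.25,
                         gamma_sd = 1.2, artifact_peak = 10,
                         artifact_tau_s = 0.1, min_gap_s = 0.1,
                         edge_s = 0.05) {
  stopifnot(rate > 0, d_floor_s > 0, k_s_per_ma >= 0, shape > 0,
            bg_sd >= 0, gamma_sd >= 0, burst_rate_hz > 0)
  structure(as.list(environment()), class = "plant_params")
}

# one-pole/one-zero cascade approximating a 1/f^(alpha/2) amplitude response:
# poles log-spaced at density `per_decade`, each zero a factor
# 10^(alpha / (2 * per_decade)) above its pole, bilinear-free direct mapping.
pink_cascade <- function(alpha, rate, f_lo = 0.08, f_hi = 200,
                         per_decade = 3) {
  fp <- 10^seq(log10(f_lo), log10(f_hi), by = 1 / per_decade)
  fz <- fp * 10^(alpha / (2 * per_decade))
  a <- exp(-2 * pi * fp / rate)
  b <- exp(-2 * pi * fz / rate)
  # overall white->output power gain on a fine grid, for unit-variance scaling
  f <- seq(0.25, rate / 2, by = 0.25)
  z1 <- exp(-2i * pi * f / rate)
  H <- rep(1 + 0i, length(f))
  for (i in seq_along(a)) H <- H * (1 - b[i] * z1) / (1 - a[i] * z1)
  list(a = a, b = b, scale = 1 / sqrt(mean(Mod(H)^2)),
       x_prev = numeric(length(a)), y_prev = numeric(length(a)))
}

cascade_filter <- function(cas, x) {
  for (i in seq_along(cas$a)) {
    u <- x - cas$b[i] * c(cas$x_prev[i], x[-length(x)])
    cas$x_prev[i] <- x[length(x)]
    y <- as.numeric(stats::filter(u, cas$a[i], method = "recursive",
                                  init = cas$y_prev[i]))
    cas$y_prev[i] <- y[length(y)]
    x <- y
  }
  list(cas = cas, values = x * cas$scale)
}

#' Create a closed-loop LFP plant
#'
#' The plant is stateful: [plant_step()] emits successive chunks whose burst
#' statistics follow the duration law at the amplitude in force when each
#' burst starts. Output is chunk-invariant: any sequence of `plant_step`
#' calls realising the same amplitude schedule yields the identical signal
#' for the same seed.
#'
#' @param params A [plant_params()].
#' @param seed Integer seed.
#' @return An `lfp_plant` environment.
#' @export
lfp_plant <- function(params = plant_params(), seed = 1) {
  stopifnot(inherits(params, "plant_params"))
  e <- new.env(parent = emptyenv())
  e$params <- params
  e$s_bg <- rng_stream(child_seed(seed, 1))
  e$s_gamma <- rng_stream(child_seed(seed, 2))
  e$s_burst <- rng_stream(child_seed(seed, 3))
  e$cascade <- pink_cascade(params$one_over_f_exponent, params$rate)
  gspec <- design_fir_bandpass(55, 20, FIR_ORDER, params$rate)
  e$gamma_b <- gspec$b
  e$gamma_carry <- numeric(0)
  e$n <- 0L                     # samples emitted
  e$active <- list()            # bursts possibly overlapping future samples
  e$next_onset <- rng_draw(e$s_burst, function()
    stats::rexp(1, params$burst_rate_hz))
  e$truth_onset <- numeric(0)
  e$truth_dur <- numeric(0)
  e$truth_amp <- numeric(0)
  e$steps <- numeric(0)         # stimulation-change times (artifact sources)
  class(e) <- "lfp_plant"
  e
}

burst_envelope_shape <- function(t, onset, dur, edge) {
  edge <- min(edge, dur / 2)
  u <- t - onset
  w <- numeric(length(t))
  inside <- u >= 0 & u < dur
  w[inside] <- 1
  if (edge > 0) {
    ramp_in <- u >= 0 & u < edge
    w[ramp_in] <- 0.5 * (1 - cos(pi * u[ramp_in] / edge))
    ramp_out <- u >= dur - edge & u < dur
    w[ramp_out] <- 0.5 * (1 - cos(pi * (dur - u[ramp_out]) / edge))
  }
  w
}

#' Emit the next LFP chunk at a given stimulation amplitude
#'
#' @param plant An [lfp_plant()].
#' @param amplitude_ma Current stimulation amplitude in mA.
#' @param dt_s Chunk duration in seconds (at least one sample).
#' @return Numeric vector of LFP samples.
#' @export
plant_step <- function(plant, amplitude_ma, dt_s) {
  stopifnot(inherits(plant, "lfp_plant"))
  p <- plant$params
  n <- round(dt_s * p$rate)
  if (n < 1L) stop("`dt_s` must cover at least one sample", call. = FALSE)
  t <- (plant$n + seq_len(n) - 1L) / p$rate
  t_end <- (plant$n + n) / p$rate

  res <- cascade_filter(plant$cascade,
                        rng_draw(plant$s_bg, function() stats::rnorm(n)))
  plant$cascade <- res$cas
  x <- res$values * p$bg_sd

  if (p$gamma_sd > 0) {
    w <- rng_draw(plant$s_gamma, function() stats::rnorm(n)) * p$gamma_sd
    y <- as.numeric(signal::filter(plant$gamma_b, 1, c(plant$gamma_carry, w)))
    x <- x + y[(length(plant$gamma_carry) + 1L):length(y)]
    plant$gamma_carry <- utils::tail(c(plant$gamma_carry, w),
                                     length(plant$gamma_b) - 1L)
  }

  # materialise bursts whose onsets fall before the chunk end
  while (plant$next_onset < t_end) {
    m <- max(p$d_floor_s, p$d0_s - p$k_s_per_ma * amplitude_ma)
    dur <- rng_draw(plant$s_burst, function()
      stats::rgamma(1, shape = p$shape, rate = p$shape / m))
    plant$active[[length(plant$active) + 1L]] <-
      c(onset = plant$next_onset, dur = dur)
    plant$truth_onset <- c(plant$truth_onset, plant$next_onset)
    plant$truth_dur <- c(plant$truth_dur, dur)
    plant$truth_amp <- c(plant$truth_amp, amplitude_ma)
    gap <- rng_draw(plant$s_burst, function()
      stats::rexp(1, p$burst_rate_hz))
    plant$next_onset <- plant$next_onset + dur + p$min_gap_s + gap
  }

  if (length(plant$active)) {
    keep <- logical(length(plant$active))
    for (i in seq_along(plant$active)) {
      bu <- plant$active[[i]]
      if (bu["onset"] + bu["dur"] <= t[1L]) next
      keep[i] <- bu["onset"] + bu["dur"] > t_end
      w <- burst_envelope_shape(t, bu["onset"], bu["dur"], p$edge_s)
      x <- x + p$burst_amp * w * sin(2 * pi * p$beta_center_hz * t)
    }
    plant$active <- plant$active[keep]
  }

  if (length(plant$steps)) {
    recent <- plant$steps[plant$steps > t[1L] - 10 * p$artifact_tau_s]
    for (t0 in recent) {
      after <- t >= t0
      x[after] <- x[after] +
        p$artifact_peak * exp(-(t[after] - t0) / p$artifact_tau_s)
    }
    plant$steps <- recent
  }

  plant$n <- plant$n + n
  x
}

#' Notify the plant of a stimulation change
#'
#' Injects the artifact transient (additive exponential decay) that follows
#' every increment or decrement of stimulation.
#'
#' @param plant An [lfp_plant()].
#' @param time_s Time of the stimulation change in seconds.
#' @return The plant, invisibly.
#' @export
plant_register_step <- function(plant, time_s) {
  stopifnot(inherits(plant, "lfp_plant"))
  plant$steps <- c(plant$steps, time_s)
  invisible(plant)
}

#' Ground-truth bursts planted so far
#'
#' @param plant An [lfp_plant()].
#' @param within_s Keep only bursts that end before this time (defaults to
#'   the emitted duration).
#' @return Data frame with `onset_s`, `duration_s`, `offset_s`,
#'   `amplitude_ma` (the stimulation amplitude when the burst started).
#' @export
plant_truth <- function(plant, within_s = NULL) {
  stopifnot(inherits(plant, "lfp_plant"))
  within_s <- within_s %||% (plant$n / plant$params$rate)
  df <- data.frame(onset_s = plant$truth_onset,
                   duration_s = plant$truth_dur,
                   offset_s = plant$truth_onset + plant$truth_dur,
                   amplitude_ma = plant$truth_amp)
  df[df$offset_s <= within_s, , drop = FALSE]
}

#' Generate a synthetic LFP recording
#'
#' One-shot wrapper around the plant: runs [plant_step()] over a constant
#' amplitude or an amplitude trace, registering the stimulation-change
#' artifact at every amplitude change.
#'
#' @param params A [plant_params()].
#' @param stim Constant amplitude in mA, or an amplitude `ts_series`.
#' @param duration_s Recording duration in seconds (taken from `stim` when it
#'   is a series).
#' @param seed Integer seed.
#' @param chunk_s Internal chunk size in seconds (default 1).
#' @return List with `lfp` (a `ts_series`), `truth` (planted burst data
#'   frame), `params`, `seed`.
#' @export
synth_lfp <- function(params = plant_params(), stim = 0, duration_s = 60,
                      seed = 1, chunk_s = 1) {
  plant <- lfp_plant(params, seed)
  if (inherits(stim, "ts_series")) {
    amps <- stim$values
    dt <- 1 / stim$rate
  } else {
    n_chunks <- ceiling(duration_s / chunk_s)
    amps <- rep(stim, n_chunks)
    dt <- chunk_s
  }
  out <- vector("list", length(amps))
  prev_amp <- amps[1L]
  for (i in seq_along(amps)) {
    if (amps[i] != prev_amp) plant_register_step(plant, (i - 1L) * dt)
    prev_amp <- amps[i]
    out[[i]] <- plant_step(plant, amps[i], dt)
  }
  lfp <- time_series(unlist(out), rate = params$rate, units = "a.u.",
                     label = "lfp")
  list(lfp = lfp, truth = plant_truth(plant), params = params, seed = seed)
}
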