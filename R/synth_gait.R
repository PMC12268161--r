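#' Parameters for synthetic stepping-in-place trials
#'
#' @param cadence_hz Stride rate in strides/s per leg (default 0.9).
#' @param swing_fraction Swing duration as a fraction of half the stride
#'   period (default 0.65).
#' @param stride_cv Stride-time coefficient of variation (default 0.03).
#' @param asym_factor Left/right swing-time ratio (default 1: symmetric).
#' @param freeze_fraction Fraction of the trial spent frozen (default 0).
#' @param freeze_style `"trembling"` (30-70 %BW oscillation at
#'   `tremble_hz`) or `"akinetic"` (static 50/50 loading).
#' @param tremble_hz Trembling frequency within the 3-8 Hz festination band
#'   (default 5).
#' @param body_weight_n Body weight in newtons (default 700).
#' @param duration_s Trial duration (default 100 s).
#' @param transfer_s Duration of each load-transfer ramp (default 0.12 s).
#' @return A `gait_params` list.
#' @export
gait_params <- function(cadence_hz = 0.9, swing_fraction = 0.65,
                        stride_cv = 0.03, asym_factor = 1,
                        freeze_fraction = 0,
                        freeze_style = c("trembling", "akinetic"),
                        tremble_hz = 5, body_weight_n = 700,
                        duration_s = 100, transfer_s = 0.12) {
  freeze_style <- match.arg(freeze_style)
  stopifnot(cadence_hz > 0, swing_fraction > 0, swing_fraction <= 1,
            stride_cv >= 0, asym_factor > 0,
            freeze_fraction >= 0, freeze_fraction <= 1,
            body_weight_n > 0, duration_s > 0)
  structure(as.list(environment()), class = "gait_params")
}

# fraction of a raised-cosine half-transfer (50 %BW <-> 0 %BW) elapsed when
# the unloading foot crosses `pct` %BW: force = 25 + 25 cos(pi u)
transfer_cross_frac <- function(pct) acos(pct / 25 - 1) / pi

#' Synthetic stepping-in-place trial with plantable freezes
#'
#' Generates smooth alternating load transfer between two force plates
#' (raised-cosine transfers) at the planted cadence, swing asymmetry and
#' stride-time variability; freeze episodes replace the alternation with
#' trembling (both plates oscillating within 30-70 %BW) or static 50/50
#' loading. Swing dwell times are constructed so the 20 %BW segmentation
#' criterion recovers the planted swing times.
#'
#' @param params A [gait_params()].
#' @param seed Integer seed.
#' @param rate Sampling rate in Hz (default 1000).
#' @return List with `trial` (a [force_trial()]) and `truth` (planted freeze
#'   intervals, per-leg swing/stride times, parameters echo).
#' @export
synth_sip <- function(params = gait_params(), seed = 1, rate = 1000) {
  stopifnot(inherits(params, "gait_params"))
  p <- params
  dur <- p$duration_s
  tt <- p$transfer_s
  stream <- rng_stream(child_seed(seed, 11))

  # schedule freeze episodes and stepping segments
  f_total <- p$freeze_fraction * dur
  if (p$freeze_fraction >= 0.99) {
    segs <- data.frame(kind = "freeze", len = dur)
  } else if (f_total <= 0) {
    segs <- data.frame(kind = "step", len = dur)
  } else {
    n_ep <- max(1L, min(floor(f_total / 8) + 1L,
                        floor((dur - f_total) / 2.5)))
    ep <- rng_draw(stream, function() stats::rexp(n_ep)) + 0.5
    ep <- ep / sum(ep) * f_total
    step_len <- rep((dur - f_total) / (n_ep + 1L), n_ep + 1L)
    kind <- c(rbind(rep("step", n_ep), rep("freeze", n_ep)), "step")
    len <- c(rbind(step_len[seq_len(n_ep)], ep), step_len[n_ep + 1L])
    segs <- data.frame(kind = kind, len = len)
  }

  n <- round(dur * rate)
  share <- numeric(0)            # left-foot share of body weight in [0, 1]
  truth_freeze <- NULL
  swing_l <- swing_r <- numeric(0)
  stride_l <- stride_r <- numeric(0)

  T0 <- 1 / p$cadence_hz
  w_base <- p$swing_fraction * T0 / 2
  w_l <- w_base * sqrt(p$asym_factor)
  w_r <- w_base / sqrt(p$asym_factor)
  # time spent below 20 %BW during the unload/reload ramps; the full-unload
  # dwell is shortened by this so the 20% crossings bracket the planted swing
  dwell_extra <- 2 * (1 - transfer_cross_frac(20)) * tt

  ramp <- function(from, to, len_s) {
    m <- max(2L, round(len_s * rate))
    from + (to - from) * 0.5 * (1 - cos(pi * seq(0, 1, length.out = m)))
  }
  cursor_t <- function() length(share) / rate

  for (si in seq_len(nrow(segs))) {
    seg_end <- sum(segs$len[seq_len(si)])
    if (segs$kind[si] == "freeze") {
      t0 <- cursor_t()
      cur <- if (length(share)) share[length(share)] else 0.5
      share <- c(share, ramp(cur, 0.5, tt / 2))
      m <- round(seg_end * rate) - length(share)
      if (m > 0) {
        tt_f <- (length(share) + seq_len(m) - 1) / rate
        vals <- if (p$freeze_style == "trembling") {
          # both plates oscillate inside 30-70 %BW, out of phase
          0.5 + 0.2 * sin(2 * pi * p$tremble_hz * tt_f) / 2 * 2
        } else rep(0.5, m)
        share <- c(share, pmin(pmax(vals, 0.3), 0.7))
      }
      truth_freeze <- rbind(truth_freeze, c(t0, cursor_t()))
    } else {
      # stride = double support, right swing, double support, left swing;
      # an integer number of jittered strides is rescaled to fill the
      # segment exactly so no quiet residue borders a freeze episode
      cur <- if (length(share)) share[length(share)] else 0.5
      if (abs(cur - 0.5) > 1e-6) share <- c(share, ramp(cur, 0.5, tt / 2))
      seg_len <- seg_end - cursor_t()
      n_str <- floor(seg_len / T0)
      if (n_str >= 1L) {
        j <- pmax(0.3, 1 + p$stride_cv *
                    rng_draw(stream, function() stats::rnorm(n_str)))
        j <- j * (seg_len / sum(T0 * j))
        for (jk in j) {
          dr <- max(w_r * jk - dwell_extra, 0.05)
          dl <- max(w_l * jk - dwell_extra, 0.05)
          ds <- max((T0 * jk - dr - dl - 4 * tt) / 2, 0.01)
          stride_len <- dr + dl + 2 * ds + 4 * tt
          share <- c(share, rep(0.5, round(ds * rate)))
          share <- c(share, ramp(0.5, 1, tt))            # right unloads
          share <- c(share, rep(1, round(dr * rate)))    # right swing
          share <- c(share, ramp(1, 0.5, tt))
          share <- c(share, rep(0.5, round(ds * rate)))
          share <- c(share, ramp(0.5, 0, tt))            # left unloads
          share <- c(share, rep(0, round(dl * rate)))    # left swing
          share <- c(share, ramp(0, 0.5, tt))
          swing_r <- c(swing_r, dr + dwell_extra)
          swing_l <- c(swing_l, dl + dwell_extra)
          stride_l <- c(stride_l, stride_len)
          stride_r <- c(stride_r, stride_len)
        }
      }
      m <- round(seg_end * rate) - length(share)
      if (m > 0) share <- c(share, rep(share[length(share)], m))
    }
  }
  share <- share[seq_len(min(n, length(share)))]
  if (length(share) < n) share <- c(share, rep(share[length(share)], n - length(share)))

  left <- p$body_weight_n * share
  right <- p$body_weight_n * (1 - share)
  trial <- force_trial(
    time_series(pmax(left, 0), rate, units = "N", label = "left"),
    time_series(pmax(right, 0), rate, units = "N", label = "right"),
    body_weight_n = p$body_weight_n
  )
  truth <- list(
    freeze_intervals = if (is.null(truth_freeze)) {
      data.frame(start_s = numeric(0), end_s = numeric(0))
    } else data.frame(start_s = truth_freeze[, 1L], end_s = truth_freeze[, 2L]),
    percent_time_freezing = 100 * p$freeze_fraction,
    swing_left_s = swing_l,
    swing_right_s = swing_r,
    stride_left_s = stride_l, stride_right_s = stride_r,
    asymmetry = 100 * abs(log(p$asym_factor)),
    params = p, seed = seed
  )
  list(trial = trial, truth = truth)
}

#' Parameters for synthetic turning-and-barrier-course IMU trials
#'
#' @param stride_s Stride period in seconds (default 1.1).
#' @param stride_cv Stride-time coefficient of variation (default 0.04).
#' @param swing_s Swing (pulse) duration in seconds (default 0.4).
#' @param peak_deg_s Peak sagittal angular velocity (default 300).
#' @param freeze_fraction Fraction of the trial frozen (default 0).
#' @param freeze_stride_s,freeze_peak_deg_s,freeze_swing_s,freeze_cv
#'   Stride period, peak velocity, swing duration and variability during
#'   freezes (defaults 0.55 s, 130 deg/s, 0.22 s, 0.25): short, shallow,
#'   irregular shuffling steps that still clear the stride-segmentation
#'   peak criterion.
#' @param noise_sd Per-axis gyroscope noise in deg/s (default 5).
#' @param duration_s Trial duration (default 60 s).
#' @param rate Sampling rate (default 128 Hz).
#' @return A `tbc_params` list.
#' @export
tbc_params <- function(stride_s = 1.1, stride_cv = 0.04, swing_s = 0.4,
                       peak_deg_s = 300, freeze_fraction = 0,
                       freeze_stride_s = 0.55, freeze_peak_deg_s = 130,
                       freeze_swing_s = 0.22, freeze_cv = 0.25,
                       noise_sd = 5, duration_s = 60, rate = 128) {
  stopifnot(stride_s > swing_s, freeze_fraction >= 0, freeze_fraction <= 1)
  structure(as.list(environment()), class = "tbc_params")
}

# random 3-D rotation matrix (uniform via QR of a Gaussian matrix)
random_rotation <- function(stream) {
  m <- matrix(rng_draw(stream, function() stats::rnorm(9)), 3L)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

#' Synthetic shank-IMU walking trial
#'
#' Per-stride raised-cosine sagittal angular-velocity pulses for both legs
#' (half a stride out of phase), embedded in a randomly rotated sensor frame
#' with additive gyroscope noise. Freeze episodes replace normal strides with
#' short, shallow, irregular pulses. The planted swing angular range of a
#' pulse equals `peak * swing / 2` degrees (the raised-cosine integral).
#'
#' @param params A [tbc_params()].
#' @param seed Integer seed.
#' @return List with `imu` (per-leg 3-axis [multi_channel()]), `truth`
#'   (per-leg stride tables with per-step freeze labels, freeze intervals,
#'   rotations) and `params`.
#' @export
synth_tbc <- function(params = tbc_params(), seed = 1) {
  stopifnot(inherits(params, "tbc_params"))
  p <- params
  stream <- rng_stream(child_seed(seed, 21))
  dur <- p$duration_s
  f_total <- p$freeze_fraction * dur
  if (p$freeze_fraction >= 0.99) {
    segs <- data.frame(kind = "freeze", len = dur)
  } else if (f_total <= 0) {
    segs <- data.frame(kind = "step", len = dur)
  } else {
    n_ep <- max(1L, min(floor(f_total / 6) + 1L,
                        floor((dur - f_total) / 4)))
    ep <- rng_draw(stream, function() stats::rexp(n_ep)) + 0.5
    ep <- ep / sum(ep) * f_total
    step_len <- rep((dur - f_total) / (n_ep + 1L), n_ep + 1L)
    segs <- data.frame(
      kind = c(rbind(rep("step", n_ep), rep("freeze", n_ep)), "step"),
      len = c(rbind(step_len[seq_len(n_ep)], ep), step_len[n_ep + 1L]))
  }

  n <- round(dur * p$rate)
  tms <- (seq_len(n) - 1) / p$rate
  sag <- list(left = numeric(n), right = numeric(n))
  truth_steps <- list()
  truth_freeze <- NULL
  t_cursor <- 0
  phase <- c(left = 0, right = 0.5)   # legs half a stride apart
  for (si in seq_len(nrow(segs))) {
    seg_end <- t_cursor + segs$len[si]
    frozen <- segs$kind[si] == "freeze"
    if (frozen) truth_freeze <- rbind(truth_freeze, c(t_cursor, seg_end))
    T0 <- if (frozen) p$freeze_stride_s else p$stride_s
    cvv <- if (frozen) p$freeze_cv else p$stride_cv
    pk <- if (frozen) p$freeze_peak_deg_s else p$peak_deg_s
    sw <- if (frozen) p$freeze_swing_s else p$swing_s
    for (leg in c("left", "right")) {
      t_next <- t_cursor + phase[[leg]] * T0
      while (t_next + sw < seg_end) {
        jit <- max(0.3, 1 + cvv * rng_draw(stream, function() stats::rnorm(1)))
        pk_j <- pk * max(0.3, 1 + 0.05 * rng_draw(stream, function() stats::rnorm(1)))
        idx <- which(tms >= t_next & tms < t_next + sw)
        if (length(idx)) {
          u <- (tms[idx] - t_next) / sw
          sag[[leg]][idx] <- sag[[leg]][idx] +
            pk_j * 0.5 * (1 - cos(2 * pi * u))
        }
        truth_steps[[length(truth_steps) + 1L]] <- data.frame(
          leg = leg, mid_swing_s = t_next + sw / 2, swing_s = sw * jit^0,
          stride_s = T0 * jit, peak_deg_s = pk_j,
          swing_range_deg = pk_j * sw / 2, freeze = as.integer(frozen))
        t_next <- t_next + T0 * jit
      }
    }
    t_cursor <- seg_end
  }
  steps <- do.call(rbind, truth_steps)
  steps <- steps[order(steps$mid_swing_s), ]

  build_imu <- function(leg) {
    rot <- random_rotation(stream)
    axes <- rot %*% rbind(sag[[leg]],
                          rng_draw(stream, function() stats::rnorm(n)) * p$noise_sd * 0.5,
                          rng_draw(stream, function() stats::rnorm(n)) * p$noise_sd * 0.5)
    axes <- axes + matrix(rng_draw(stream, function() stats::rnorm(3 * n)),
                          3L) * p$noise_sd
    chans <- lapply(1:3, function(i)
      time_series(axes[i, ], p$rate, units = "deg/s",
                  label = paste0(leg, "_g", i)))
    names(chans) <- paste0("g", 1:3)
    list(mc = multi_channel(chans, meta = list(placement = leg)), rot = rot)
  }
  li <- build_imu("left"); ri <- build_imu("right")
  truth <- list(
    steps = steps,
    freeze_intervals = if (is.null(truth_freeze)) {
      data.frame(start_s = numeric(0), end_s = numeric(0))
    } else data.frame(start_s = truth_freeze[, 1L], end_s = truth_freeze[, 2L]),
    percent_time_freezing = 100 * p$freeze_fraction,
    rotations = list(left = li$rot, right = ri$rot),
    params = p, seed = seed
  )
  list(imu = list(left = li$mc, right = ri$mc), truth = truth)
}

#' Synthetic wrist flexion-extension trial
#'
#' A sinusoidal flexion-extension angular velocity plus Gaussian noise; the
#' planted RMS velocity is `amplitude / sqrt(2)` and the planted rate is
#' `freq_hz`.
#'
#' @param freq_hz Oscillation frequency (default 1.5; below the 4 Hz analysis
#'   cut-off).
#' @param amplitude_deg_s Peak angular velocity (default 100).
#' @param noise_sd Additive noise in deg/s (default 5).
#' @param duration_s Trial duration (default 30 s).
#' @param rate Sampling rate (default 128 Hz).
#' @param seed Integer seed.
#' @return List with `hand` (a `ts_series`) and `truth`
#'   (`vrms`, `cycles_per_second`, `oscillatory` flag).
#' @export
synth_wrist <- function(freq_hz = 1.5, amplitude_deg_s = 100, noise_sd = 5,
                        duration_s = 30, rate = 128, seed = 1) {
  n <- round(duration_s * rate)
  t <- (seq_len(n) - 1) / rate
  stream <- rng_stream(child_seed(seed, 31))
  v <- amplitude_deg_s * sin(2 * pi * freq_hz * t) +
    rng_draw(stream, function() stats::rnorm(n)) * noise_sd
  truth <- list(vrms = amplitude_deg_s / sqrt(2),
                cycles_per_second = freq_hz,
                oscillatory = amplitude_deg_s > 0)
  list(hand = time_series(v, rate, units = "deg/s", label = "hand"),
       truth = truth)
}

#' Labelled synthetic stride corpus for freeze-model fitting
#'
#' Generates several IMU walking trials with planted freeze episodes, runs
#' the sagittal-extraction and stride-segmentation pipeline, computes the
#' rolling step features and labels every step by whether its mid-swing time
#' falls inside a planted freeze interval.
#'
#' @param n_trials Number of trials (default 4).
#' @param freeze_fraction Planted freeze fraction per trial (default 0.35).
#' @param seed Integer seed (trial k uses `seed + k`).
#' @param params A [tbc_params()] template (its `freeze_fraction` is
#'   overridden).
#' @return Data frame of steps with feature columns and a binary `freeze`
#'   label.
#' @export
synth_freeze_corpus <- function(n_trials = 4, freeze_fraction = 0.35,
                                seed = 1, params = tbc_params()) {
  params$freeze_fraction <- freeze_fraction
  out <- lapply(seq_len(n_trials), function(k) {
    x <- synth_tbc(params, seed = seed + k)
    lt <- segment_strides_imu(extract_sagittal(x$imu$left))
    rt <- segment_strides_imu(extract_sagittal(x$imu$right))
    st <- step_features(lt, rt)
    if (is.null(st)) return(NULL)
    fi <- x$truth$freeze_intervals
    st$freeze <- as.integer(vapply(st$mid_swing_s, function(t)
      any(fi$start_s <= t & t <= fi$end_s), logical(1)))
    st$trial <- k
    st
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}
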