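#' Therapeutic window
#'
#' The amplitude range the controller may use: `i_min_ma` is the smallest
#' amplitude giving acceptable therapeutic benefit, `i_max_ma` the largest
#' without adverse effects, never exceeding 125% of the clinically optimised
#' amplitude.
#'
#' @param i_min_ma,i_max_ma Window bounds in mA.
#' @param clinical_ma Clinical stimulation amplitude in mA.
#' @return A `therapeutic_window` object.
#' @export
therapeutic_window <- function(i_min_ma, i_max_ma, clinical_ma) {
  if (!(i_min_ma > 0 && i_min_ma <= i_max_ma))
    stop("need 0 < i_min <= i_max", call. = FALSE)
  if (i_max_ma > 1.25 * clinical_ma + 1e-9)
    stop("i_max exceeds 125% of the clinical amplitude", call. = FALSE)
  structure(list(i_min_ma = i_min_ma, i_max_ma = i_max_ma,
                 clinical_ma = clinical_ma), class = "therapeutic_window")
}

#' Ramp policy
#'
#' Sustained ramp rates and the discrete step size. The default ramp down is
#' half the ramp up, biasing stimulation towards higher amplitudes. Rate
#' limiting is realised as a per-direction minimum dwell: a step in direction
#' `d` executes only if at least `step_ma / rate(d)` seconds have elapsed
#' since the last executed step.
#'
#' @param up_ma_per_s Ramp-up rate in mA/s (default 0.1).
#' @param down_ma_per_s Ramp-down rate in mA/s (default half the up rate).
#' @param step_ma Increment/decrement step in mA (default 0.1).
#' @return A `ramp_policy` object.
#' @export
ramp_policy <- function(up_ma_per_s = 0.1, down_ma_per_s = up_ma_per_s / 2,
                        step_ma = 0.1) {
  if (up_ma_per_s <= 0 || down_ma_per_s <= 0 || step_ma <= 0)
    stop("ramp rates and step must be > 0", call. = FALSE)
  structure(list(up_ma_per_s = up_ma_per_s, down_ma_per_s = down_ma_per_s,
                 step_ma = step_ma), class = "ramp_policy")
}

# Stimulation constants shared by all conditions.
STIM_FREQUENCY_HZ <- 140.1
STIM_PULSE_WIDTH_S <- 60e-6

#' Per-hemisphere controller configuration
#'
#' @param band A [band_config()] (required for adaptive mode).
#' @param power_threshold Envelope power threshold.
#' @param duration_threshold_s Burst-duration threshold in seconds.
#' @param window A [therapeutic_window()].
#' @param ramp A [ramp_policy()].
#' @param mode `"adaptive"` or `"held_at_clinical"` (the unilateral case: the
#'   hemisphere is held at 100% clinical amplitude).
#' @param blank_s Detector blanking after each executed step (default 0.5 s).
#' @param side Label (e.g. `"left"`, `"right"`).
#' @return A `hemisphere_config` object.
#' @export
hemisphere_config <- function(band = NULL, power_threshold = NULL,
                              duration_threshold_s = NULL, window,
                              ramp = ramp_policy(),
                              mode = c("adaptive", "held_at_clinical"),
                              blank_s = 0.5, side = "") {
  mode <- match.arg(mode)
  if (mode == "adaptive") {
    stopifnot(inherits(band, "band_config"),
              is.numeric(power_threshold), power_threshold > 0,
              is.numeric(duration_threshold_s), duration_threshold_s > 0)
  }
  stopifnot(inherits(window, "therapeutic_window"), inherits(ramp, "ramp_policy"))
  structure(list(band = band, power_threshold = power_threshold,
                 duration_threshold_s = duration_threshold_s,
                 window = window, ramp = ramp, mode = mode,
                 blank_s = blank_s, side = side),
            class = "hemisphere_config")
}

#' Control policy decision
#'
#' The single-threshold rule: stimulation increases when the current beta
#' burst duration exceeds the participant-specific duration threshold and
#' decreases otherwise (ties decrement, since only strictly longer bursts
#' count as pathological).
#'
#' @param current_burst_duration_s Observed burst duration in seconds.
#' @param duration_threshold_s Duration threshold in seconds.
#' @return `+1` (increment) or `-1` (decrement).
#' @export
decide <- function(current_burst_duration_s, duration_threshold_s) {
  if (current_burst_duration_s < 0 || duration_threshold_s < 0)
    stop("durations must be >= 0", call. = FALSE)
  if (current_burst_duration_s > duration_threshold_s) 1L else -1L
}

# mutable per-hemisphere controller state
hemisphere_state <- function(cfg, init_ma = NULL) {
  e <- new.env(parent = emptyenv())
  e$amplitude_ma <- init_ma %||%
    (if (cfg$mode == "adaptive") cfg$window$i_min_ma else cfg$window$clinical_ma)
  e$last_step_time <- -Inf
  e$log <- list()
  class(e) <- "hemisphere_state"
  e
}

#' Attempt a ramp-limited stimulation step
#'
#' Executes a `+/- step_ma` change only if the per-direction minimum dwell
#' time (`step_ma / rate`) has elapsed since the last executed step and the
#' result stays inside the therapeutic window. Saturation at the window edge
#' is silent; every decision is logged with its executed flag.
#'
#' @param state A hemisphere state (internal to [run_adaptive()], also used by
#'   the rDBS replay).
#' @param cfg The [hemisphere_config()].
#' @param direction `+1` or `-1`.
#' @param now_s Decision time in seconds.
#' @param burst_s Burst duration that drove the decision (logged).
#' @return `TRUE` if the step executed.
#' @export
apply_step <- function(state, cfg, direction, now_s, burst_s = NA_real_) {
  stopifnot(inherits(state, "hemisphere_state"), direction %in% c(-1L, 1L))
  rate <- if (direction > 0) cfg$ramp$up_ma_per_s else cfg$ramp$down_ma_per_s
  dwell <- cfg$ramp$step_ma / rate
  target <- state$amplitude_ma + direction * cfg$ramp$step_ma
  executed <- (now_s - state$last_step_time >= dwell - 1e-9) &&
    target >= cfg$window$i_min_ma - 1e-9 &&
    target <= cfg$window$i_max_ma + 1e-9
  if (executed) {
    state$amplitude_ma <- target
    state$last_step_time <- now_s
  }
  state$log[[length(state$log) + 1L]] <-
    list(time_s = now_s, burst_s = burst_s, direction = direction,
         executed = executed, amplitude_ma = state$amplitude_ma)
  executed
}

decision_log_df <- function(state) {
  if (!length(state$log)) {
    return(data.frame(time_s = numeric(0), burst_s = numeric(0),
                      direction = integer(0), executed = logical(0),
                      amplitude_ma = numeric(0)))
  }
  do.call(rbind, lapply(state$log, as.data.frame))
}

#' Run the closed-loop adaptive controller
#'
#' Per hemisphere and decision period: ingest the next LFP chunk into the
#' streaming detector, read the current burst duration, apply the
#' single-threshold decision through the ramp machinery, and blank the
#' detector (and notify the plant, which injects a stimulation-change
#' artifact) whenever a step executes. Hemispheres are fully independent; a
#' `held_at_clinical` hemisphere keeps 100% clinical amplitude throughout.
#'
#' @param sources List of per-hemisphere signal sources: each an
#'   [lfp_plant()] (closed loop) or a [time_series()] (open loop replay).
#' @param configs List of [hemisphere_config()], same length as `sources`.
#' @param duration_s Run duration in seconds.
#' @param decision_period_s Decision cadence in seconds (default 1; matches a
#'   0.1 mA step at 0.1 mA/s so every up decision can execute).
#' @param init_ma Optional initial amplitudes (default: `i_min` for adaptive
#'   hemispheres, clinical for held ones).
#' @return A `loop_result` list: `stim` (list of amplitude `ts_series`, one
#'   per hemisphere, sampled at the decision cadence), `decisions` (list of
#'   data frames), `bursts` (list of data frames), `configs`.
#' @export
run_adaptive <- function(sources, configs, duration_s, decision_period_s = 1,
                         init_ma = NULL) {
  if (inherits(sources, c("lfp_plant", "ts_series"))) sources <- list(sources)
  if (inherits(configs, "hemisphere_config")) configs <- list(configs)
  stopifnot(length(sources) == length(configs))
  nh <- length(sources)
  n_ticks <- floor(duration_s / decision_period_s + 1e-9)
  if (n_ticks < 1) stop("duration shorter than one decision period", call. = FALSE)
  states <- vector("list", nh)
  detectors <- vector("list", nh)
  amps <- vector("list", nh)
  for (h in seq_len(nh)) {
    cfg <- configs[[h]]
    states[[h]] <- hemisphere_state(cfg, init_ma[h][[1]])
    if (cfg$mode == "adaptive")
      detectors[[h]] <- burst_detector(cfg$band, cfg$power_threshold)
    amps[[h]] <- numeric(n_ticks + 1L)
    amps[[h]][1L] <- states[[h]]$amplitude_ma
    if (inherits(sources[[h]], "ts_series") &&
        ts_duration(sources[[h]]) < duration_s - 1e-9)
      stop("recorded series shorter than the requested duration", call. = FALSE)
  }
  for (k in seq_len(n_ticks)) {
    t0 <- (k - 1L) * decision_period_s
    t1 <- k * decision_period_s
    for (h in seq_len(nh)) {
      cfg <- configs[[h]]
      st <- states[[h]]
      chunk <- source_chunk(sources[[h]], st$amplitude_ma, t0, t1)
      if (cfg$mode == "adaptive") {
        stream_process(detectors[[h]], chunk)
        d <- current_burst_duration(detectors[[h]])
        dir <- decide(d, cfg$duration_threshold_s)
        if (apply_step(st, cfg, dir, t1, burst_s = d)) {
          blank_interval(detectors[[h]], t1, cfg$blank_s)
          if (inherits(sources[[h]], "lfp_plant"))
            plant_register_step(sources[[h]], t1)
        }
      }
      amps[[h]][k + 1L] <- st$amplitude_ma
    }
  }
  stim <- lapply(seq_len(nh), function(h)
    time_series(amps[[h]], rate = 1 / decision_period_s, start = 0,
                units = "mA", label = configs[[h]]$side))
  bursts <- lapply(seq_len(nh), function(h) {
    if (is.null(detectors[[h]])) return(empty_bursts())
    fin <- try(detector_finalize(detectors[[h]]), silent = TRUE)
    out <- collected_bursts(detectors[[h]])
    out
  })
  structure(list(stim = stim,
                 decisions = lapply(states, decision_log_df),
                 bursts = bursts, configs = configs,
                 decision_period_s = decision_period_s),
            class = "loop_result")
}

# next chunk [t0, t1) from a plant (closed loop) or a recorded series
source_chunk <- function(src, amplitude_ma, t0, t1) {
  if (inherits(src, "lfp_plant")) {
    plant_step(src, amplitude_ma, t1 - t0)
  } else {
    i0 <- round((t0 - src$start) * src$rate) + 1L
    i1 <- round((t1 - src$start) * src$rate)
    src$values[i0:min(i1, length(src$values))]
  }
}

#' Continuous DBS trace
#'
#' @param clinical_ma Clinical amplitude in mA.
#' @param duration_s Trace duration in seconds.
#' @param rate Trace sampling rate in Hz (default 1).
#' @return A `ts_series` of constant amplitude.
#' @export
hold_continuous <- function(clinical_ma, duration_s, rate = 1) {
  if (clinical_ma <= 0) stop("`clinical_ma` must be > 0", call. = FALSE)
  n <- floor(duration_s * rate + 1e-9)
  time_series(rep(clinical_ma, n), rate = rate, units = "mA",
              label = "cDBS")
}

#' Total electrical energy delivered (unit-impedance proxy)
#'
#' `sum(I^2 * f * pw * dt)` over the trace with impedance normalised to 1 and
#' amplitude in mA; only ratios and differences across conditions are
#' meaningful.
#'
#' @param trace Amplitude `ts_series` in mA.
#' @param frequency_hz Stimulation frequency (default 140.1 Hz).
#' @param pulse_width_s Pulse width in seconds (default 60 us).
#' @return Energy in proxy units.
#' @export
teed_proxy <- function(trace, frequency_hz = STIM_FREQUENCY_HZ,
                       pulse_width_s = STIM_PULSE_WIDTH_S) {
  stopifnot(inherits(trace, "ts_series"))
  if (!length(trace$values)) return(0)
  sum(trace$values^2) / trace$rate * frequency_hz * pulse_width_s
}

#' Adaptation pattern of a completed aDBS run
#'
#' The recorded amplitude trace together with the ordered sequence of
#' executed step directions and the time gaps between them. Replaying the
#' step sequence through the ramp machinery (or replaying the unshuffled
#' trace) reproduces the source amplitude trace exactly.
#'
#' @param decisions Decision log data frame from [run_adaptive()].
#' @param trace The amplitude `ts_series` of the run.
#' @return An `adaptation_pattern` object.
#' @export
adaptation_pattern <- function(decisions, trace) {
  stopifnot(inherits(trace, "ts_series"))
  ex <- decisions[decisions$executed, , drop = FALSE]
  gaps <- diff(c(0, ex$time_s))
  structure(list(directions = ex$direction, gaps_s = gaps,
                 trace = trace, init_ma = trace$values[1L],
                 duration_s = (length(trace$values) - 1L) / trace$rate,
                 rate = trace$rate),
            class = "adaptation_pattern")
}

# replay (direction, gap) pairs through clamped stepping; produces the same
# sample grid as a run_adaptive stim trace (sample 1 at t = 0)
replay_pattern <- function(directions, gaps_s, init_ma, duration_s, window,
                           step_ma, rate = 1, label = "") {
  n <- floor(duration_s * rate + 1e-9) + 1L
  tms <- cumsum(gaps_s)
  amp <- init_ma
  out <- numeric(n)
  k <- 1L
  for (i in seq_len(n)) {
    t <- (i - 1L) / rate
    while (k <= length(tms) && tms[k] <= t + 1e-9) {
      target <- amp + directions[k] * step_ma
      if (target >= window$i_min_ma - 1e-9 && target <= window$i_max_ma + 1e-9)
        amp <- target
      k <- k + 1L
    }
    out[i] <- amp
  }
  time_series(out, rate = rate, units = "mA", label = label)
}

#' Randomly adapting DBS trace
#'
#' Shuffles the adaptation pattern of a recorded aDBS run to produce a
#' stimulation trace with the same dwell statistics and total electrical
#' energy but no link to the beta biomarker: the source amplitude trace is
#' cut into `n_blocks` contiguous blocks, the blocks are uniformly permuted,
#' and the shuffled trace is replayed through the step machinery as a
#' rate-limited pursuit (one `step_ma` move per allowed per-direction dwell,
#' clamped to the window), so the result honours the ramp policy and the
#' 0.1 mA amplitude grid. With no executed steps in the source the constant
#' trace is returned unchanged; the brief catch-up ramps at block boundaries
#' are the only source of TEED mismatch.
#'
#' @param pattern An [adaptation_pattern()] (see [loop_pattern()]).
#' @param seed Integer seed for the shuffle.
#' @param block_s Approximate block length in seconds (default 50; the block
#'   count scales with the run length so catch-up ramps stay a negligible
#'   fraction of the trace).
#' @return Amplitude `ts_series` (same rate and duration as the source).
#' @export
generate_rdbs <- function(pattern, seed, block_s = 50) {
  stopifnot(inherits(pattern, "adaptation_pattern"))
  window <- attr(pattern, "window")
  ramp <- attr(pattern, "ramp") %||% ramp_policy()
  src <- pattern$trace$values
  rate <- pattern$trace$rate
  n <- length(src)
  if (length(pattern$directions) == 0L || n < 2L)
    return(time_series(src, rate, units = "mA", label = "rDBS"))
  # cut at upward crossings of the median level so block boundaries sit at
  # nearly equal amplitudes and the catch-up ramps stay negligible
  med <- stats::median(src)
  cuts <- which(src[-1L] >= med & src[-n] < med) + 1L
  min_block <- max(2L, round(block_s * rate / 5))
  keep <- numeric(0)
  last <- 1L
  for (cc in cuts) {
    if (cc - last >= min_block && n - cc + 1L >= min_block) {
      keep <- c(keep, cc)
      last <- cc
    }
  }
  bounds <- if (length(keep) >= 2L) {
    c(0L, keep - 1L, n)
  } else {
    n_blocks <- max(2L, min(round(n / (block_s * rate)), n))
    round(seq(0L, n, length.out = n_blocks + 1L))
  }
  n_blocks <- length(bounds) - 1L
  blocks <- lapply(seq_len(n_blocks), function(k)
    src[(bounds[k] + 1L):bounds[k + 1L]])
  perm <- with_seed(seed, sample.int(n_blocks))
  target <- unlist(blocks[perm])
  # pursue the shuffled trace under the per-direction dwell rule
  dwell_up <- ramp$step_ma / ramp$up_ma_per_s
  dwell_down <- ramp$step_ma / ramp$down_ma_per_s
  out <- numeric(n)
  out[1L] <- target[1L]
  last_step_t <- -Inf
  for (i in 2L:n) {
    t <- (i - 1L) / rate
    cur <- out[i - 1L]
    d <- target[i] - cur
    if (abs(d) > 1e-9) {
      dir <- sign(d)
      dwell <- if (dir > 0) dwell_up else dwell_down
      nxt <- cur + dir * ramp$step_ma
      if (t - last_step_t >= dwell - 1e-9 &&
          (is.null(window) ||
           (nxt >= window$i_min_ma - 1e-9 && nxt <= window$i_max_ma + 1e-9))) {
        cur <- nxt
        last_step_t <- t
      }
    }
    out[i] <- cur
  }
  time_series(out, rate, units = "mA", label = "rDBS")
}

#' Extract the adaptation pattern from a closed-loop result
#'
#' @param result A `loop_result` from [run_adaptive()].
#' @param hemisphere Hemisphere index (default 1).
#' @return An [adaptation_pattern()] carrying the hemisphere's window and
#'   step size.
#' @export
loop_pattern <- function(result, hemisphere = 1L) {
  cfg <- result$configs[[hemisphere]]
  pat <- adaptation_pattern(result$decisions[[hemisphere]],
                            result$stim[[hemisphere]])
  attr(pat, "window") <- cfg$window
  attr(pat, "ramp") <- cfg$ramp
  pat
}
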