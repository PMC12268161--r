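#' Streaming burst tracker over envelope samples
#'
#' The envelope-level core of the streaming detector: consumes envelope
#' samples one chunk at a time, maintains the above/below-threshold state
#' machine, emits completed burst events, and answers the controller's
#' "current burst duration" query. Time spans registered with
#' [blank_interval()] are excluded from the logic: a burst ongoing at blank
#' start is held, and the first sample after the blank decides whether it
#' bridges the blank or ended at the blank start.
#'
#' @param power_threshold Positive envelope threshold defining bursts.
#' @param rate Envelope sampling rate in Hz.
#' @param start Time of the first envelope sample in seconds.
#' @param capacity_s Buffer capacity in seconds; reported durations are capped
#'   at this value (default 5, covering the longest plausible duration
#'   thresholds with margin).
#' @return A `burst_tracker` environment; feed it with [tracker_ingest()].
#' @export
burst_tracker <- function(power_threshold, rate, start = 0, capacity_s = 5) {
  if (power_threshold <= 0) stop("`power_threshold` must be > 0", call. = FALSE)
  if (capacity_s <= 0) stop("`capacity_s` must be > 0", call. = FALSE)
  e <- new.env(parent = emptyenv())
  e$threshold <- power_threshold
  e$rate <- rate
  e$start <- start
  e$capacity_s <- capacity_s
  e$n_seen <- 0L            # envelope samples consumed
  e$in_burst <- FALSE
  e$burst_onset <- NA_real_
  e$last_completed <- NA_real_
  e$pending_blank_offset <- NA_real_  # burst offset to use if blank ends below
  e$last_live_value <- NA_real_       # most recent non-blanked envelope value
  e$last_live_time <- NA_real_
  e$blanks <- matrix(numeric(0), ncol = 2L)
  e$events <- list()
  class(e) <- "burst_tracker"
  e
}

tracker_sample_time <- function(trk, idx) trk$start + (idx - 1L) / trk$rate

# span start of the blank containing time t (falls back to t itself)
blank_span_start <- function(trk, t) {
  if (!nrow(trk$blanks)) return(t)
  hit <- trk$blanks[, 1L] <= t & t < trk$blanks[, 2L]
  if (any(hit)) min(trk$blanks[hit, 1L]) else t
}

tracker_complete <- function(trk, offset_s, ongoing = FALSE, collector) {
  dur <- offset_s - trk$burst_onset
  ev <- data.frame(onset_s = trk$burst_onset, offset_s = offset_s,
                   duration_s = dur, ongoing = ongoing)
  collector[[length(collector) + 1L]] <- ev
  if (!ongoing) trk$last_completed <- dur
  trk$in_burst <- FALSE
  trk$burst_onset <- NA_real_
  collector
}

#' Feed envelope samples to a burst tracker
#'
#' @param trk A [burst_tracker()].
#' @param values Numeric vector of consecutive envelope samples.
#' @return Data frame of burst events completed by this chunk (possibly empty).
#' @export
tracker_ingest <- function(trk, values) {
  stopifnot(inherits(trk, "burst_tracker"))
  emitted <- list()
  n <- length(values)
  if (!n) return(empty_bursts())
  idx0 <- trk$n_seen
  tms <- trk$start + (idx0 + seq_len(n) - 1L) / trk$rate
  blanked <- rep(FALSE, n)
  if (nrow(trk$blanks)) {
    for (k in seq_len(nrow(trk$blanks)))
      blanked <- blanked |
        (tms >= trk$blanks[k, 1L] & tms < trk$blanks[k, 2L])
  }
  above <- values > trk$threshold
  cls <- ifelse(blanked, 2L, as.integer(above))   # 0 below, 1 above, 2 blank
  r <- rle(cls)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    t_run <- tms[starts[k]]
    if (r$values[k] == 2L) {                      # blanked span: hold state
      if (trk$in_burst && is.na(trk$pending_blank_offset))
        trk$pending_blank_offset <- blank_span_start(trk, t_run)
      next
    }
    if (r$values[k] == 1L) {                      # above threshold
      if (!trk$in_burst) {
        trk$in_burst <- TRUE
        trk$burst_onset <- t_run
      }
      # an ongoing burst resuming after a blank simply bridges it
      trk$pending_blank_offset <- NA_real_
    } else {                                      # below threshold
      if (trk$in_burst) {
        off <- if (!is.na(trk$pending_blank_offset))
          trk$pending_blank_offset else t_run
        emitted <- tracker_complete(trk, off, FALSE, emitted)
      }
      trk$pending_blank_offset <- NA_real_
    }
    trk$last_live_value <- values[ends[k]]
    trk$last_live_time <- tms[ends[k]]
  }
  trk$n_seen <- trk$n_seen + n
  # prune blanks that can no longer affect anything
  if (nrow(trk$blanks)) {
    keep <- trk$blanks[, 2L] > tms[n] - trk$capacity_s
    trk$blanks <- trk$blanks[keep, , drop = FALSE]
  }
  out <- if (length(emitted)) do.call(rbind, emitted) else empty_bursts()
  if (nrow(out)) trk$events <- c(trk$events, list(out))
  out
}

tracker_finalize <- function(trk) {
  emitted <- list()
  if (trk$in_burst) {
    end_t <- trk$start + trk$n_seen / trk$rate
    off <- if (!is.na(trk$pending_blank_offset))
      trk$pending_blank_offset else end_t
    emitted <- tracker_complete(trk, off, ongoing = TRUE, emitted)
  }
  out <- if (length(emitted)) do.call(rbind, emitted) else empty_bursts()
  if (nrow(out)) trk$events <- c(trk$events, list(out))
  out
}

empty_bursts <- function() {
  data.frame(onset_s = numeric(0), offset_s = numeric(0),
             duration_s = numeric(0), ongoing = logical(0))
}

#' Streaming burst detector
#'
#' Stateful front end that turns a streamed LFP channel into burst events:
#' causal 128-order FIR bandpass (group-delay compensated), squaring,
#' incremental peak detection and linear interpolation to the envelope, and
#' the [burst_tracker()] state machine. Chunking is immaterial: for any split
#' of the same signal the completed bursts equal the offline
#' [compute_envelope()] + [extract_bursts()] result, provided
#' [detector_finalize()] is called at the end of the stream.
#'
#' @param band A [band_config()].
#' @param power_threshold Envelope threshold (see
#'   [power_threshold_from_gamma()]).
#' @param rate LFP sampling rate in Hz (500 nominal).
#' @param start Stream start time in seconds.
#' @param order FIR order (default 128).
#' @param capacity_s Tracker buffer capacity in seconds.
#' @return A `burst_detector` environment.
#' @export
burst_detector <- function(band, power_threshold, rate = 500, start = 0,
                           order = FIR_ORDER, capacity_s = 5) {
  stopifnot(inherits(band, "band_config"))
  spec <- design_fir_bandpass(band$center_hz, band$width_hz, order, rate)
  e <- new.env(parent = emptyenv())
  e$band <- band
  e$rate <- rate
  e$start <- start
  e$b <- spec$b
  e$g <- order %/% 2L
  e$carry <- numeric(0)       # last ntaps-1 raw inputs
  e$n_in <- 0L                # raw samples ingested
  e$n_causal <- 0L            # causal filter outputs produced
  e$pending <- numeric(0)     # squared aligned samples since last peak (incl.)
  e$pend0 <- 1L               # aligned index of pending[1]
  e$last_peak_idx <- NA_integer_
  e$last_peak_val <- NA_real_
  e$emitted <- 0L             # envelope samples forwarded to the tracker
  e$tracker <- burst_tracker(power_threshold, rate, start, capacity_s)
  e$finalized <- FALSE
  class(e) <- "burst_detector"
  e
}

# push raw samples through the causal FIR, returning newly available
# group-delay-aligned squared samples
detector_filter_chunk <- function(det, x) {
  y <- as.numeric(signal::filter(det$b, 1, c(det$carry, x)))
  y <- y[(length(det$carry) + 1L):length(y)]
  ntaps <- length(det$b)
  det$carry <- utils::tail(c(det$carry, x), ntaps - 1L)
  idx <- det$n_causal + seq_along(y) - det$g   # aligned indices
  det$n_causal <- det$n_causal + length(y)
  keep <- idx >= 1L
  (y[keep])^2
}

# detect new peaks in the pending squared samples and forward the
# interpolated envelope (up to the newest peak) to the tracker
detector_emit <- function(det) {
  pk_rel <- local_maxima(det$pending)
  if (!length(pk_rel)) return(empty_bursts())
  pk_abs <- det$pend0 + pk_rel - 1L
  nodes_i <- pk_abs
  nodes_v <- det$pending[pk_rel]
  if (!is.na(det$last_peak_idx) && det$last_peak_idx < nodes_i[1L]) {
    nodes_i <- c(det$last_peak_idx, nodes_i)
    nodes_v <- c(det$last_peak_val, nodes_v)
  }
  first <- det$emitted + 1L
  last <- pk_abs[length(pk_abs)]
  vals <- if (length(nodes_i) == 1L) {
    rep(nodes_v, last - first + 1L)
  } else {
    stats::approx(nodes_i, nodes_v, xout = first:last, rule = 2)$y
  }
  det$emitted <- last
  det$last_peak_idx <- pk_abs[length(pk_abs)]
  det$last_peak_val <- det$pending[pk_rel[length(pk_rel)]]
  cut <- pk_rel[length(pk_rel)]
  det$pending <- det$pending[cut:length(det$pending)]
  det$pend0 <- det$last_peak_idx
  tracker_ingest(det$tracker, vals)
}

#' Process a chunk of streamed LFP samples
#'
#' @param det A [burst_detector()].
#' @param new_samples Numeric vector, or a [time_series()] whose rate must
#'   match the detector's.
#' @return Data frame of burst events completed by this chunk.
#' @export
stream_process <- function(det, new_samples) {
  stopifnot(inherits(det, "burst_detector"))
  if (det$finalized) stop("detector already finalized", call. = FALSE)
  if (inherits(new_samples, "ts_series")) {
    if (abs(new_samples$rate - det$rate) > 1e-9)
      stop("chunk rate ", new_samples$rate, " Hz does not match detector rate ",
           det$rate, " Hz", call. = FALSE)
    new_samples <- new_samples$values
  }
  if (!length(new_samples)) return(empty_bursts())
  det$n_in <- det$n_in + length(new_samples)
  sq <- detector_filter_chunk(det, new_samples)
  if (length(sq)) det$pending <- c(det$pending, sq)
  detector_emit(det)
}

#' Finish a stream and flush remaining burst events
#'
#' Flushes the FIR group delay, emits the envelope tail (held at the last
#' peak value) and returns the remaining events; a burst still above
#' threshold at the stream end is returned with `ongoing = TRUE`.
#'
#' @param det A [burst_detector()].
#' @return Data frame of remaining burst events.
#' @export
detector_finalize <- function(det) {
  stopifnot(inherits(det, "burst_detector"))
  if (det$finalized) stop("detector already finalized", call. = FALSE)
  ev <- list()
  if (det$n_in > 0L) {
    sq <- detector_filter_chunk(det, numeric(det$g))
    if (length(sq)) det$pending <- c(det$pending, sq)
    ev[[1L]] <- detector_emit(det)
    if (is.na(det$last_peak_idx))
      stop("degenerate signal: no local maxima in the squared band-passed signal",
           call. = FALSE)
    if (det$emitted < det$n_in) {
      vals <- rep(det$last_peak_val, det$n_in - det$emitted)
      det$emitted <- det$n_in
      ev[[length(ev) + 1L]] <- tracker_ingest(det$tracker, vals)
    }
    ev[[length(ev) + 1L]] <- tracker_finalize(det$tracker)
  }
  det$finalized <- TRUE
  out <- do.call(rbind, ev)
  if (is.null(out)) empty_bursts() else out
}

#' All burst events a detector or tracker has emitted so far
#' @param x A `burst_detector` or `burst_tracker`.
#' @return Data frame of burst events.
#' @export
collected_bursts <- function(x) {
  trk <- if (inherits(x, "burst_detector")) x$tracker else x
  stopifnot(inherits(trk, "burst_tracker"))
  if (!length(trk$events)) return(empty_bursts())
  do.call(rbind, trk$events)
}

#' Exclude a time span from burst logic
#'
#' Registers a blanking interval (typically right after a stimulation step, to
#' let the stimulation-change artifact subside). Envelope samples inside the
#' span neither extend nor terminate bursts; a burst ongoing at blank start is
#' held, and the first post-blank sample decides whether it continues across
#' the blank or ended at the blank start.
#'
#' @param det A [burst_detector()] or [burst_tracker()].
#' @param start_s Blank start time in seconds.
#' @param duration_s Blank duration in seconds (>= 0).
#' @return The detector, invisibly.
#' @export
blank_interval <- function(det, start_s, duration_s) {
  if (duration_s < 0) stop("`duration_s` must be >= 0", call. = FALSE)
  trk <- if (inherits(det, "burst_detector")) det$tracker else det
  stopifnot(inherits(trk, "burst_tracker"))
  if (duration_s > 0)
    trk$blanks <- rbind(trk$blanks, c(start_s, start_s + duration_s))
  invisible(det)
}

#' Duration of the most recent burst in the buffer
#'
#' The control signal of the adaptive policy: if the envelope is currently
#' above threshold, the elapsed time since the last upward crossing (the
#' ongoing burst); otherwise the duration of the most recently completed
#' burst; 0 if no burst has been seen. Values are capped at the buffer
#' capacity. During a blank the last pre-blank answer is returned.
#'
#' @param det A [burst_detector()] or [burst_tracker()].
#' @param now_s Query time in seconds; defaults to the time just after the
#'   most recent non-blanked envelope sample.
#' @return Duration in seconds.
#' @export
current_burst_duration <- function(det, now_s = NULL) {
  trk <- if (inherits(det, "burst_detector")) det$tracker else det
  stopifnot(inherits(trk, "burst_tracker"))
  if (trk$n_seen == 0L) stop("empty buffer", call. = FALSE)
  dur <- if (trk$in_burst) {
    if (is.null(now_s)) now_s <- trk$last_live_time + 1 / trk$rate
    now_s - trk$burst_onset
  } else if (!is.na(trk$last_completed)) {
    trk$last_completed
  } else {
    0
  }
  min(max(dur, 0), trk$capacity_s)
}
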