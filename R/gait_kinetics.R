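#' Force-plate stepping trial
#'
#' Vertical ground-reaction forces under each foot during the harnessed
#' stepping-in-place task, sampled at 1000 Hz on dual force plates.
#'
#' @param left,right [time_series()] of vertical force (N), shared clock.
#' @param body_weight_n Body weight in newtons, or `NULL` to estimate it as
#'   the mean total force over the trial.
#' @return A `force_trial` object.
#' @export
force_trial <- function(left, right, body_weight_n = NULL) {
  mc <- multi_channel(list(left = left, right = right))
  if (any(left$values < -1e-9) || any(right$values < -1e-9))
    stop("vertical forces must be >= 0", call. = FALSE)
  structure(list(left = left, right = right, body_weight_n = body_weight_n),
            class = "force_trial")
}

#' Convert plate forces to percent body weight
#'
#' @param trial A [force_trial()].
#' @return List with `left` and `right` `ts_series` in %BW and the
#'   `body_weight_n` used (estimated when not supplied).
#' @export
normalize_to_bodyweight <- function(trial) {
  stopifnot(inherits(trial, "force_trial"))
  bw <- trial$body_weight_n
  if (is.null(bw)) {
    tot <- trial$left$values + trial$right$values
    if (!length(tot)) stop("empty trial: cannot estimate body weight", call. = FALSE)
    bw <- mean(tot)
  }
  if (!is.numeric(bw) || bw <= 0)
    stop("body weight must be > 0", call. = FALSE)
  scale <- function(ts) time_series(ts$values * 100 / bw, ts$rate, ts$start,
                                    units = "%BW", label = ts$label)
  list(left = scale(trial$left), right = scale(trial$right),
       body_weight_n = bw)
}

# runs of `below` shorter than `min_n` samples are flipped (debounce), so a
# crossing only counts if the signal dwells on the new side
debounce_runs <- function(below, min_n) {
  repeat {
    r <- rle(below)
    short <- which(r$lengths < min_n)
    # never flip the first/last run: the edges are genuinely unknown
    short <- short[short > 1L & short < length(r$values)]
    if (!length(short)) break
    i <- short[which.min(r$lengths[short])]
    r$values[i] <- !r$values[i]
    below <- inverse.rle(r)
  }
  below
}

#' Segment stepping forces into gait cycles
#'
#' Foot-off is the time a foot's force falls below the unload threshold
#' (default 20% BW) and foot-strike the time it rises back above it, with a
#' 50 ms dwell requirement on either side of each crossing to reject chatter.
#' Swing time is foot-off to foot-strike of the same foot, stride time the
#' interval between successive same-foot strikes.
#'
#' @param left,right %BW `ts_series` from [normalize_to_bodyweight()].
#' @param threshold_pct Unload threshold in %BW (default 20).
#' @param debounce_s Minimum dwell on either side of a crossing (default
#'   0.05 s).
#' @return A `gait_cycles` list with per-leg data frames (`foot_off_s`,
#'   `foot_strike_s`, `swing_s`) and per-leg `stride_s` vectors.
#' @export
segment_cycles_force <- function(left, right, threshold_pct = 20,
                                 debounce_s = 0.05) {
  one_leg <- function(ts) {
    v <- ts$values
    empty <- data.frame(foot_off_s = numeric(0), foot_strike_s = numeric(0),
                        swing_s = numeric(0))
    if (length(v) < 3L) return(list(events = empty, stride_s = numeric(0)))
    below <- debounce_runs(v < threshold_pct, max(1L, round(debounce_s * ts$rate)))
    d <- diff(below)
    off_i <- which(d == 1L) + 1L      # first sample below
    strike_i <- which(d == -1L) + 1L  # first sample back above
    tms <- ts_time(ts)
    offs <- tms[off_i]
    strikes <- tms[strike_i]
    # pair each foot-off with the next strike
    swings <- vapply(offs, function(o) {
      s <- strikes[strikes > o]
      if (length(s)) s[1L] - o else NA_real_
    }, numeric(1))
    keep <- !is.na(swings)
    ev <- data.frame(foot_off_s = offs[keep],
                     foot_strike_s = offs[keep] + swings[keep],
                     swing_s = swings[keep])
    list(events = ev, stride_s = diff(strikes))
  }
  l <- one_leg(left); r <- one_leg(right)
  structure(list(left = l$events, right = r$events,
                 stride_left_s = l$stride_s, stride_right_s = r$stride_s),
            class = "gait_cycles")
}

#' Gait asymmetry from swing times
#'
#' `100 * |ln(mean swing of the leg with the shorter swing / mean swing of
#' the leg with the longer swing)|`; symmetric in leg order, 0 for equal
#' means, larger for more asymmetric gait.
#'
#' @param swing_left_s,swing_right_s Per-leg swing time vectors (seconds).
#' @return Asymmetry in percent.
#' @export
asymmetry <- function(swing_left_s, swing_right_s) {
  if (!length(swing_left_s) || !length(swing_right_s))
    stop("asymmetry undefined: a leg has no swings", call. = FALSE)
  m <- c(mean(swing_left_s), mean(swing_right_s))
  100 * abs(log(min(m) / max(m)))
}

#' Gait arrhythmicity from stride times
#'
#' Mean over legs of the stride-time coefficient of variation
#' `100 * sd/mean` (sample standard deviation); larger values indicate less
#' rhythmic gait.
#'
#' @param stride_left_s,stride_right_s Per-leg stride time vectors (seconds).
#' @return Arrhythmicity in percent.
#' @export
arrhythmicity <- function(stride_left_s, stride_right_s) {
  if (length(stride_left_s) < 2L || length(stride_right_s) < 2L)
    stop("arrhythmicity undefined: fewer than 2 strides on a leg", call. = FALSE)
  cv <- function(x) 100 * stats::sd(x) / mean(x)
  mean(c(cv(stride_left_s), cv(stride_right_s)))
}

#' Detect freezing episodes from force plates
#'
#' During effective stepping each foot periodically unloads below `lo` %BW
#' while the contralateral foot carries more than `hi` %BW (a full
#' load-transfer excursion). Spans of at least `min_freeze_s` seconds without
#' any such excursion on either side are freezing episodes; episodes
#' separated by less than `merge_gap_s` are merged.
#'
#' @param left,right %BW `ts_series`.
#' @param lo,hi Excursion thresholds in %BW (defaults 15 and 85).
#' @param min_freeze_s Minimum episode duration (default 1 s).
#' @param merge_gap_s Merge gap (default 0.2 s).
#' @return A `freeze_intervals` object: data frame `intervals`
#'   (`start_s`, `end_s`), `total_s`, `percent_of_trial`.
#' @export
detect_freezes_forceplate <- function(left, right, lo = 15, hi = 85,
                                      min_freeze_s = 1.0, merge_gap_s = 0.2) {
  stopifnot(inherits(left, "ts_series"), inherits(right, "ts_series"))
  l <- left$values; r <- right$values
  excursion <- (l < lo & r > hi) | (r < lo & l > hi)
  tms <- ts_time(left)
  dur <- ts_duration(left)
  qr <- rle(!excursion)
  ends <- cumsum(qr$lengths); starts <- ends - qr$lengths + 1L
  quiet <- which(qr$values)
  mat <- cbind(start = tms[starts[quiet]],
               end = tms[ends[quiet]] + 1 / left$rate)
  mat <- mat[mat[, 2L] - mat[, 1L] >= min_freeze_s, , drop = FALSE]
  mat <- merge_intervals(mat, gap = merge_gap_s)
  freeze_intervals(mat, dur)
}

freeze_intervals <- function(mat, duration_s) {
  df <- as.data.frame(mat)
  if (!nrow(df)) df <- data.frame(start_s = numeric(0), end_s = numeric(0))
  names(df) <- c("start_s", "end_s")
  total <- sum(df$end_s - df$start_s)
  structure(list(intervals = df, total_s = total,
                 duration_s = duration_s,
                 percent_of_trial = if (duration_s > 0) 100 * total / duration_s
                 else NA_real_),
            class = "freeze_intervals")
}

#' Percent of trial time spent frozen
#'
#' @param intervals A `freeze_intervals` object or a data frame with
#'   `start_s`, `end_s`.
#' @param duration_s Trial duration in seconds.
#' @return Percent in `[0, 100]`.
#' @export
percent_time_freezing <- function(intervals, duration_s) {
  if (duration_s <= 0) stop("`duration_s` must be > 0", call. = FALSE)
  df <- if (inherits(intervals, "freeze_intervals")) intervals$intervals
  else intervals
  if (!nrow(df)) return(0)
  if (any(df$start_s < -1e-9) || any(df$end_s > duration_s + 1e-9))
    stop("intervals exceed trial bounds", call. = FALSE)
  100 * sum(df$end_s - df$start_s) / duration_s
}

#' Full stepping-in-place analysis
#'
#' Normalises to body weight, segments gait cycles, detects freezes and
#' computes the summary metrics. Asymmetry and arrhythmicity are `NA` with
#' `defined = FALSE` when the participant was frozen for (essentially) the
#' whole trial or produced too few strides — mirroring trials that cannot be
#' scored.
#'
#' @param trial A [force_trial()].
#' @param ... Passed to [segment_cycles_force()] and
#'   [detect_freezes_forceplate()].
#' @return List of metrics: `percent_time_freezing`, `asymmetry`,
#'   `arrhythmicity`, `n_strides`, `mean_stride_s`, `mean_swing_s`,
#'   `defined`, plus the `freezes` and `cycles` objects.
#' @export
analyze_sip <- function(trial, ...) {
  norm <- normalize_to_bodyweight(trial)
  cyc <- segment_cycles_force(norm$left, norm$right)
  frz <- detect_freezes_forceplate(norm$left, norm$right)
  dur <- ts_duration(norm$left)
  ptf <- percent_time_freezing(frz, dur)
  n_strides <- length(cyc$stride_left_s) + length(cyc$stride_right_s)
  ok <- length(cyc$stride_left_s) >= 2L && length(cyc$stride_right_s) >= 2L &&
    nrow(cyc$left) >= 1L && nrow(cyc$right) >= 1L && ptf < 99
  list(percent_time_freezing = ptf,
       asymmetry = if (ok) asymmetry(cyc$left$swing_s, cyc$right$swing_s)
       else NA_real_,
       arrhythmicity = if (ok) arrhythmicity(cyc$stride_left_s,
                                             cyc$stride_right_s) else NA_real_,
       n_strides = n_strides,
       mean_stride_s = if (n_strides)
         mean(c(cyc$stride_left_s, cyc$stride_right_s)) else NA_real_,
       mean_swing_s = if (nrow(cyc$left) + nrow(cyc$right))
         mean(c(cyc$left$swing_s, cyc$right$swing_s)) else NA_real_,
       defined = ok, freezes = frz, cycles = cyc)
}
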