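#' Beta band configuration
#'
#' A 6 Hz band centred on the participant-specific beta peak (13-30 Hz) drives
#' burst detection; the same machinery with a wider band around 55 Hz serves
#' as the high-frequency reference used to set the power threshold.
#'
#' @param center_hz Band centre in Hz.
#' @param width_hz Band width in Hz (default 6).
#' @param beta Logical; when `TRUE` (default) the centre must lie in the
#'   13-30 Hz beta range.
#' @return A `band_config` object.
#' @export
band_config <- function(center_hz, width_hz = 6, beta = TRUE) {
  if (width_hz <= 0) stop("`width_hz` must be > 0", call. = FALSE)
  if (beta && (center_hz < 13 || center_hz > 30))
    stop("beta band centre must lie in [13, 30] Hz", call. = FALSE)
  structure(list(center_hz = center_hz, width_hz = width_hz),
            class = "band_config")
}

# The reference band whose envelope troughs set the burst power threshold.
gamma_reference_band <- function() band_config(55, 20, beta = FALSE)

FIR_ORDER <- 128L

# Causal FIR filtering compensated for the linear-phase group delay
# (order/2 samples): the output sample aligned with input n is the causal
# output at n + order/2, obtained by flushing order/2 zeros through the
# filter. Identical arithmetic is used by the streaming detector.
fir_filter_aligned <- function(x, b) {
  g <- (length(b) - 1L) %/% 2L
  y <- as.numeric(signal::filter(b, 1, c(x, numeric(g))))
  y[(g + 1L):(g + length(x))]
}

#' Beta envelope of an LFP channel
#'
#' Implements the on-device envelope pipeline: bandpass with a 128-order FIR
#' around the configured band, square, locate local maxima of the squared
#' signal, and linearly interpolate between consecutive maxima. Before the
#' first and after the last maximum the nearest maximum value is held. For a
#' sinusoid of amplitude A in the passband the envelope is approximately A^2.
#'
#' @param lfp A [time_series()]; any rate at least four times the band top is
#'   accepted (500 Hz nominal).
#' @param band A [band_config()].
#' @param order FIR order (default 128).
#' @return An `envelope_series`: a `ts_series` of squared-peak-interpolated
#'   values (same rate and start as the input) with the source band attached.
#' @export
compute_envelope <- function(lfp, band, order = FIR_ORDER) {
  stopifnot(inherits(lfp, "ts_series"), inherits(band, "band_config"))
  top <- band$center_hz + band$width_hz / 2
  if (lfp$rate < 4 * top)
    stop("rate ", lfp$rate, " Hz too low for band top ", top, " Hz",
         call. = FALSE)
  if (length(lfp$values) <= 3L * order)
    stop("series too short for the FIR envelope pipeline", call. = FALSE)
  spec <- design_fir_bandpass(band$center_hz, band$width_hz, order, lfp$rate)
  sq <- fir_filter_aligned(lfp$values, spec$b)^2
  pk <- local_maxima(sq)
  if (!length(pk))
    stop("degenerate signal: no local maxima in the squared band-passed signal",
         call. = FALSE)
  env <- stats::approx(pk, sq[pk], xout = seq_along(sq), rule = 2)$y
  out <- time_series(env, rate = lfp$rate, start = lfp$start,
                     units = paste0("(", lfp$units, ")^2"), label = lfp$label)
  out$band <- band
  class(out) <- c("envelope_series", class(out))
  out
}

#' Power threshold from the high-frequency envelope floor
#'
#' The burst power threshold is the average trough (local minima) value of the
#' 45-65 Hz envelope of an OFF-stimulation recording, computed through the
#' same FIR/square/peak-interpolation pipeline as the beta envelope. The
#' troughs of this high-frequency envelope track the aperiodic noise floor, so
#' beta excursions above the threshold mark genuine bursts.
#'
#' @param off_lfp OFF-stimulation [time_series()] (>= `min_duration_s`).
#' @param min_duration_s Minimum accepted duration in seconds (default 10; 30
#'   or more is recommended).
#' @return The power threshold in envelope units (amplitude squared).
#' @export
power_threshold_from_gamma <- function(off_lfp, min_duration_s = 10) {
  stopifnot(inherits(off_lfp, "ts_series"))
  if (ts_duration(off_lfp) < min_duration_s)
    stop("OFF recording shorter than ", min_duration_s, " s", call. = FALSE)
  env <- compute_envelope(off_lfp, gamma_reference_band())
  tr <- local_minima(env$values)
  if (length(tr) < 10L)
    stop("insufficient data: fewer than 10 envelope troughs", call. = FALSE)
  mean(env$values[tr])
}

#' Extract burst events from an envelope
#'
#' Bursts are maximal contiguous runs of envelope samples strictly above the
#' power threshold. Onsets and offsets are reported at sample resolution; the
#' offset is the time of the first sample at or below threshold (exclusive
#' end), so the duration equals the run length times the sample period. A run
#' touching the end of the series is flagged `ongoing`.
#'
#' @param env An `envelope_series` (or any `ts_series` of envelope values).
#' @param power_threshold Positive threshold in envelope units.
#' @return A data frame with columns `onset_s`, `offset_s`, `duration_s`,
#'   `ongoing`.
#' @export
extract_bursts <- function(env, power_threshold) {
  stopifnot(inherits(env, "ts_series"))
  if (power_threshold <= 0) stop("`power_threshold` must be > 0", call. = FALSE)
  empty <- data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      duration_s = numeric(0), ongoing = logical(0))
  n <- length(env$values)
  if (!n) return(empty)
  r <- rle(env$values > power_threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  if (!any(keep)) return(empty)
  starts <- starts[keep]
  ends <- ends[keep]
  onset <- env$start + (starts - 1L) / env$rate
  offset <- env$start + ends / env$rate
  data.frame(onset_s = onset, offset_s = offset,
             duration_s = offset - onset,
             ongoing = ends == n)
}

#' Summary statistics of a burst table
#'
#' @param bursts A burst data frame from [extract_bursts()].
#' @param completed_only Drop ongoing bursts before summarising (default TRUE).
#' @return List with `n`, `mean_s`, `median_s`, `total_s`.
#' @export
burst_stats <- function(bursts, completed_only = TRUE) {
  if (completed_only) bursts <- bursts[!bursts$ongoing, , drop = FALSE]
  list(n = nrow(bursts),
       mean_s = if (nrow(bursts)) mean(bursts$duration_s) else NA_real_,
       median_s = if (nrow(bursts)) stats::median(bursts$duration_s) else NA_real_,
       total_s = sum(bursts$duration_s))
}
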