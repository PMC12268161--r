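#' Design a linear-phase FIR bandpass filter
#'
#' Windowed-sinc (Hamming) design of an even-order FIR bandpass, the filter
#' family used on the streamed LFP before envelope extraction. The passband
#' gain is normalised to unity at the band centre, so a sinusoid at the centre
#' frequency passes with amplitude 1 within design accuracy.
#'
#' @param center_hz Band centre in Hz.
#' @param width_hz Band width in Hz (passband is `center +/- width/2`).
#' @param order Filter order (even); the filter has `order + 1` coefficients.
#' @param rate Sampling rate in Hz the filter is designed for.
#' @return A `filter_spec` with fields `kind`, `order`, `band`, `rate`, `b`
#'   (coefficients) and `zero_phase = FALSE` (the filter is applied causally).
#' @export
design_fir_bandpass <- function(center_hz, width_hz, order = 128, rate = 500) {
  lo <- center_hz - width_hz / 2
  hi <- center_hz + width_hz / 2
  if (!(lo > 0 && hi < rate / 2))
    stop(sprintf("band [%g, %g] Hz outside (0, %g) Hz", lo, hi, rate / 2),
         call. = FALSE)
  if (order < 1 || order %% 2 != 0)
    stop("`order` must be a positive even integer", call. = FALSE)
  b <- signal::fir1(order, c(lo, hi) / (rate / 2), type = "pass")
  structure(list(kind = "fir_bandpass", order = order, band = c(lo, hi),
                 rate = rate, b = as.numeric(b), zero_phase = FALSE),
            class = "filter_spec")
}

#' Design a low-pass Butterworth filter for zero-phase application
#'
#' The stated order is the design order of the underlying Butterworth filter;
#' zero-phase application runs it forward and backward, squaring the magnitude
#' response. Coefficients are computed per series at application time so one
#' spec can serve signals at different rates.
#'
#' @param cutoff_hz Cut-off frequency in Hz.
#' @param order Design order of the Butterworth filter.
#' @return A `filter_spec` with `kind = "butter_lowpass"` and
#'   `zero_phase = TRUE`.
#' @export
design_butter_lowpass <- function(cutoff_hz, order) {
  if (order < 1) stop("`order` must be >= 1", call. = FALSE)
  if (cutoff_hz <= 0) stop("`cutoff_hz` must be > 0", call. = FALSE)
  structure(list(kind = "butter_lowpass", order = as.integer(order),
                 cutoff = cutoff_hz, zero_phase = TRUE),
            class = "filter_spec")
}

filter_coefs <- function(spec, rate) {
  switch(spec$kind,
    fir_bandpass = {
      if (abs(rate - spec$rate) > 1e-9)
        stop("FIR spec designed for ", spec$rate, " Hz, series is ", rate,
             " Hz", call. = FALSE)
      list(b = spec$b, a = 1)
    },
    butter_lowpass = {
      if (spec$cutoff >= rate / 2)
        stop("cut-off ", spec$cutoff, " Hz at or above Nyquist for rate ",
             rate, " Hz", call. = FALSE)
      ba <- signal::butter(spec$order, spec$cutoff / (rate / 2), type = "low")
      list(b = as.numeric(ba$b), a = as.numeric(ba$a))
    },
    stop("unknown filter kind ", spec$kind, call. = FALSE)
  )
}

# Forward-backward filtering of a bare numeric vector with reflect padding of
# length 3 x order at each edge to suppress edge transients on short trials.
zero_phase_filter_values <- function(x, b, a, order) {
  n <- length(x)
  pad <- 3L * order
  if (n <= pad)
    stop(sprintf("series too short for zero-phase filtering (%d samples, need > %d)",
                 n, pad), call. = FALSE)
  # reflect about the end points so the padded signal is continuous
  left <- 2 * x[1L] - x[seq(pad + 1L, 2L)]
  right <- 2 * x[n] - x[seq(n - 1L, n - pad)]
  xp <- c(left, x, right)
  y <- signal::filter(b, a, xp)
  y <- rev(signal::filter(b, a, rev(y)))
  as.numeric(y[(pad + 1L):(pad + n)])
}

#' Apply a filter with zero net phase shift
#'
#' Runs the filter forward and backward over the series (with reflect padding
#' of three filter orders at each edge), so band-limited features keep their
#' timing: the cross-correlation of a filtered in-band signal with the
#' original peaks at lag zero.
#'
#' @param series A [time_series()].
#' @param spec A `filter_spec` from [design_butter_lowpass()] or
#'   [design_fir_bandpass()].
#' @return A filtered `ts_series` with the same length, rate and start.
#' @export
filter_zero_phase <- function(series, spec) {
  stopifnot(inherits(series, "ts_series"), inherits(spec, "filter_spec"))
  co <- filter_coefs(spec, series$rate)
  out <- zero_phase_filter_values(series$values, co$b, co$a, spec$order)
  time_series(out, rate = series$rate, start = series$start,
              units = series$units, label = series$label)
}

#' Welch power spectral density
#'
#' One-sided PSD by Welch's method: the series is split into Hann-tapered
#' segments of `window_s` seconds with fractional `overlap`, periodograms are
#' averaged, and the result is scaled as a density (power / Hz) so that the
#' integral over frequency approximates the signal variance (plus the squared
#' mean in the DC bin; the series is not detrended, so a constant series puts
#' all its power at 0 Hz).
#'
#' @param series A [time_series()] of duration at least `2 * window_s`.
#' @param window_s Segment length in seconds (default 1).
#' @param overlap Fractional overlap between segments in `[0, 1)` (default 0.5).
#' @return A `psd` object with `frequencies` (Hz), `power` (density),
#'   `window_s`, `overlap_fraction` and `n_segments`.
#' @export
welch_psd <- function(series, window_s = 1.0, overlap = 0.5) {
  stopifnot(inherits(series, "ts_series"))
  if (window_s <= 0) stop("`window_s` must be > 0", call. = FALSE)
  if (overlap < 0 || overlap >= 1) stop("`overlap` must be in [0, 1)", call. = FALSE)
  fs <- series$rate
  x <- series$values
  nper <- round(window_s * fs)
  if (length(x) < 2L * nper)
    stop("series shorter than 2 windows (", length(x), " samples, window ",
         nper, ")", call. = FALSE)
  step <- max(1L, round(nper * (1 - overlap)))
  starts <- seq(1L, length(x) - nper + 1L, by = step)
  w <- as.numeric(signal::hanning(nper))
  scale <- fs * sum(w^2)
  nfreq <- nper %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nper - 1L)] * w
    X <- stats::fft(seg)[seq_len(nfreq)]
    acc <- acc + (Mod(X)^2) / scale
  }
  pxx <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when nper is even)
  dbl <- rep(2, nfreq)
  dbl[1L] <- 1
  if (nper %% 2L == 0L) dbl[nfreq] <- 1
  structure(list(frequencies = (seq_len(nfreq) - 1L) * fs / nper,
                 power = pxx * dbl, window_s = window_s,
                 overlap_fraction = overlap, n_segments = length(starts)),
            class = "psd")
}

#' @export
print.psd <- function(x, ...) {
  cat(sprintf("<psd> %d bins, 0-%g Hz (res %g Hz), %d segment(s)\n",
              length(x$frequencies), max(x$frequencies),
              x$frequencies[2L] - x$frequencies[1L], x$n_segments))
  invisible(x)
}

#' Band power from a PSD
#'
#' Integrates the one-sided spectral density over `[lo, hi]` Hz by the
#' trapezoidal rule.
#'
#' @param psd A `psd` object.
#' @param lo,hi Band edges in Hz.
#' @return Integrated power (signal-variance units).
#' @export
band_power <- function(psd, lo, hi) {
  stopifnot(inherits(psd, "psd"))
  keep <- psd$frequencies >= lo & psd$frequencies <= hi
  f <- psd$frequencies[keep]
  p <- psd$power[keep]
  if (length(f) < 2L) return(sum(p) * (psd$frequencies[2L] - psd$frequencies[1L]))
  sum(diff(f) * (utils::head(p, -1L) + utils::tail(p, -1L)) / 2)
}
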