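#' Stimulation titration run
#'
#' One calibration recording at a fixed stimulation amplitude: the LFP
#' channel, the amplitude (as mA and % of clinical), the behavioural metric
#' observed at that amplitude (percent time freezing by default) and a
#' side-effect flag.
#'
#' @param lfp A [time_series()] (one STN channel).
#' @param amplitude_ma Stimulation amplitude in mA (0 for OFF).
#' @param clinical_ma Clinical amplitude in mA.
#' @param behavior Behavioural metric in `[0, 100]` (percent time freezing).
#' @param side_effect Logical side-effect flag.
#' @return A `titration_run` object with `amplitude_pct` derived.
#' @export
titration_run <- function(lfp, amplitude_ma, clinical_ma, behavior = NA_real_,
                          side_effect = FALSE) {
  stopifnot(inherits(lfp, "ts_series"), amplitude_ma >= 0, clinical_ma > 0)
  pct <- 100 * amplitude_ma / clinical_ma
  if (pct > 125 + 1e-9)
    stop("titration amplitude exceeds 125% of clinical", call. = FALSE)
  if (!is.na(behavior) && (behavior < 0 || behavior > 100))
    stop("behaviour metric must be in [0, 100]", call. = FALSE)
  structure(list(lfp = lfp, amplitude_ma = amplitude_ma,
                 amplitude_pct = pct, clinical_ma = clinical_ma,
                 behavior = behavior, side_effect = isTRUE(side_effect)),
            class = "titration_run")
}

sort_runs <- function(runs) {
  runs[order(vapply(runs, function(r) r$amplitude_ma, numeric(1)))]
}

#' Welch spectra across titration levels
#'
#' @param runs List of [titration_run()]s covering at least two amplitude
#'   levels (including OFF).
#' @param window_s,overlap Welch parameters (1 s Hann, 50% overlap).
#' @return List of `psd` objects ordered by amplitude, with an
#'   `amplitudes_ma` attribute.
#' @export
titration_spectra <- function(runs, window_s = 1.0, overlap = 0.5) {
  runs <- sort_runs(runs)
  amps <- vapply(runs, function(r) r$amplitude_ma, numeric(1))
  if (length(unique(amps)) < 2L)
    stop("need at least two amplitude levels", call. = FALSE)
  out <- lapply(runs, function(r) welch_psd(r$lfp, window_s, overlap))
  attr(out, "amplitudes_ma") <- amps
  out
}

# candidate beta peaks: local PSD maxima in 13-30 Hz at least `min_db` above
# a log-log linear aperiodic fit over 5-45 Hz (excluding 13-30 Hz)
beta_peak_candidates <- function(psd, min_db = 3) {
  f <- psd$frequencies
  p <- psd$power
  fit_band <- f >= 5 & f <= 45 & !(f >= 13 & f <= 30) & p > 0
  if (sum(fit_band) < 3L) return(numeric(0))
  fit <- stats::lm(log10(p[fit_band]) ~ log10(f[fit_band]))
  beta <- which(f >= 13 & f <= 30)
  pk <- beta[beta %in% (local_maxima(p) )]
  if (!length(pk)) return(numeric(0))
  bg <- 10^(stats::coef(fit)[1L] + stats::coef(fit)[2L] * log10(f[pk]))
  f[pk][10 * log10(p[pk] / bg) >= min_db]
}

#' Select the beta band with the strongest burst-duration modulation
#'
#' Finds candidate peaks in the OFF-run PSD (local maxima in 13-30 Hz rising
#' at least 3 dB above the fitted aperiodic background), and for each
#' candidate computes the mean burst duration at every titration amplitude
#' through the standard envelope/threshold pipeline with a 6 Hz band around
#' the peak. The band whose mean duration falls fastest with amplitude (most
#' negative least-squares slope) is returned.
#'
#' @param runs List of [titration_run()]s (the lowest amplitude is the OFF
#'   reference).
#' @param width_hz Band width (default 6).
#' @param min_db Peak prominence over the aperiodic fit (default 3 dB).
#' @return A [band_config()] with attributes `slope_s_per_ma` and
#'   `candidates`.
#' @export
select_beta_band <- function(runs, width_hz = 6, min_db = 3) {
  runs <- sort_runs(runs)
  off <- runs[[1L]]
  cand <- beta_peak_candidates(welch_psd(off$lfp), min_db)
  # keep the 6 Hz band inside the beta range
  cand <- pmin(pmax(cand, 13 + width_hz / 2), 30 - width_hz / 2)
  cand <- unique(cand)
  if (!length(cand))
    stop("no beta peak above the aperiodic background (insufficient modulation)",
         call. = FALSE)
  thr <- power_threshold_from_gamma(off$lfp)
  amps <- vapply(runs, function(r) r$amplitude_ma, numeric(1))
  slopes <- vapply(cand, function(ctr) {
    band <- band_config(ctr, width_hz)
    md <- vapply(runs, function(r) {
      b <- extract_bursts(compute_envelope(r$lfp, band), thr)
      burst_stats(b)$mean_s
    }, numeric(1))
    if (any(is.na(md))) return(NA_real_)
    stats::coef(stats::lm(md ~ amps))[2L]
  }, numeric(1))
  if (all(is.na(slopes)))
    stop("no candidate band yields bursts at every level", call. = FALSE)
  best <- which.min(slopes)
  out <- band_config(cand[best], width_hz)
  attr(out, "slope_s_per_ma") <- slopes[best]
  attr(out, "candidates") <- data.frame(center_hz = cand,
                                        slope_s_per_ma = slopes)
  out
}

#' Initial burst-duration threshold
#'
#' The average observed beta burst duration during the OFF (or `i_min`)
#' recording: the starting duration threshold before any manual adjustment.
#'
#' @param run A [titration_run()] (OFF or at `i_min`).
#' @param band A [band_config()].
#' @param power_threshold Envelope power threshold.
#' @param min_bursts Minimum number of completed bursts (default 10).
#' @return Threshold in seconds.
#' @export
initial_duration_threshold <- function(run, band, power_threshold,
                                       min_bursts = 10) {
  lfp <- if (inherits(run, "titration_run")) run$lfp else run
  b <- extract_bursts(compute_envelope(lfp, band), power_threshold)
  b <- b[!b$ongoing, , drop = FALSE]
  if (nrow(b) < min_bursts)
    stop("insufficient data: only ", nrow(b), " completed bursts",
         call. = FALSE)
  mean(b$duration_s)
}

#' Burst-duration modulation across titration levels
#'
#' @param runs List of [titration_run()]s (at least 3 levels).
#' @param band A [band_config()].
#' @param power_threshold Envelope power threshold.
#' @return List with `amplitudes_ma`, `mean_durations_s`, `slope_s_per_ma`,
#'   `slope_ci` (95% confidence interval).
#' @export
burst_modulation <- function(runs, band, power_threshold) {
  runs <- sort_runs(runs)
  amps <- vapply(runs, function(r) r$amplitude_ma, numeric(1))
  if (length(unique(amps)) < 3L)
    stop("need at least three amplitude levels", call. = FALSE)
  md <- vapply(runs, function(r) {
    b <- extract_bursts(compute_envelope(r$lfp, band), power_threshold)
    burst_stats(b)$mean_s
  }, numeric(1))
  fit <- stats::lm(md ~ amps)
  ci <- stats::confint(fit)["amps", ]
  list(amplitudes_ma = amps, mean_durations_s = md,
       slope_s_per_ma = unname(stats::coef(fit)[2L]),
       slope_ci = unname(ci))
}

#' Select the therapeutic window from behavioural titrations
#'
#' `i_min` is the lowest non-zero amplitude whose behaviour satisfies the
#' benefit rule (default: percent time freezing at most half the OFF value,
#' or at least 50 points below it); `i_max` is the highest amplitude at or
#' above `i_min` with no side-effect flag below it, behaviour within the
#' tolerance of the best level (default 10 points), and at most 125% of the
#' clinical amplitude.
#'
#' @param runs List of [titration_run()]s with behaviour metrics.
#' @param clinical_ma Clinical amplitude in mA.
#' @param benefit_rule Function `(behavior, behavior_off) -> logical`.
#' @param tolerance_rule Function `(behavior, best_behavior) -> logical`.
#' @param i_min_floor_ma Optional floor for `i_min` (tremor-dominant
#'   adjustment).
#' @return A [therapeutic_window()] with attribute `table` (the per-level
#'   decisions).
#' @export
select_therapeutic_window <- function(runs, clinical_ma,
                                      benefit_rule = NULL,
                                      tolerance_rule = NULL,
                                      i_min_floor_ma = 0) {
  benefit_rule <- benefit_rule %||%
    function(b, b_off) b <= 0.5 * b_off | b <= b_off - 50
  tolerance_rule <- tolerance_rule %||%
    function(b, b_best) b <= b_best + 10
  runs <- sort_runs(runs)
  amps <- vapply(runs, function(r) r$amplitude_ma, numeric(1))
  beh <- vapply(runs, function(r) r$behavior, numeric(1))
  se <- vapply(runs, function(r) r$side_effect, logical(1))
  if (any(is.na(beh))) stop("all runs need a behaviour metric", call. = FALSE)
  b_off <- beh[which.min(amps)]
  cap <- 1.25 * clinical_ma
  ok_benefit <- amps > 0 & benefit_rule(beh, b_off) & amps <= cap + 1e-9
  ok_benefit <- ok_benefit & amps >= i_min_floor_ma
  if (!any(ok_benefit))
    stop("no amplitude provides acceptable benefit: no therapeutic window",
         call. = FALSE)
  i_min <- min(amps[ok_benefit])
  first_se <- if (any(se)) min(amps[se]) else Inf
  if (!any(ok_benefit & amps < first_se))
    stop("no tolerated amplitude at or above i_min", call. = FALSE)
  b_best <- min(beh[ok_benefit & amps < first_se])
  ok_max <- amps >= i_min & amps < first_se & amps <= cap + 1e-9 &
    tolerance_rule(beh, b_best)
  if (!any(ok_max)) stop("no tolerated amplitude at or above i_min",
                         call. = FALSE)
  i_max <- max(amps[ok_max])
  out <- therapeutic_window(i_min, i_max, clinical_ma)
  attr(out, "table") <- data.frame(amplitude_ma = amps, behavior = beh,
                                   side_effect = se, benefit = ok_benefit,
                                   tolerated = ok_max)
  out
}

#' End-to-end calibration of one hemisphere
#'
#' Runs the full parameter-selection pipeline on a set of titration runs:
#' power threshold from the OFF recording's 45-65 Hz envelope troughs, beta
#' band by burst-duration modulation, initial duration threshold from the
#' OFF run, and the therapeutic window from the behavioural metrics.
#'
#' @param runs List of [titration_run()]s.
#' @param clinical_ma Clinical amplitude in mA.
#' @param ... Passed to [select_therapeutic_window()].
#' @return A `calibration_result`: `band`, `power_threshold`,
#'   `duration_threshold_s`, `window`, `modulation`, `usable` flag and
#'   `reason` when unusable.
#' @export
calibrate_hemisphere <- function(runs, clinical_ma, ...) {
  runs <- sort_runs(runs)
  off <- runs[[1L]]
  res <- list(usable = FALSE, reason = NA_character_)
  band <- try(select_beta_band(runs), silent = TRUE)
  if (inherits(band, "try-error")) {
    res$reason <- "insufficient modulation"
    class(res) <- "calibration_result"
    return(res)
  }
  thr <- power_threshold_from_gamma(off$lfp)
  dthr <- initial_duration_threshold(off, band, thr)
  window <- select_therapeutic_window(runs, clinical_ma, ...)
  mod <- burst_modulation(runs, band, thr)
  structure(list(band = band, power_threshold = thr,
                 duration_threshold_s = dthr, window = window,
                 modulation = mod, usable = TRUE, reason = NA_character_),
            class = "calibration_result")
}
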