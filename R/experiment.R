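#' Configuration for an in-silico condition-comparison experiment
#'
#' Couples the neural plant to the behavioural generators through an explicit
#' linkage: a logistic function maps the mean detected beta burst duration to
#' a 0-1 impairment level, which scales the planted freeze fraction, gait
#' variability, asymmetry and wrist slowing. The linkage is a documented
#' simulation device (worse bursts, worse behaviour), not a measured law.
#'
#' @param band A [band_config()].
#' @param power_threshold Envelope threshold.
#' @param duration_threshold_s Controller duration threshold in seconds.
#' @param window A [therapeutic_window()].
#' @param plant A [plant_params()] for the neural generator.
#' @param ramp A [ramp_policy()].
#' @param neural_s Neural run length per condition in seconds (default 180).
#' @param linkage_gain Gain of the burst-to-behaviour linkage in `[0, 1]`
#'   (default 0.85; 0 decouples behaviour from stimulation entirely).
#' @param linkage_mid_s,linkage_width_s Midpoint and width of the logistic
#'   linkage (defaults 0.3 and 0.05 s).
#' @param sip_s,tbc_s,wrist_s Behavioural trial durations (defaults 100, 60,
#'   30 s).
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(band, power_threshold, duration_threshold_s,
                              window, plant = plant_params(),
                              ramp = ramp_policy(), neural_s = 180,
                              linkage_gain = 0.85, linkage_mid_s = 0.3,
                              linkage_width_s = 0.05, sip_s = 100,
                              tbc_s = 60, wrist_s = 30) {
  stopifnot(inherits(band, "band_config"),
            inherits(window, "therapeutic_window"),
            linkage_gain >= 0, linkage_gain <= 1)
  structure(as.list(environment()), class = "experiment_config")
}

#' Derive an experiment configuration from a calibration result
#'
#' @param cal A `calibration_result` from [calibrate_hemisphere()].
#' @param ... Overrides passed to [experiment_config()].
#' @return An `experiment_config`.
#' @export
experiment_config_from_calibration <- function(cal, ...) {
  stopifnot(inherits(cal, "calibration_result"))
  if (!isTRUE(cal$usable))
    stop("calibration unusable: ", cal$reason, call. = FALSE)
  experiment_config(band = cal$band, power_threshold = cal$power_threshold,
                    duration_threshold_s = cal$duration_threshold_s,
                    window = cal$window, ...)
}

linkage_level <- function(mean_burst_s, cfg) {
  if (!is.finite(mean_burst_s)) mean_burst_s <- cfg$linkage_mid_s
  1 / (1 + exp(-(mean_burst_s - cfg$linkage_mid_s) / cfg$linkage_width_s))
}

# neural run for one condition; returns detected burst stats and stim trace
condition_neural <- function(condition, cfg, seed, adbs_result = NULL) {
  hemi <- hemisphere_config(band = cfg$band,
                            power_threshold = cfg$power_threshold,
                            duration_threshold_s = cfg$duration_threshold_s,
                            window = cfg$window, ramp = cfg$ramp)
  detect <- function(lfp) {
    b <- extract_bursts(compute_envelope(lfp, cfg$band), cfg$power_threshold)
    burst_stats(b)
  }
  plant_seed <- child_seed(seed, 41)
  if (condition == "aDBS") {
    plant <- lfp_plant(cfg$plant, plant_seed)
    res <- run_adaptive(plant, hemi, duration_s = cfg$neural_s)
    bs <- burst_stats(res$bursts[[1L]])
    return(list(stim = res$stim[[1L]], bursts = bs, loop = res))
  }
  stim <- switch(condition,
    OFF = time_series(rep(0, cfg$neural_s), 1, units = "mA", label = "OFF"),
    cDBS = hold_continuous(cfg$window$clinical_ma, cfg$neural_s),
    rDBS = {
      if (is.null(adbs_result)) stop("rDBS needs the aDBS run", call. = FALSE)
      generate_rdbs(loop_pattern(adbs_result), seed = child_seed(seed, 7))
    })
  sim <- synth_lfp(cfg$plant, stim = stim, seed = plant_seed)
  list(stim = stim, bursts = detect(sim$lfp), loop = NULL)
}

condition_behavior <- function(level, cfg, seed) {
  bseed <- child_seed(seed, 100)   # shared across conditions on purpose
  sip <- synth_sip(gait_params(freeze_fraction = min(level, 0.95),
                               stride_cv = 0.02 + 0.06 * level,
                               asym_factor = 1 - 0.15 * level,
                               duration_s = cfg$sip_s), seed = bseed)
  sipm <- analyze_sip(sip$trial)
  tbc <- synth_tbc(tbc_params(freeze_fraction = min(level, 0.95),
                              stride_cv = 0.04 + 0.08 * level,
                              duration_s = cfg$tbc_s), seed = bseed)
  tabs <- lapply(tbc$imu, function(mc) segment_strides_imu(extract_sagittal(mc)))
  mp <- tryCatch(mean_peak_shank_angular_velocity(tabs),
                 error = function(e) NA_real_)
  wr <- synth_wrist(amplitude_deg_s = 150 - 90 * level,
                    duration_s = cfg$wrist_s, seed = bseed)
  list(percent_time_freezing = sipm$percent_time_freezing,
       asymmetry = sipm$asymmetry, arrhythmicity = sipm$arrhythmicity,
       mean_peak_shank_angular_velocity = mp,
       vrms = wrist_vrms(wr$hand),
       cycles_per_second = wrist_cycles_per_second(wr$hand))
}

#' Run the full in-silico condition comparison
#'
#' For each seed, runs the four stimulation conditions (OFF, cDBS, aDBS and
#' the TEED-matched rDBS derived from that seed's aDBS adaptation pattern)
#' on the neural plant, maps the detected burst statistics to behavioural
#' generator settings through the configured linkage, and computes the gait
#' and bradykinesia metrics on the generated trials.
#'
#' @param cfg An [experiment_config()].
#' @param seeds Integer vector of replicate seeds.
#' @return An `experiment_report`: `results` (one row per seed and
#'   condition), `summary` (per-condition mean and sd of each metric),
#'   `pairwise` (condition differences of means).
#' @export
run_experiment <- function(cfg, seeds = 1:5) {
  stopifnot(inherits(cfg, "experiment_config"))
  conditions <- c("OFF", "cDBS", "aDBS", "rDBS")
  rows <- list()
  for (seed in seeds) {
    adbs <- NULL
    for (cond in conditions) {
      nr <- condition_neural(cond, cfg, seed,
                             adbs_result = if (cond == "rDBS") adbs else NULL)
      if (cond == "aDBS") adbs <- nr$loop
      level <- cfg$linkage_gain * linkage_level(nr$bursts$mean_s, cfg)
      beh <- condition_behavior(level, cfg, seed)
      rows[[length(rows) + 1L]] <- data.frame(
        seed = seed, condition = cond,
        mean_amplitude_ma = mean(nr$stim$values),
        teed = if (cond == "OFF") 0 else teed_proxy(nr$stim),
        mean_burst_s = nr$bursts$mean_s,
        median_burst_s = nr$bursts$median_s,
        impairment_level = level,
        percent_time_freezing = beh$percent_time_freezing,
        asymmetry = beh$asymmetry,
        arrhythmicity = beh$arrhythmicity,
        mean_peak_shank_angular_velocity = beh$mean_peak_shank_angular_velocity,
        vrms = beh$vrms,
        cycles_per_second = beh$cycles_per_second
      )
    }
  }
  results <- do.call(rbind, rows)
  metrics <- setdiff(names(results), c("seed", "condition"))
  summary <- do.call(rbind, lapply(split(results, results$condition),
    function(d) {
      data.frame(condition = d$condition[1L],
                 t(vapply(metrics, function(m) {
                   x <- d[[m]]
                   c(mean = mean(x, na.rm = TRUE), sd = stats::sd(x, na.rm = TRUE))
                 }, numeric(2))))
    }))
  pairs <- utils::combn(conditions, 2L)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    data.frame(a = a, b = b, t(vapply(metrics, function(m) {
      mean(results[[m]][results$condition == a], na.rm = TRUE) -
        mean(results[[m]][results$condition == b], na.rm = TRUE)
    }, numeric(1))))
  }))
  structure(list(results = results, summary = summary, pairwise = pairwise,
                 config = cfg, seeds = seeds),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report>", length(x$seeds), "seed(s) x 4 conditions\n")
  s <- x$summary
  cat(sprintf("%-5s %8s %8s %8s %8s\n", "cond", "%freeze", "TEED",
              "burst_s", "Vrms"))
  for (i in seq_len(nrow(s)))
    cat(sprintf("%-5s %8.1f %8.3f %8.3f %8.1f\n", s$condition[i],
                s$percent_time_freezing.mean[i], s$teed.mean[i],
                s$mean_burst_s.mean[i], s$vrms.mean[i]))
  invisible(x)
}
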