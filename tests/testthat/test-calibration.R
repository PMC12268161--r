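# shared titration fixture: 15 Hz rhythm whose bursts shorten with amplitude
make_titrations <- function(clinical = 3, seed = 40,
                            behavior = c(100, 100, 60, 10, 5, 0),
                            pp = plant_params(), duration = 90) {
  amps <- c(0, 0.25, 0.5, 0.75, 1.0, 1.1) * clinical
  lapply(seq_along(amps), function(i) {
    s <- synth_lfp(pp, stim = amps[i], duration_s = duration, seed = seed + i)
    titration_run(s$lfp, amps[i], clinical, behavior = behavior[i])
  })
}

runs <- make_titrations()

test_that("titration spectra show decreasing beta power with stimulation", {
  sp <- titration_spectra(runs)
  bp <- vapply(sp, function(p) band_power(p, 13, 30), numeric(1))
  expect_equal(length(sp), 6L)
  expect_lt(bp[length(bp)], 0.5 * bp[1L])
  expect_lt(stats::cor(bp, attr(sp, "amplitudes_ma")), -0.8)
  expect_error(titration_spectra(runs[1]), "two amplitude")
})

test_that("beta band selection finds the modulated peak", {
  band <- select_beta_band(runs)
  expect_lte(abs(band$center_hz - 15), 1)
  expect_lt(attr(band, "slope_s_per_ma"), 0)
  # flat 1/f spectrum (no beta rhythm): no-peak error
  flat <- lapply(c(0, 1.5, 3), function(a) {
    s <- synth_lfp(plant_params(burst_amp = 0, burst_rate_hz = 0.01),
                   stim = a, duration_s = 30, seed = 90 + round(a * 10))
    titration_run(s$lfp, a, 3)
  })
  expect_error(select_beta_band(flat), "no beta peak")
})

test_that("beta band selection prefers the stimulation-modulated rhythm", {
  # two rhythms: modulated 15 Hz (via plant) + unmodulated 25 Hz added on top
  clinical <- 3
  amps <- c(0, 0.75, 1.5, 2.25, 3)
  two <- lapply(seq_along(amps), function(i) {
    s <- synth_lfp(plant_params(), stim = amps[i], duration_s = 60,
                   seed = 70 + i)
    # bursty but stimulation-independent 25 Hz rhythm (no noise terms)
    extra <- synth_lfp(plant_params(beta_center_hz = 25, k_s_per_ma = 0,
                                    bg_sd = 0, gamma_sd = 0),
                       stim = amps[i], duration_s = 60, seed = 200 + i)
    lfp <- time_series(s$lfp$values + extra$lfp$values, s$lfp$rate)
    titration_run(lfp, amps[i], clinical)
  })
  band <- select_beta_band(two)
  expect_lt(abs(band$center_hz - 15), 1.5)
})

test_that("beta band selection is invariant to overall gain", {
  g <- lapply(runs, function(r) {
    r$lfp$values <- r$lfp$values * 7.3
    r
  })
  b1 <- select_beta_band(runs)
  b2 <- select_beta_band(g)
  expect_equal(b1$center_hz, b2$center_hz)
})

test_that("initial duration threshold is the OFF mean burst duration", {
  off <- runs[[1L]]
  band <- band_config(15)
  thr <- power_threshold_from_gamma(off$lfp)
  dthr <- initial_duration_threshold(off, band, thr)
  s <- synth_lfp(plant_params(), stim = 0, duration_s = 90, seed = 41)
  expect_lt(abs(dthr - mean(s$truth$duration_s)) / mean(s$truth$duration_s),
            0.1)
  # constructed envelope with identical bursts gives their exact duration
  env_vals <- rep(c(numeric(350), rep(4, 150)), 20)
  fake <- list(lfp = NULL)
  b <- extract_bursts(time_series(env_vals, 500), 1)
  expect_equal(mean(b$duration_s[!b$ongoing]), 0.3)
  # too few bursts is an error
  short <- synth_lfp(plant_params(burst_rate_hz = 0.05), stim = 0,
                     duration_s = 30, seed = 42)
  expect_error(initial_duration_threshold(
    titration_run(short$lfp, 0, 3), band, thr), "insufficient")
})

test_that("burst modulation recovers the planted slope", {
  pp <- plant_params(d0_s = 0.5, k_s_per_ma = 0.1)
  slopes <- vapply(1:5, function(sd) {
    rs <- make_titrations(seed = 500 + sd * 7, pp = pp)
    m <- burst_modulation(rs, band_config(15),
                          power_threshold_from_gamma(rs[[1L]]$lfp))
    m$slope_s_per_ma
  }, numeric(1))
  expect_lt(abs(mean(slopes) - (-0.1)) / 0.1, 0.25)
  # amplitude-independent plant: CI contains 0
  pp0 <- plant_params(k_s_per_ma = 0)
  rs0 <- make_titrations(seed = 600, pp = pp0)
  m0 <- burst_modulation(rs0, band_config(15),
                         power_threshold_from_gamma(rs0[[1L]]$lfp))
  expect_true(m0$slope_ci[1L] <= 0 && m0$slope_ci[2L] >= 0)
  expect_error(burst_modulation(rs0[1:2], band_config(15), 0.05), "three")
})

test_that("therapeutic window selection applies benefit and tolerance rules", {
  # the constructed freezing series: window [75%, 110%] of clinical
  w <- select_therapeutic_window(runs, clinical_ma = 3)
  expect_equal(w$i_min_ma, 2.25)
  expect_equal(w$i_max_ma, 3.3)
  # side-effect flag caps i_max below the flagged level
  runs2 <- runs
  runs2[[6L]]$side_effect <- TRUE
  w2 <- select_therapeutic_window(runs2, clinical_ma = 3)
  expect_lt(w2$i_max_ma, 3.3)
  # all levels fully frozen: no window
  runs3 <- make_titrations(behavior = rep(100, 6), seed = 40)
  expect_error(select_therapeutic_window(runs3, clinical_ma = 3),
               "no therapeutic window|no amplitude")
  # the 125% cap binds for any behaviour series
  set.seed(8)
  for (k in 1:5) {
    beh <- c(100, sort(runif(5, 0, 100), decreasing = TRUE))
    rk <- runs
    for (i in seq_along(rk)) rk[[i]]$behavior <- beh[i]
    wk <- try(select_therapeutic_window(rk, clinical_ma = 3), silent = TRUE)
    if (!inherits(wk, "try-error"))
      expect_lte(wk$i_max_ma, 1.25 * 3 + 1e-9)
  }
})

test_that("end-to-end calibration recovers the planted configuration", {
  cal <- calibrate_hemisphere(runs, clinical_ma = 3)
  expect_true(cal$usable)
  expect_lte(abs(cal$band$center_hz - 15), 1)
  s <- synth_lfp(plant_params(), stim = 0, duration_s = 90, seed = 41)
  expect_lt(abs(cal$duration_threshold_s - mean(s$truth$duration_s)) /
              mean(s$truth$duration_s), 0.1)
  expect_equal(cal$window$i_min_ma, 2.25)
  expect_equal(cal$window$i_max_ma, 3.3)
  expect_lt(cal$modulation$slope_s_per_ma, 0)
})
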