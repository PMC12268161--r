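test_that("generators are deterministic given a seed", {
  a <- synth_lfp(duration_s = 10, seed = 3)
  b <- synth_lfp(duration_s = 10, seed = 3)
  expect_identical(a$lfp$values, b$lfp$values)
  expect_identical(a$truth, b$truth)
  expect_false(identical(synth_lfp(duration_s = 10, seed = 4)$lfp$values,
                         a$lfp$values))
  s1 <- synth_sip(gait_params(duration_s = 20), seed = 5)
  s2 <- synth_sip(gait_params(duration_s = 20), seed = 5)
  expect_identical(s1$trial$left$values, s2$trial$left$values)
  t1 <- synth_tbc(tbc_params(duration_s = 20), seed = 6)
  t2 <- synth_tbc(tbc_params(duration_s = 20), seed = 6)
  expect_identical(t1$imu$left$channels$g1$values,
                   t2$imu$left$channels$g1$values)
  w1 <- synth_wrist(seed = 7)
  w2 <- synth_wrist(seed = 7)
  expect_identical(w1$hand$values, w2$hand$values)
})

test_that("plant_step chunks concatenate to the one-shot signal", {
  pp <- plant_params()
  one <- synth_lfp(pp, stim = 2, duration_s = 20, seed = 11)
  # same amplitude schedule in irregular chunks
  plant <- lfp_plant(pp, seed = 11)
  set.seed(1)
  total <- 20 * 500
  got <- numeric(0)
  while (length(got) < total) {
    dt <- sample(c(1, 3, 7, 250, 500, 1250), 1) / 500
    dt <- min(dt, (total - length(got)) / 500)
    got <- c(got, plant_step(plant, 2, dt))
  }
  expect_equal(got, one$lfp$values, tolerance = 1e-12)
  # single-sample stepping works
  plant2 <- lfp_plant(pp, seed = 11)
  tiny <- unlist(lapply(1:500, function(i) plant_step(plant2, 2, 1 / 500)))
  expect_equal(tiny, one$lfp$values[1:500], tolerance = 1e-12)
})

test_that("the duration law is exact in the truth record", {
  pp <- plant_params(d0_s = 0.5, k_s_per_ma = 0.1, d_floor_s = 0.1)
  lo <- synth_lfp(pp, stim = 0, duration_s = 400, seed = 21)
  hi <- synth_lfp(pp, stim = 3, duration_s = 400, seed = 21)
  # planted means differ by ~ k * amplitude
  expect_lt(abs(mean(lo$truth$duration_s) - 0.5) / 0.5, 0.15)
  expect_lt(abs(mean(hi$truth$duration_s) - 0.2) / 0.2, 0.15)
  # the floor binds at high amplitude
  floor_run <- synth_lfp(pp, stim = 10, duration_s = 200, seed = 22)
  expect_lt(abs(mean(floor_run$truth$duration_s) - 0.1) / 0.1, 0.2)
})

test_that("amplitude changes mid-burst let the running burst complete", {
  pp <- plant_params(burst_rate_hz = 0.5)
  plant <- lfp_plant(pp, seed = 31)
  plant_step(plant, 0, 10)
  tr1 <- plant_truth(plant, within_s = Inf)
  # jump the amplitude; bursts already materialised keep their durations
  plant_step(plant, 3, 10)
  tr2 <- plant_truth(plant, within_s = Inf)
  shared <- seq_len(nrow(tr1))
  expect_equal(tr2$duration_s[shared], tr1$duration_s)
  expect_true(all(tr2$amplitude_ma[tr2$onset_s < 10] == 0))
})

test_that("stimulation-change artifacts decay into the signal", {
  pp <- plant_params(bg_sd = 0, gamma_sd = 0, burst_amp = 0,
                     artifact_peak = 10, artifact_tau_s = 0.1)
  plant <- lfp_plant(pp, seed = 41)
  quiet <- plant_step(plant, 0, 1)
  expect_equal(max(abs(quiet)), 0)
  plant_register_step(plant, 1)
  after <- plant_step(plant, 0, 1)
  expect_equal(after[1L], 10, tolerance = 1e-6)
  # one decay constant (0.1 s = 50 samples) later: 10 * exp(-1)
  expect_equal(after[51L], 10 * exp(-0.1 / 0.1), tolerance = 0.01)
})

test_that("synthetic truth labels are consistent with the emitted signals", {
  s <- synth_sip(gait_params(freeze_fraction = 0.3), seed = 51)
  expect_lt(abs(sum(s$truth$freeze_intervals$end_s -
                      s$truth$freeze_intervals$start_s) -
                  0.3 * 100), 1)
  tb <- synth_tbc(tbc_params(freeze_fraction = 0.25, duration_s = 40),
                  seed = 52)
  frac <- sum(tb$truth$freeze_intervals$end_s -
                tb$truth$freeze_intervals$start_s) / 40
  expect_lt(abs(frac - 0.25), 0.02)
  expect_true(all(diff(tb$truth$steps$mid_swing_s) > 0))
  w <- synth_wrist(amplitude_deg_s = 0, seed = 53)
  expect_false(w$truth$oscillatory)
  expect_equal(w$truth$vrms, 0)
})

test_that("closed-loop stimulation shortens detected bursts versus i_min", {
  pp <- plant_params(d0_s = 1.1, k_s_per_ma = 0.3)
  win <- therapeutic_window(1.5, 3.5, 3.0)
  cfg <- hemisphere_config(band = band_config(15), power_threshold = 0.065,
                           duration_threshold_s = 0.26, window = win)
  res <- run_adaptive(lfp_plant(pp, 61), cfg, duration_s = 200)
  b <- res$bursts[[1L]]
  half <- b[b$onset_s > 100 & !b$ongoing, ]
  # reference: held at i_min
  ref <- synth_lfp(pp, stim = win$i_min_ma, duration_s = 200, seed = 61)
  thr <- 0.065
  rb <- extract_bursts(compute_envelope(ref$lfp, band_config(15)), thr)
  rb <- rb[rb$onset_s > 100 & !rb$ongoing, ]
  mean_amp <- mean(res$stim[[1L]]$values[100:200])
  planted_gap <- 0.3 * (mean_amp - win$i_min_ma)
  expect_lt(mean(half$duration_s),
            mean(rb$duration_s) - 0.5 * planted_gap)
})
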