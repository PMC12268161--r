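test_that("sagittal extraction recovers single-axis rotation in any frame", {
  fs <- 128
  t <- seq(0, 10, by = 1 / fs)
  sag <- 200 * pmax(sin(2 * pi * 1 * t), 0)^2
  m <- cbind(sag, 0 * t, 0 * t)
  out <- extract_sagittal(m, rate = fs)
  core <- 200:1000
  expect_gt(stats::cor(out$values[core], sag[core]), 0.999)
  expect_gt(attr(out, "var_share"), 0.99)
  # rotated frame: same output up to sign and small filter tolerance
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3)
  out_rot <- extract_sagittal(m %*% t(R), rate = fs)
  expect_gt(abs(stats::cor(out$values[core], out_rot$values[core])), 0.999)
  expect_lt(abs(max(out_rot$values) - max(out$values)) / max(out$values),
            0.02)
  # isotropic noise: low-confidence flag
  set.seed(3)
  nz <- extract_sagittal(matrix(rnorm(3 * 1500), ncol = 3), rate = 128)
  expect_true(attr(nz, "low_confidence"))
  expect_error(extract_sagittal(matrix(0, 1500, 3), rate = 128),
               "degenerate")
})

test_that("stride segmentation recovers planted stride trains", {
  s <- synth_tbc(tbc_params(stride_cv = 0.02, noise_sd = 3), seed = 8)
  tb <- segment_strides_imu(extract_sagittal(s$imu$left))
  truth <- s$truth$steps[s$truth$steps$leg == "left", ]
  expect_equal(nrow(tb), nrow(truth))
  expect_lt(abs(mean(tb$stride_s, na.rm = TRUE) - 1.1), 0.02)
  expect_lt(abs(mean(tb$peak_deg_s) - mean(truth$peak_deg_s)) /
              mean(truth$peak_deg_s), 0.05)
  expect_lt(abs(mean(tb$swing_range_deg) - mean(truth$swing_range_deg)) /
              mean(truth$swing_range_deg), 0.1)
  # flat signal: empty table
  flat <- time_series(rep(0.01, 1280), 128)
  expect_equal(nrow(segment_strides_imu(flat)), 0L)
})

test_that("mean peak shank angular velocity averages strides across legs", {
  tb1 <- data.frame(peak_deg_s = c(200, 300))
  tb2 <- data.frame(peak_deg_s = 250)
  expect_equal(mean_peak_shank_angular_velocity(list(tb1, tb2)), 250)
  expect_equal(mean_peak_shank_angular_velocity(list(tb2)), 250)
  expect_error(mean_peak_shank_angular_velocity(
    list(data.frame(peak_deg_s = numeric(0)))), "undefined")
})

test_that("freeze probability is the standardised logistic", {
  f <- c(arrhythmicity6 = 10, asymmetry6 = 5, stride_time_last = 1,
         swing_range_last = 60)
  m0 <- freeze_model(0, rep(0, 4))
  expect_equal(freeze_probability(f, m0), 0.5)
  m2 <- freeze_model(-2, rep(0, 4))
  expect_equal(freeze_probability(f, m2), 1 / (1 + exp(2)), tolerance = 1e-9)
  expect_equal(freeze_probability(f, m2), 0.1192, tolerance = 1e-3)
  # monotone in a positively weighted feature
  m <- freeze_model(0, c(1, 0, 0, 0))
  p <- vapply(c(5, 10, 20), function(a) {
    f["arrhythmicity6"] <- a
    freeze_probability(f, m)
  }, numeric(1))
  expect_true(all(diff(p) > 0))
  expect_error(freeze_probability(c(arrhythmicity6 = 1), m0), "feature")
})

test_that("fitted freeze model separates planted freezes and is seed-stable", {
  model <- fixture_freeze_model()
  expect_gte(model$auroc, 0.9)
  # determinism
  model2 <- fit_freeze_model(fixture_freeze_corpus(), seed = 301)
  expect_identical(model$betas, model2$betas)
  # label shuffling destroys discrimination
  corpus <- fixture_freeze_corpus()
  corpus$freeze <- with_seed(99, sample(corpus$freeze))
  null_model <- fit_freeze_model(corpus, seed = 302)
  expect_gte(null_model$auroc, 0.35)
  expect_lte(null_model$auroc, 0.65)
  # single-class corpus cannot be fitted
  one <- fixture_freeze_corpus()
  one$freeze <- 0L
  expect_error(fit_freeze_model(one, seed = 1), "single class")
})

test_that("logistic detection recovers planted freezes on fresh trials", {
  model <- fixture_freeze_model()
  # regular walking: no freezes
  ok <- synth_tbc(tbc_params(freeze_fraction = 0), seed = 401)
  tabs <- lapply(ok$imu, function(mc)
    segment_strides_imu(extract_sagittal(mc)))
  fz0 <- detect_freezes_logistic(tabs$left, tabs$right, model, 60)
  expect_lt(fz0$percent_of_trial, 5)
  # planted freeze segment: detected interval overlaps (IoU >= 0.5)
  tr <- synth_tbc(tbc_params(freeze_fraction = 0.3), seed = 402)
  tabs2 <- lapply(tr$imu, function(mc)
    segment_strides_imu(extract_sagittal(mc)))
  fz <- detect_freezes_logistic(tabs2$left, tabs2$right, model, 60)
  truth <- tr$truth$freeze_intervals
  inter <- sum(vapply(seq_len(nrow(fz$intervals)), function(i)
    interval_overlap_test(fz$intervals$start_s[i], fz$intervals$end_s[i],
                          truth), numeric(1)))
  uni <- fz$total_s + sum(truth$end_s - truth$start_s) - inter
  expect_gte(inter / uni, 0.5)
  # too few steps: warning and empty intervals
  tiny <- tabs$left[1:3, ]
  expect_warning(
    out <- detect_freezes_logistic(tiny, tabs$right[1:2, ], model, 60),
    "fewer than 7")
  expect_equal(nrow(out$intervals), 0L)
})

test_that("wrist metrics match closed forms", {
  w <- synth_wrist(freq_hz = 1.5, amplitude_deg_s = 100, noise_sd = 0,
                   seed = 1)
  expect_lt(abs(wrist_vrms(w$hand) - 100 / sqrt(2)) / (100 / sqrt(2)), 0.02)
  expect_lt(abs(wrist_cycles_per_second(w$hand) - 1.5), 0.04)
  # zero signal
  z <- time_series(rep(0, 128 * 10), 128)
  expect_equal(wrist_vrms(z), 0)
  expect_equal(wrist_cycles_per_second(z), 0)
  # 10 Hz sinusoid is crushed by the 4 Hz cut-off
  fs <- 128
  t <- seq(0, 10, by = 1 / fs)
  fast <- time_series(100 * sin(2 * pi * 10 * t), fs)
  expect_lt(wrist_vrms(fast), 0.05 * (100 / sqrt(2)))
  # drift without oscillation: zero crossings after demeaning only
  drift <- time_series(seq(0, 50, length.out = 1280), 128)
  expect_lte(wrist_cycles_per_second(drift), 0.2)
  expect_error(wrist_vrms(time_series(rnorm(100), 128)), "at least")
})

test_that("vrms shrinks with planted movement amplitude", {
  v <- vapply(c(120, 80, 40), function(a)
    wrist_vrms(synth_wrist(amplitude_deg_s = a, seed = 5)$hand), numeric(1))
  expect_true(all(diff(v) < 0))
})

test_that("symmetric walking yields near-zero IMU asymmetry and arrhythmicity", {
  s <- synth_tbc(tbc_params(stride_cv = 0.01, noise_sd = 3), seed = 77)
  tabs <- lapply(s$imu, function(mc) segment_strides_imu(extract_sagittal(mc)))
  asym <- asymmetry(tabs$left$swing_s, tabs$right$swing_s)
  arr <- arrhythmicity(tabs$left$stride_s[-1L], tabs$right$stride_s[-1L])
  expect_lt(asym, 2)
  expect_lt(arr, 3)
})
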