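fs <- 500

test_that("envelope of a pure beta sinusoid is its squared amplitude", {
  t <- seq(0, 20, by = 1 / fs)
  env <- compute_envelope(time_series(0.8 * sin(2 * pi * 15 * t), fs),
                          band_config(15))
  core <- env$values[2000:8000]
  expect_true(all(abs(core - 0.64) < 0.064))
  expect_error(compute_envelope(time_series(rep(0, 5000), fs),
                                band_config(15)), "degenerate")
})

test_that("envelope tracks an amplitude step within the interpolation lag", {
  t <- seq(0, 10, by = 1 / fs)
  amp <- ifelse(t < 5, 0.2, 1.0)
  env <- compute_envelope(time_series(amp * sin(2 * pi * 15 * t), fs),
                          band_config(15))
  cross <- ts_time(env)[which(env$values > 0.5)[1L]]
  expect_lt(abs(cross - 5), 0.25)
})

test_that("gamma-trough power threshold matches closed forms", {
  t <- seq(0, 30, by = 1 / fs)
  # pure 55 Hz sinusoid: envelope ~ A^2, troughs ~ A^2
  thr <- power_threshold_from_gamma(time_series(0.5 * sin(2 * pi * 55 * t), fs))
  expect_lt(abs(thr - 0.25) / 0.25, 0.1)
  # white noise: trough mean below the envelope mean, above zero
  set.seed(7)
  lfp <- time_series(rnorm(length(t)), fs)
  thr2 <- power_threshold_from_gamma(lfp)
  env <- compute_envelope(lfp, band_config(55, 20, beta = FALSE))
  expect_gt(thr2, 0)
  expect_lt(thr2, mean(env$values))
  # beta-only signal: threshold near the leakage floor, positive
  thr3 <- power_threshold_from_gamma(time_series(sin(2 * pi * 15 * t), fs))
  expect_gt(thr3, 0)
  expect_lt(thr3, 0.01)
  expect_error(power_threshold_from_gamma(time_series(rnorm(1000), fs)),
               "shorter")
})

test_that("extract_bursts matches constructed crossings and the brute-force scan", {
  env <- time_series(c(rep(0, 1000), rep(2, 150), rep(0, 1000)), fs)
  b <- extract_bursts(env, 1)
  expect_equal(nrow(b), 1L)
  expect_equal(b$onset_s, 2.0)
  expect_equal(b$duration_s, 0.3)
  expect_false(b$ongoing)

  expect_equal(nrow(extract_bursts(time_series(rep(0.5, 100), fs), 1)), 0L)

  # square wave with 10 plateaus against the per-sample oracle
  sq <- time_series(rep(rep(c(0, 2), 10), each = 50), fs)
  got <- extract_bursts(sq, 1)
  ref <- brute_bursts(sq$values, 1, fs)
  expect_equal(nrow(got), 10L)
  expect_equal(got, ref)

  # random envelopes: exact agreement with the oracle
  set.seed(42)
  for (k in 1:20) {
    env_v <- random_envelope(1500)
    got <- extract_bursts(time_series(env_v, fs), 1)
    expect_equal(got, brute_bursts(env_v, 1, fs))
  }
})

test_that("raising the threshold shrinks bursts and total burst time", {
  set.seed(9)
  env_v <- abs(cumsum(rnorm(5000))) / 10
  thrs <- c(0.5, 1, 1.5, 2, 3)
  tabs <- lapply(thrs, function(thr)
    extract_bursts(time_series(env_v, fs), thr))
  totals <- vapply(tabs, function(b) sum(b$duration_s), numeric(1))
  expect_true(all(diff(totals) <= 1e-12))
  # nesting: every burst at a higher threshold lies inside one at a lower
  for (k in 2:length(tabs)) {
    hi <- tabs[[k]]; lo <- tabs[[k - 1L]]
    if (!nrow(hi)) next
    inside <- vapply(seq_len(nrow(hi)), function(i)
      any(lo$onset_s <= hi$onset_s[i] & lo$offset_s >= hi$offset_s[i]),
      logical(1))
    expect_true(all(inside))
  }
})

test_that("current_burst_duration reports ongoing, last-completed and empty states", {
  trk <- burst_tracker(1, rate = 100)
  expect_error(current_burst_duration(trk), "empty")
  # never above threshold
  tracker_ingest(trk, rep(0.5, 200))
  expect_equal(current_burst_duration(trk), 0)
  # ongoing burst started 0.42 s ago (42 samples at 100 Hz)
  tracker_ingest(trk, rep(2, 42))
  expect_equal(current_burst_duration(trk), 0.42, tolerance = 1e-9)
  # completed burst of 0.25 s, then 1 s below threshold
  trk2 <- burst_tracker(1, rate = 100)
  tracker_ingest(trk2, c(rep(0, 50), rep(2, 25), rep(0, 100)))
  expect_equal(current_burst_duration(trk2), 0.25, tolerance = 1e-9)
  # capped at capacity
  trk3 <- burst_tracker(1, rate = 100, capacity_s = 2)
  tracker_ingest(trk3, rep(2, 500))
  expect_equal(current_burst_duration(trk3), 2)
})

test_that("blanking bridges or truncates bursts per the hold contract", {
  # burst ongoing, blank 0.5 s, still above after: single bridged burst
  trk <- burst_tracker(1, rate = 100)
  blank_interval(trk, 1.0, 0.5)
  tracker_ingest(trk, c(rep(2, 150), rep(2, 50), rep(0, 100)))
  ev <- collected_bursts(trk)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$onset_s, 0)
  expect_equal(ev$offset_s, 2.0)

  # burst ongoing, blank, below after: offset at blank start
  trk2 <- burst_tracker(1, rate = 100)
  blank_interval(trk2, 1.0, 0.5)
  tracker_ingest(trk2, c(rep(2, 100), rep(2, 50), rep(0, 150)))
  ev2 <- collected_bursts(trk2)
  expect_equal(nrow(ev2), 1L)
  expect_equal(ev2$offset_s, 1.0)
  expect_equal(ev2$duration_s, 1.0)

  # blank covering everything new: duration query returns pre-blank answer
  trk3 <- burst_tracker(1, rate = 100)
  tracker_ingest(trk3, c(rep(0, 50), rep(2, 30), rep(0, 20)))
  before <- current_burst_duration(trk3)
  blank_interval(trk3, 1.0, 10)
  tracker_ingest(trk3, rep(2, 300))
  expect_equal(current_burst_duration(trk3), before)
})

test_that("streaming detector equals offline pipeline for any chunking", {
  set.seed(31)
  sig <- synth_lfp(duration_s = 30, seed = 77)
  thr <- power_threshold_from_gamma(sig$lfp)
  off <- extract_bursts(compute_envelope(sig$lfp, band_config(15)), thr)
  for (chunk_fn in list(function() 25L,          # 50 ms chunks
                        function() sample(1:400, 1L),
                        function() 1L)) {
    det <- burst_detector(band_config(15), thr)
    got <- chunked_ingest(det, sig$lfp$values, chunk_fn)
    expect_equal(got$onset_s, off$onset_s, tolerance = 1e-9)
    expect_equal(got$offset_s, off$offset_s, tolerance = 1e-9)
    expect_equal(got$ongoing, off$ongoing)
  }
  # empty chunk leaves state unchanged
  det <- burst_detector(band_config(15), thr)
  stream_process(det, sig$lfp$values[1:1000])
  n_before <- det$n_in
  expect_equal(nrow(stream_process(det, numeric(0))), 0L)
  expect_equal(det$n_in, n_before)
  # rate mismatch is an error
  expect_error(stream_process(det, time_series(rnorm(10), 250)), "rate")
})

test_that("planted burst durations are recovered at realistic SNR", {
  # default generator (SNR ~ 14) and a low-SNR variant (~3)
  for (amp in c(1, 0.45)) {
    s <- synth_lfp(plant_params(burst_amp = amp), stim = 0,
                   duration_s = 120, seed = 13)
    thr <- power_threshold_from_gamma(s$lfp)
    b <- extract_bursts(compute_envelope(s$lfp, band_config(15)), thr)
    b <- b[!b$ongoing, ]
    expect_lt(abs(mean(b$duration_s) - mean(s$truth$duration_s)) /
                mean(s$truth$duration_s), 0.15)
  }
})
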