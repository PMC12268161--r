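win <- therapeutic_window(1.5, 3.5, 3.0)

test_that("therapeutic window enforces the 125% clinical cap", {
  expect_error(therapeutic_window(1, 4, 3), "125")
  expect_error(therapeutic_window(0, 2, 3), "i_min")
  w <- therapeutic_window(2, 3.75, 3)
  expect_equal(w$i_max_ma, 3.75)
})

test_that("decision rule increments only for strictly longer bursts", {
  expect_equal(decide(0.40, 0.35), 1L)
  expect_equal(decide(0.30, 0.35), -1L)
  expect_equal(decide(0.35, 0.35), -1L)   # ties decrement
  expect_error(decide(-0.1, 0.35), ">= 0")
})

test_that("apply_step respects per-direction dwell times and window clamps", {
  cfg <- hemisphere_config(band = band_config(15), power_threshold = 1,
                           duration_threshold_s = 0.3, window = win)
  st <- burstloop:::hemisphere_state(cfg, init_ma = 2.0)
  # up steps need 1.0 s dwell (0.1 mA at 0.1 mA/s)
  expect_true(apply_step(st, cfg, 1L, 0))
  expect_false(apply_step(st, cfg, 1L, 0.5))
  expect_true(apply_step(st, cfg, 1L, 1.0))
  expect_equal(st$amplitude_ma, 2.2)
  # down steps need 2.0 s dwell
  st2 <- burstloop:::hemisphere_state(cfg, init_ma = 3.0)
  times <- seq(1, 10)
  executed <- vapply(times, function(t) apply_step(st2, cfg, -1L, t),
                     logical(1))
  expect_equal(diff(times[executed]), rep(2, sum(executed) - 1L))
  # clamping at i_max is silent but logged
  st3 <- burstloop:::hemisphere_state(cfg, init_ma = 3.5)
  expect_false(apply_step(st3, cfg, 1L, 0))
  expect_equal(st3$amplitude_ma, 3.5)
  lg <- burstloop:::decision_log_df(st3)
  expect_false(lg$executed[1L])
})

test_that("hold_continuous and the TEED proxy match closed forms", {
  tr <- hold_continuous(3.0, 100)
  expect_equal(unique(tr$values), 3.0)
  expect_equal(ts_duration(tr), 100)
  expect_equal(teed_proxy(tr), 3^2 * 140.1 * 60e-6 * 100)
  expect_length(hold_continuous(3.0, 0)$values, 0)
  expect_equal(teed_proxy(time_series(rep(0, 50), 1)), 0)
  # two-level trace: piecewise integral
  two <- time_series(c(rep(2, 50), rep(4, 50)), 1)
  expect_equal(teed_proxy(two), 140.1 * 60e-6 * 100 * (4 + 16) / 2)
})

test_that("saturating plants drive the staircase to the window edges", {
  cfg <- hemisphere_config(band = band_config(15), power_threshold = 0.065,
                           duration_threshold_s = 0.05, window = win)
  # durations always far above threshold: monotone ramp to i_max, then hold
  plant <- lfp_plant(plant_params(d0_s = 0.8, k_s_per_ma = 0), seed = 3)
  res <- run_adaptive(plant, cfg, duration_s = 60)
  v <- res$stim[[1L]]$values
  expect_true(all(diff(v) >= -1e-12))
  expect_true(all(diff(v) <= 0.1 + 1e-12))        # <= 0.1 mA/s
  expect_equal(v[length(v)], win$i_max_ma)
  # durations always below threshold: amplitude stays at i_min
  cfg2 <- hemisphere_config(band = band_config(15), power_threshold = 0.065,
                            duration_threshold_s = 3, window = win)
  plant2 <- lfp_plant(plant_params(), seed = 4)
  res2 <- run_adaptive(plant2, cfg2, duration_s = 30)
  expect_equal(unique(res2$stim[[1L]]$values), win$i_min_ma)
})

test_that("closed-loop traces satisfy bound, rate and quantisation invariants", {
  cfg <- hemisphere_config(band = band_config(15), power_threshold = 0.065,
                           duration_threshold_s = 0.26, window = win)
  for (seed in 1:3) {
    plant <- lfp_plant(plant_params(d0_s = 1.1, k_s_per_ma = 0.3), seed)
    res <- run_adaptive(plant, cfg, duration_s = 120)
    v <- res$stim[[1L]]$values
    expect_true(all(v >= win$i_min_ma - 1e-9 & v <= win$i_max_ma + 1e-9))
    expect_true(all(abs(v - (win$i_min_ma +
                               round((v - win$i_min_ma) / 0.1) * 0.1)) < 1e-9))
    # sliding 10 s window rate bounds
    for (k in seq(1, length(v) - 10, by = 5)) {
      d <- diff(v[k:(k + 10)])
      expect_lte(sum(d[d > 0]), 0.1 * 10 + 0.1 + 1e-9)
      expect_lte(-sum(d[d < 0]), 0.05 * 10 + 0.1 + 1e-9)
    }
  }
})

test_that("hemispheres are independent given fixed seeds", {
  mk <- function(thr2) list(
    hemisphere_config(band = band_config(15), power_threshold = 0.065,
                      duration_threshold_s = 0.26, window = win,
                      side = "left"),
    hemisphere_config(band = band_config(15), power_threshold = 0.065,
                      duration_threshold_s = thr2, window = win,
                      side = "right"))
  run <- function(cfgs) {
    plants <- list(lfp_plant(plant_params(d0_s = 1.1, k_s_per_ma = 0.3), 21),
                   lfp_plant(plant_params(d0_s = 1.1, k_s_per_ma = 0.3), 22))
    run_adaptive(plants, cfgs, duration_s = 60)
  }
  a <- run(mk(0.26))
  b <- run(mk(0.8))     # change only the contralateral threshold
  expect_identical(a$stim[[1L]]$values, b$stim[[1L]]$values)
  expect_false(identical(a$stim[[2L]]$values, b$stim[[2L]]$values))
})

test_that("held_at_clinical hemispheres never change amplitude", {
  cfgs <- list(hemisphere_config(window = win, mode = "held_at_clinical"))
  res <- run_adaptive(list(lfp_plant(seed = 5)), cfgs, duration_s = 20)
  expect_equal(unique(res$stim[[1L]]$values), win$clinical_ma)
})

test_that("rDBS shuffles match source TEED and honour all constraints", {
  cfg <- hemisphere_config(band = band_config(15), power_threshold = 0.065,
                           duration_threshold_s = 0.26, window = win)
  plant <- lfp_plant(plant_params(d0_s = 1.1, k_s_per_ma = 0.3), 31)
  res <- run_adaptive(plant, cfg, duration_s = 150)
  pat <- loop_pattern(res)
  te_a <- teed_proxy(res$stim[[1L]])
  r1 <- generate_rdbs(pat, seed = 1)
  r1b <- generate_rdbs(pat, seed = 1)
  expect_identical(r1$values, r1b$values)            # deterministic in seed
  for (s in 1:10) {
    r <- generate_rdbs(pat, seed = s)
    expect_lt(abs(teed_proxy(r) - te_a) / te_a, 0.05)
    expect_true(all(r$values >= win$i_min_ma - 1e-9 &
                      r$values <= win$i_max_ma + 1e-9))
    expect_true(all(abs(diff(r$values)) <= 0.1 + 1e-9))
  }
  # zero-step pattern: constant trace returned unchanged
  hold <- hold_continuous(2.5, 60)
  pat0 <- adaptation_pattern(
    data.frame(time_s = numeric(0), burst_s = numeric(0),
               direction = integer(0), executed = logical(0),
               amplitude_ma = numeric(0)), hold)
  expect_equal(generate_rdbs(pat0, seed = 2)$values, hold$values)
})

test_that("raising the duration threshold never raises mean amplitude", {
  means <- vapply(c(0.2, 0.3, 0.45), function(tau) {
    cfg <- hemisphere_config(band = band_config(15), power_threshold = 0.065,
                             duration_threshold_s = tau, window = win)
    plant <- lfp_plant(plant_params(d0_s = 1.1, k_s_per_ma = 0.3), 55)
    res <- run_adaptive(plant, cfg, duration_s = 120)
    mean(res$stim[[1L]]$values)
  }, numeric(1))
  expect_true(all(diff(means) <= 1e-9))
})
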