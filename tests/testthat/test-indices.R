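test_that("cross-spectral phase recovers analytic lags", {
  # closed form: the cross-spectrum phase of two sinusoids at the same
  # frequency equals their lag
  rec <- simulate_breathing(rate_bpm = 15, phase_lag_deg = 90, duration_s = 180,
                            seed = 1)
  ph <- estimate_phase(rec)
  expect_true(all(abs(ph$phase_deg - 90) < 1))
  # signed phase keeps the direction (abd lags rc -> positive)
  expect_true(all(ph$signed_phase_deg > 0))

  sync <- estimate_phase(simulate_breathing(phase_lag_deg = 0, seed = 2))
  expect_true(all(sync$phase_deg < 1))

  para <- estimate_phase(simulate_breathing(phase_lag_deg = 180, seed = 3))
  expect_true(all(abs(para$phase_deg - 180) < 1))
})

test_that("windows with a dead channel are skipped, all-dead errors", {
  t <- seq(0, 120, by = 0.02)
  rec <- band_recording(
    data.frame(t = t, rc = ifelse(t <= 89, sin(2 * pi * 0.3 * t), 0),
               abd = sin(2 * pi * 0.3 * t)), fs = 50)
  expect_warning(ph <- estimate_phase(rec, window_s = 30, step_s = 30),
                 "zero-variance")
  expect_identical(nrow(ph), 3L)

  flat <- band_recording(data.frame(t = t, rc = 0, abd = 0), fs = 50)
  expect_error(suppressWarnings(estimate_phase(flat)), "No usable window")
})

test_that("%RC reflects the amplitude split and complements to 100", {
  eq <- compute_rc_percent(simulate_breathing(seed = 4))
  expect_true(all(abs(eq$rc_percent - 50) < 0.5))

  skew <- simulate_breathing(amp_rc = 3, amp_abd = 1, seed = 5)
  expect_true(all(abs(compute_rc_percent(skew)$rc_percent - 75) < 1))

  none <- simulate_breathing(amp_rc = 0, amp_abd = 1, seed = 6)
  expect_true(all(compute_rc_percent(none)$rc_percent < 0.5))

  # mirrored formula: swapping the channels gives the complement
  swapped <- band_recording(
    data.frame(t = skew$t, rc = skew$abd, abd = skew$rc), fs = 50)
  expect_equal(compute_rc_percent(skew)$rc_percent +
                 compute_rc_percent(swapped)$rc_percent,
               rep(100, nrow(compute_rc_percent(skew))), tolerance = 1e-9)
})

test_that("LBI matches analytic values and diverges at cancellation", {
  expect_true(all(abs(compute_lbi(simulate_breathing(seed = 7))$lbi - 1) < 0.01))
  # equal unit amplitudes at 90 degrees: sum amplitude sqrt(2), LBI = sqrt(2)
  l90 <- compute_lbi(simulate_breathing(phase_lag_deg = 90, seed = 8))
  expect_true(all(abs(l90$lbi - 2 / sqrt(2)) < 0.02))
  # perfect paradoxical cancellation: infinity sentinel
  expect_warning(
    l180 <- compute_lbi(simulate_breathing(phase_lag_deg = 180, seed = 9)),
    "cancellation")
  expect_true(all(is.infinite(l180$lbi)))
})

test_that("LBI is >= 1 and non-decreasing in the generated lag", {
  lags <- seq(0, 180, by = 30)
  mean_lbi <- vapply(lags, function(lag) {
    rec <- simulate_breathing(phase_lag_deg = lag, amp_rc = 1, amp_abd = 0.8,
                              noise_sd = 0.01, duration_s = 90, seed = 31)
    mean(compute_lbi(rec)$lbi)
  }, numeric(1))
  expect_true(all(mean_lbi >= 1))
  expect_true(all(diff(mean_lbi) >= -1e-6))
})

test_that("respiratory rate estimation hits the generated rate", {
  expect_equal(estimate_rr(simulate_breathing(rate_bpm = 20, seed = 10)),
               20, tolerance = 0.2)
  expect_equal(estimate_rr(simulate_breathing(rate_bpm = 12, seed = 11)),
               12, tolerance = 0.2)
  t <- seq(0, 60, 0.02)
  expect_error(estimate_rr(band_recording(data.frame(t = t, rc = 0, abd = 0),
                                          fs = 50)), "flat")
  expect_error(estimate_rr(simulate_breathing(duration_s = 10, seed = 1)),
               "30 s")
})

test_that("compute_indices composes the per-window series coherently", {
  rec <- simulate_breathing(rate_bpm = 20, phase_lag_deg = 120,
                            noise_sd = 0.05, rate_jitter_sd = 0.5,
                            duration_s = 180, seed = 12)
  idx <- compute_indices(rec)
  s <- summarise_indices(idx)
  expect_gt(s$mean_phase_deg, 115)
  expect_lt(s$mean_phase_deg, 125)
  expect_equal(s$rr_bpm, 20, tolerance = 1)
  expect_identical(nrow(idx), 31L)  # (180 - 30)/5 + 1 full windows

  sync <- summarise_indices(compute_indices(simulate_breathing(seed = 13)))
  expect_lt(sync$mean_phase_deg, 2)
  expect_lt(sync$mean_lbi, 1.02)
  expect_gt(sync$mean_rc_percent, 49.5)
  expect_lt(sync$mean_rc_percent, 50.5)

  # window longer than the recording: single whole-recording window
  short <- compute_indices(simulate_breathing(duration_s = 40, seed = 14),
                           window_s = 60, step_s = 5)
  expect_identical(nrow(short), 1L)
})

test_that("indices are invariant to recalibration of both channels", {
  rec <- simulate_breathing(phase_lag_deg = 60, amp_rc = 1.2, amp_abd = 0.9,
                            noise_sd = 0.03, duration_s = 90, seed = 15)
  scaled <- band_recording(
    data.frame(t = rec$t, rc = 3.7 * rec$rc, abd = 3.7 * rec$abd), fs = 50)
  a <- compute_indices(rec)
  b <- compute_indices(scaled)
  expect_equal(b$phase_deg, a$phase_deg, tolerance = 1e-9)
  expect_equal(b$rc_percent, a$rc_percent, tolerance = 1e-9)
  expect_equal(b$lbi, a$lbi, tolerance = 1e-9)
  expect_equal(attr(b, "rr_bpm"), attr(a, "rr_bpm"), tolerance = 1e-9)
})

test_that("index series CSV + sidecar round-trips", {
  idx <- compute_indices(simulate_breathing(duration_s = 60, seed = 16))
  f <- withr::local_tempfile(fileext = ".csv")
  write_indices(idx, f)
  idx2 <- read_indices(f)
  expect_equal(idx2$phase_deg, idx$phase_deg)
  expect_equal(attr(idx2, "rr_bpm"), attr(idx, "rr_bpm"))
  expect_equal(attr(idx2, "window_s"), 30)
})
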