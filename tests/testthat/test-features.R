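feat_for <- function(tech, seed = 1, ...) {
  f <- gen_filtered(tech, seed = seed, ...)
  seg <- segment_cycles(f, technique_family(tech))
  list(f = f, seg = seg, fv = extract_features(f, seg))
}

test_that("every technique's features satisfy its signature clauses", {
  # conformance matrix: one row of expectations per technique
  x <- feat_for("DP")$fv
  expect_gte(x$pitch_peak_dps, 75)
  expect_lt(x$roll_peak_dps, 20)
  expect_lt(x$yaw_peak_dps, 20)
  expect_false(x$sidea_regular)
  expect_equal(x$fwd_peaks_per_cycle, 1)
  expect_true(x$pitch_precedes_fwd)

  x <- feat_for("KDP")$fv
  expect_gte(x$pitch_peak_dps, 75)
  expect_gte(x$roll_peak_dps, 20)
  expect_false(x$sidea_regular)
  expect_true(x$fwd_major_minor)       # minor kick peak + major poling peak
  expect_true(x$pitch_precedes_fwd)

  x <- feat_for("DS")$fv
  expect_lt(x$pitch_peak_dps, 50)
  expect_gte(x$roll_peak_dps, 20)
  expect_false(x$sidea_regular)
  expect_equal(x$fwd_peaks_per_cycle, 2)  # two even kick peaks
  expect_false(x$fwd_major_minor)

  x <- feat_for("G2")$fv
  expect_true(x$sidea_regular)
  expect_gte(x$pitch_peak_dps, 50)
  expect_gte(x$roll_peak_dps, 50)
  expect_gt(x$yaw_pitch_lag, 0.02)     # yaw just after pitch
  expect_false(x$fwd_major_minor)      # double peak, not major+minor

  x <- feat_for("G3")$fv
  expect_true(x$sidea_regular)
  expect_gte(x$pitch_peak_dps, 75)
  expect_equal(x$pitch_yaw_ratio, 2, tolerance = 0.1)

  x <- feat_for("G4")$fv
  expect_true(x$sidea_regular)
  expect_gte(x$pitch_peak_dps, 75)
  expect_equal(x$pitch_yaw_ratio, 1, tolerance = 0.1)
  expect_lt(x$yaw_pitch_lag, -0.02)    # yaw precedes pitch
  expect_true(x$fwd_major_minor)

  x <- feat_for("G5")$fv
  expect_true(x$sidea_regular)
  expect_lt(x$pitch_peak_dps, 40)      # no poling
})

test_that("zero-noise diagonal stride has exactly two fwd_a peaks per cycle", {
  r <- feat_for("DS", noise_sd_accel = 0, noise_sd_gyro = 0,
                hf_noise_accel = 0, hf_noise_gyro = 0)
  expect_identical(as.numeric(r$fv$fwd_peaks_per_cycle), 2)
})

test_that("yaw-pitch timing recovers the generator's phase offsets", {
  r4 <- feat_for("G4")
  expect_lt(abs(yaw_pitch_timing(r4$f, r4$seg) - (-0.10)), 0.03)
  r2 <- feat_for("G2")
  expect_lt(abs(yaw_pitch_timing(r2$f, r2$seg) - 0.05), 0.03)
  # identical pitch and yaw channels: zero lag by construction
  f <- r4$f
  f$yaw <- f$pitch
  seg <- segment_cycles(f, "skating")
  expect_lt(abs(yaw_pitch_timing(f, seg)), 0.01)
})

test_that("the poling pitch peak precedes the fwd_a peak, and flips if delayed", {
  for (tech in c("DP", "KDP", "DS", "G2", "G3", "G4")) {
    r <- feat_for(tech)
    expect_true(pitch_fwd_order(r$f, r$seg), label = tech)
  }
  # push the pitch peak after the fwd_a peak: ordering must invert
  r <- feat_for("DP", phase = c(pitch = 0.30, fwd_a = 0.15))
  expect_false(pitch_fwd_order(r$f, r$seg))
})

test_that("single-time skating has a wider yaw trough than peak", {
  r4 <- feat_for("G4")$fv
  r2 <- feat_for("G2")$fv
  expect_gt(r4$yaw_trough_width_ratio, 1.1)
  expect_equal(r2$yaw_trough_width_ratio, 1, tolerance = 0.1)
})

test_that("features are stable under a one-cycle time shift", {
  r <- feat_for("G4", seed = 8)
  f2 <- r$f
  cut <- round(r$f$sample_rate_hz / default_params("G4")$cycle_rate_hz)
  n <- n_samples(f2)
  for (ch in c("fwd_a", "side_a", "up_a", "roll", "pitch", "yaw"))
    f2[[ch]] <- f2[[ch]][(cut + 1):n]
  seg2 <- segment_cycles(f2, "skating")
  fv2 <- extract_features(f2, seg2)
  expect_lt(abs(fv2$pitch_peak_dps - r$fv$pitch_peak_dps),
            0.02 * r$fv$pitch_peak_dps)
  expect_lt(abs(fv2$yaw_pitch_lag - r$fv$yaw_pitch_lag), 0.02)
  expect_equal(fv2$fwd_peaks_per_cycle, r$fv$fwd_peaks_per_cycle)
  expect_lt(abs(fv2$pitch_yaw_ratio - r$fv$pitch_yaw_ratio), 0.15)
})

test_that("amplitude features scale linearly with a global channel gain", {
  r <- feat_for("G4", seed = 5)
  f2 <- r$f
  for (ch in c("fwd_a", "side_a", "up_a", "roll", "pitch", "yaw"))
    f2[[ch]] <- 2 * f2[[ch]]
  fv2 <- extract_features(f2, segment_cycles(f2, "skating"))
  expect_equal(fv2$pitch_peak_dps, 2 * r$fv$pitch_peak_dps,
               tolerance = 0.01 * 2 * r$fv$pitch_peak_dps)
  expect_equal(fv2$roll_peak_dps, 2 * r$fv$roll_peak_dps,
               tolerance = 0.01 * 2 * r$fv$roll_peak_dps)
  expect_equal(fv2$sidea_peak_g, 2 * r$fv$sidea_peak_g,
               tolerance = 0.02 * 2 * r$fv$sidea_peak_g)
})

test_that("feature extraction refuses fewer than two cycles", {
  f <- gen_filtered("DP", seed = 1)
  seg <- segment_cycles(f, "classical")
  seg$boundaries <- seg$boundaries[1:2]
  seg$n_cycles <- 1L
  expect_error(extract_features(f, seg), "2 cycles")
})
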