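test_that("gravity components reproduce the mounting contract", {
  expect_equal(unname(gravity_components(0)), c(1, 0))
  expect_equal(unname(gravity_components(90)), c(0, 1), tolerance = 1e-12)
  expect_equal(unname(gravity_components(30)), c(cos(pi / 6), 0.5),
               tolerance = 1e-6)
  expect_error(gravity_components(-1), "\\[0, 90\\]")
  expect_error(gravity_components(91), "\\[0, 90\\]")
})

test_that("with no movement or noise the acceleration norm is 1 g at any lean", {
  for (lean in c(0, 15, 37.5, 60, 90)) {
    p <- default_params("DP", trunk_lean_deg = lean, tap_marker = FALSE,
                        noise_sd_accel = 0, noise_sd_gyro = 0,
                        hf_noise_accel = 0, hf_noise_gyro = 0,
                        amp = c(fwd_a = 0, side_a = 0, up_a = 0,
                                roll = 0, pitch = 0, yaw = 0))
    s <- generate_imu(p)
    norm <- sqrt(s$fwd_a^2 + s$side_a^2 + s$up_a^2)
    expect_equal(norm, rep(1, n_samples(s)), tolerance = 1e-9)
  }
})

test_that("default parameters encode the poling and kick signature levels", {
  expect_gt(default_params("DP")$amp[["pitch"]], 75)
  expect_gt(default_params("KDP")$amp[["pitch"]], 75)
  expect_lt(default_params("DS")$amp[["pitch"]], 50)
  expect_gt(default_params("G2")$amp[["pitch"]], 50)
  expect_lt(default_params("G5")$amp[["pitch"]], 40)
  expect_lt(default_params("DP")$amp[["roll"]], 20)
  expect_gt(default_params("G2")$amp[["roll"]], 50)
  expect_gt(default_params("G5")$amp[["roll"]], 50)
  expect_equal(technique_family("DS"), "classical")
  expect_equal(technique_family("G3"), "skating")
})

test_that("generation is bit-reproducible under a fixed seed", {
  a <- generate_imu(default_params("G3", seed = 9))
  b <- generate_imu(default_params("G3", seed = 9))
  c <- generate_imu(default_params("G3", seed = 10))
  expect_identical(a$pitch, b$pitch)
  expect_identical(a$fwd_a, b$fwd_a)
  expect_false(identical(a$pitch, c$pitch))
})

test_that("generator does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_imu(default_params("DP", seed = 4)))
  expect_identical(.Random.seed, before)
})

test_that("quiet standing after the taps reads the leaned gravity level", {
  s <- generate_imu(default_params("DP", seed = 1))
  fs <- s$sample_rate_hz
  quiet <- s$fwd_a[round(1.3 * fs):round(3.1 * fs)]
  expect_equal(mean(quiet), cos(15 * pi / 180), tolerance = 0.02)
})

test_that("steeper trunk lean lowers mean fwd_a and raises mean up_a", {
  leans <- seq(0, 40, by = 10)
  res <- vapply(leans, function(l) {
    s <- generate_imu(default_params("DS", trunk_lean_deg = l,
                                     tap_marker = FALSE, seed = 3))
    c(mean(s$fwd_a), mean(s$up_a))
  }, numeric(2))
  expect_true(all(diff(res[1, ]) < 0))
  expect_true(all(diff(res[2, ]) > 0))
})

test_that("double-time skating carries two pitch oscillations per skate cycle", {
  f <- gen_filtered("G3", seed = 2)
  up_cross <- function(x) sum(x[-length(x)] < 0 & x[-1] >= 0)
  seg <- segment_cycles(f, "skating")
  expect_equal(up_cross(f$pitch), 2 * seg$n_cycles, tolerance = 0.15)
})

test_that("lead-left offset skate inverts the yaw and roll curves only", {
  quiet <- list(noise_sd_accel = 0, noise_sd_gyro = 0,
                hf_noise_accel = 0, hf_noise_gyro = 0)
  pR <- do.call(default_params, c(list("G2", lead_side = "R",
                                       tap_marker = FALSE, seed = 5), quiet))
  pL <- do.call(default_params, c(list("G2", lead_side = "L",
                                       tap_marker = FALSE, seed = 5), quiet))
  sR <- generate_imu(pR); sL <- generate_imu(pL)
  expect_equal(sL$yaw, -sR$yaw, tolerance = 1e-9)
  expect_equal(sL$roll, -sR$roll, tolerance = 1e-9)
  expect_equal(sL$side_a, sR$side_a, tolerance = 1e-9)
  expect_equal(sL$pitch, sR$pitch, tolerance = 1e-9)
})

test_that("fixture sets are labelled, complete and deterministic", {
  fx <- make_fixture_set(7, 3)
  expect_length(fx, 21)
  expect_equal(sort(unique(vapply(fx, `[[`, character(1), "label"))),
               sort(technique_labels()))
  fx2 <- make_fixture_set(7, 3)
  expect_identical(fx[[5]]$series$pitch, fx2[[5]]$series$pitch)
  expect_identical(fx[[20]]$params$seed, fx2[[20]]$params$seed)
})

test_that("a duration shorter than one cycle is rejected", {
  expect_error(generate_imu(default_params("DP", duration_s = 0.5)),
               "one full cycle")
})
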