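test_that("feature vectors map to the signature-table labels", {
  expect_equal(classify_features(fv_stub(pitch_peak_dps = 100,
                                         roll_peak_dps = 10))$label, "DP")
  expect_equal(classify_features(fv_stub(pitch_peak_dps = 100,
                                         roll_peak_dps = 40))$label, "KDP")
  expect_equal(classify_features(fv_stub(pitch_peak_dps = 40,
                                         roll_peak_dps = 40))$label, "DS")
  expect_equal(classify_features(fv_stub(sidea_regular = TRUE,
                                         pitch_peak_dps = 25))$label, "G5")
  expect_equal(classify_features(fv_stub(sidea_regular = TRUE,
                                         pitch_peak_dps = 90,
                                         pitch_yaw_ratio = 2))$label, "G3")
  expect_equal(classify_features(fv_stub(sidea_regular = TRUE,
                                         pitch_peak_dps = 90,
                                         yaw_pitch_lag = -0.1))$label, "G4")
  # offset skate is reached with 50-75 d/s pitch: never blocked by the
  # 75 d/s poling bound
  expect_equal(classify_features(fv_stub(sidea_regular = TRUE,
                                         pitch_peak_dps = 60,
                                         yaw_pitch_lag = +0.05))$label, "G2")
  # zero-band tie-break on the fwd_a pattern
  expect_equal(classify_features(fv_stub(sidea_regular = TRUE,
                                         pitch_peak_dps = 90,
                                         yaw_pitch_lag = 0.0,
                                         fwd_major_minor = TRUE))$label, "G4")
  expect_equal(classify_features(fv_stub(sidea_regular = TRUE,
                                         pitch_peak_dps = 90,
                                         yaw_pitch_lag = 0.0,
                                         fwd_major_minor = FALSE))$label, "G2")
  # unclassifiable combinations return a label-none result, not an error
  none <- classify_features(fv_stub(pitch_peak_dps = 60, roll_peak_dps = 10))
  expect_true(is.na(none$label))
  expect_gt(nrow(none$evidence), 0)
})

test_that("generated recordings round-trip to their own label", {
  for (seed in 1:3) for (tech in technique_labels()) {
    r <- classify_series(generate_imu(default_params(tech, seed = seed)))
    expect_equal(r$label, tech, label = sprintf("%s seed %d", tech, seed))
  }
})

test_that("offset skate classifies identically for either lead side", {
  for (seed in 1:3) {
    rR <- classify_series(generate_imu(default_params("G2", lead_side = "R",
                                                      seed = seed)))
    rL <- classify_series(generate_imu(default_params("G2", lead_side = "L",
                                                      seed = seed)))
    expect_equal(rR$label, "G2")
    expect_equal(rL$label, "G2")
  }
})

test_that("the evidence trail is self-consistent and replays to the label", {
  ops <- list(ge = `>=`, gt = `>`, le = `<=`, lt = `<`,
              eq = function(a, b) isTRUE(all.equal(a, b)),
              abs_le = function(a, b) abs(a) <= b)
  replay <- function(ev) {
    # the rule names encode the decision path
    rules <- ev$rule[ev$passed]
    if ("family_classical" %in% rules) {
      if (all(c("pitch_below_ds_max", "kick_roll_present") %in% rules)) return("DS")
      if (all(c("poling_pitch", "kick_roll_present") %in% rules)) return("KDP")
      if (all(c("poling_pitch", "no_kick_roll") %in% rules)) return("DP")
      return(NA_character_)
    }
    if ("no_poling_pitch" %in% rules) return("G5")
    if ("pitch_yaw_ratio_two" %in% rules) return("G3")
    if ("yaw_precedes_pitch" %in% rules || "fwd_major_minor" %in% rules) return("G4")
    if ("yaw_follows_pitch" %in% rules || "fwd_double_peak" %in% rules) return("G2")
    NA_character_
  }
  for (tech in technique_labels()) {
    r <- classify_series(generate_imu(default_params(tech, seed = 11)))
    ev <- r$evidence
    for (i in seq_len(nrow(ev)))
      expect_equal(ev$passed[i],
                   ops[[ev$op[i]]](ev$value[i], ev$threshold[i]),
                   label = paste(tech, ev$rule[i]))
    expect_equal(replay(ev), r$label, label = tech)
    expect_gte(r$confidence, 0)
    expect_lte(r$confidence, 1)
  }
})

test_that("pure noise yields a label-none result", {
  set.seed(31)
  n <- 1500
  s <- signal_series(1 + rnorm(n, sd = 0.05), rnorm(n, sd = 0.05),
                     rnorm(n, sd = 0.05), rnorm(n, sd = 5),
                     rnorm(n, sd = 5), rnorm(n, sd = 5))
  r <- classify_series(s)
  expect_true(is.na(r$label))
  expect_gt(nrow(r$evidence), 0)
})

test_that("labels are stable under moderate global gain changes", {
  for (tech in technique_labels()) {
    s <- generate_imu(default_params(tech, seed = 13))
    for (gain in c(0.9, 1.1)) {
      s2 <- s
      for (ch in c("fwd_a", "side_a", "up_a", "roll", "pitch", "yaw"))
        s2[[ch]] <- gain * s[[ch]]
      expect_equal(classify_series(s2)$label, tech,
                   label = sprintf("%s gain %.1f", tech, gain))
    }
  }
})

test_that("recordings shorter than five seconds are rejected", {
  expect_error(classify_series(make_series(300)), "5 s")
})
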