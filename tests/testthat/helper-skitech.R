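# shared fixtures: generate a technique recording without the tap-marker
# prefix, filter it with the defaults, and trim half a second at each end
# to clear filter transients
gen_filtered <- function(technique, seed = 1, guard_s = 0.5, ...) {
  s <- generate_imu(default_params(technique, tap_marker = FALSE,
                                   seed = seed, ...))
  f <- apply_lowpass(s)
  g <- round(guard_s * f$sample_rate_hz)
  n <- n_samples(f)
  for (ch in c("fwd_a", "side_a", "up_a", "roll", "pitch", "yaw"))
    f[[ch]] <- f[[ch]][(g + 1):(n - g)]
  f
}

make_series <- function(n, fs = 100, ...) {
  chans <- list(...)
  base <- list(fwd_a = numeric(n), side_a = numeric(n), up_a = numeric(n),
               roll = numeric(n), pitch = numeric(n), yaw = numeric(n))
  base[names(chans)] <- chans
  signal_series(base$fwd_a, base$side_a, base$up_a,
                base$roll, base$pitch, base$yaw, sample_rate_hz = fs)
}

# a bare feature vector for classifier unit tests
fv_stub <- function(...) {
  base <- list(pitch_peak_dps = 0, roll_peak_dps = 0, yaw_peak_dps = 0,
               sidea_peak_g = 0, sidea_cv = 0, sidea_regular = FALSE,
               fwd_peaks_per_cycle = 1, fwd_major_peaks_per_cycle = 1,
               fwd_major_minor = FALSE, pitch_yaw_ratio = 1,
               yaw_pitch_lag = 0, yaw_trough_width_ratio = 1,
               pitch_precedes_fwd = TRUE, n_cycles = 10, cycle_rate_hz = 0.8)
  over <- list(...)
  base[names(over)] <- over
  structure(base, class = "ski_features")
}
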