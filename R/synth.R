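#' Technique labels
#'
#' The seven sub-techniques covered: classical style `DP` (double pole),
#' `KDP` (kick double pole), `DS` (diagonal stride); skating gears `G2`
#' (offset skate), `G3` (double time), `G4` (single time), `G5` (free
#' skate, no poling).
#'
#' @param technique Technique code as a string.
#' @return `technique_family()` returns `"classical"` or `"skating"`.
#' @export
technique_labels <- function() c("DP", "KDP", "DS", "G2", "G3", "G4", "G5")

#' @rdname technique_labels
#' @export
technique_family <- function(technique) {
  technique <- match.arg(technique, technique_labels())
  if (technique %in% c("DP", "KDP", "DS")) "classical" else "skating"
}

#' Gravity components of the trunk-mounted unit
#'
#' With the athlete standing upright the unit's mounting puts the full
#' 1 g gravity reading on the forward/backward channel (`fwd_a`); rotating
#' the unit fully forward transfers it to the up/down channel (`up_a`).
#' Intermediate trunk lean splits gravity between the two as
#' `fwd = cos(lean)`, `up = sin(lean)`; the sideways channel carries no
#' gravity. Steeper terrain therefore reads as lower `fwd_a` and higher
#' `up_a` mean levels.
#'
#' @param trunk_lean_deg Forward trunk lean in degrees, in `[0, 90]`.
#' @return Named numeric vector `c(fwd_g=, up_g=)`.
#' @examples
#' gravity_components(0)   # upright: fwd 1, up 0
#' gravity_components(90)  # fully rotated forward: fwd 0, up 1
#' @export
gravity_components <- function(trunk_lean_deg) {
  if (!is.numeric(trunk_lean_deg) || length(trunk_lean_deg) != 1L ||
      is.na(trunk_lean_deg) || trunk_lean_deg < 0 || trunk_lean_deg > 90)
    stop("trunk_lean_deg must be in [0, 90]", call. = FALSE)
  th <- trunk_lean_deg * pi / 180
  c(fwd_g = cos(th), up_g = sin(th))
}

# Harmonic template per technique. Each channel is a sum of cosine
# components k (multiple of the cycle frequency) with relative weight
# `rel`, all centred on the channel's peak position `p` (cycle fraction).
# Peak positions encode the signature timing:
#   * the pitch (poling) peak precedes the main fwd_a peak by 0.15 cycle
#     in every poling technique;
#   * G4's yaw peak precedes its pitch peak by 0.10 cycle, G2's yaw peak
#     follows its pitch peak by 0.05 cycle;
#   * classical cycles are anchored on the yaw (kick) peak at phase 0
#     (pitch peak for DP), skating cycles on the side_a peak at 0.25 so
#     the left half-cycle is phase [0, 0.5).
# Two-harmonic mixes realise major+minor peak pairs (weight 0.5 on k=1)
# or a near-even double peak (weight 0.1); G4's yaw gets a 0.2-weight
# second harmonic so its trough is wider than its peak.
ski_templates <- function() {
  comp <- function(p, k, rel = rep(1, length(k))) list(p = p, k = k, rel = rel)
  list(
    DP = list(
      pitch = comp(0.00, 1), fwd_a = comp(0.15, 1), up_a = comp(0.65, 1),
      side_a = comp(0.40, 1), roll = comp(0.10, 1), yaw = comp(0.20, 1)
    ),
    KDP = list(
      yaw = comp(0.00, 1), roll = comp(0.00, 1), side_a = comp(0.40, 1),
      fwd_a = comp(0.60, c(1, 2), c(0.5, 1)),   # minor (kick) at 0.10, major (poling) at 0.60
      up_a = comp(0.10, 1),                     # coincides with the minor fwd_a peak
      pitch = comp(0.45, 1)
    ),
    DS = list(
      yaw = comp(0.00, 1), roll = comp(0.00, 1), side_a = comp(0.40, 1),
      fwd_a = comp(0.00, 2),                    # two even peaks (left/right kick)
      up_a = comp(0.06, 2),                     # slightly after fwd_a
      pitch = comp(0.35, 2)
    ),
    G2 = list(
      side_a = comp(0.25, 1), pitch = comp(0.25, 1),
      yaw = comp(0.30, 1),                      # just after the pitch peak
      roll = comp(0.40, 1),                     # clear roll peak follows yaw
      fwd_a = comp(0.40, c(1, 2), c(0.1, 1)),   # near-even double peak
      up_a = comp(0.30, 1)
    ),
    G3 = list(
      side_a = comp(0.25, 1),
      fwd_a = comp(0.25, 2),
      pitch = comp(0.10, 2),                    # poling with every push: 2 peaks/cycle
      yaw = comp(0.30, 1), roll = comp(0.35, 1), up_a = comp(0.50, 1)
    ),
    G4 = list(
      side_a = comp(0.25, 1), pitch = comp(0.40, 1),
      yaw = comp(0.30, c(1, 2), c(1, 0.2)),     # peak sharper, trough wider
      roll = comp(0.45, 1),
      fwd_a = comp(0.55, c(1, 2), c(0.5, 1)),   # minor (skate) at 0.05, major at 0.55
      up_a = comp(0.05, 1)
    ),
    G5 = list(
      side_a = comp(0.25, 1),
      fwd_a = comp(0.25, 2),
      up_a = comp(0.30, 2),
      pitch = comp(0.25, 2),                    # rhythmic but low: no poling
      roll = comp(0.45, 1), yaw = comp(0.30, 1)
    )
  )
}

# Default peak amplitudes on the filtered/analysis scale: gyro channels in
# d/s, accel channels in g. Pitch encodes the poling thresholds (DP/KDP
# well above 75, DS below 50, G2 above 50, G3/G4 above 75, G5 below 40);
# roll/yaw encode the kick channels (below 20 for DP, 40 for DS/KDP kicks,
# above 50 for the G2/G5 roll).
ski_default_amps <- function() {
  list(
    DP  = c(fwd_a = 0.30, side_a = 0.02, up_a = 0.15, roll = 10, pitch = 100, yaw = 10),
    KDP = c(fwd_a = 0.30, side_a = 0.02, up_a = 0.20, roll = 40, pitch = 100, yaw = 40),
    DS  = c(fwd_a = 0.30, side_a = 0.02, up_a = 0.20, roll = 40, pitch = 40,  yaw = 40),
    G2  = c(fwd_a = 0.35, side_a = 0.40, up_a = 0.20, roll = 60, pitch = 60,  yaw = 40),
    G3  = c(fwd_a = 0.30, side_a = 0.40, up_a = 0.20, roll = 30, pitch = 90,  yaw = 40),
    G4  = c(fwd_a = 0.30, side_a = 0.40, up_a = 0.20, roll = 30, pitch = 90,  yaw = 40),
    G5  = c(fwd_a = 0.30, side_a = 0.40, up_a = 0.10, roll = 60, pitch = 25,  yaw = 40)
  )
}

#' Default generator parameters for a technique
#'
#' Returns a full `gen_params` parameter set whose generated-and-filtered
#' signal exhibits every quantitative signature of the technique: peak
#' magnitudes, peaks-per-cycle multiplicities and inter-channel timing.
#' Amplitudes are specified on the analysis (filtered) scale; see
#' [generate_imu()] for how the generator pre-equalises for the default
#' filter response.
#'
#' Fields may be overridden via `...` (e.g. `cycle_rate_hz`, `seed`,
#' `trunk_lean_deg`, `asymmetry_ratio`, `noise_sd_accel`).
#'
#' @param technique One of [technique_labels()].
#' @param ... Named overrides of any parameter field.
#' @return An object of class `gen_params` with fields: `technique`,
#'   `family`, `duration_s` (default 20), `cycle_rate_hz` (default 0.8
#'   classical / 0.7 skating), `amp` (named per-channel peak amplitudes,
#'   g or d/s), `phase` (named per-channel peak positions as cycle
#'   fractions), `noise_sd_accel` (g, default 0.05), `noise_sd_gyro`
#'   (d/s, default 5), `hf_noise_accel` (g, default 0.1), `hf_noise_gyro`
#'   (d/s, default 10) for the 8 Hz contaminating harmonic,
#'   `trunk_lean_deg` (default 15), `asymmetry_ratio` (left-side scale,
#'   default 1), `lead_side` (`"R"` or `"L"`, G2 only), `tap_marker`
#'   (default `TRUE`), `seed` (default 1).
#' @export
default_params <- function(technique, ...) {
  technique <- match.arg(technique, technique_labels())
  fam <- technique_family(technique)
  tmpl <- ski_templates()[[technique]]
  p <- list(
    technique = technique,
    family = fam,
    duration_s = 20,
    cycle_rate_hz = if (fam == "classical") 0.8 else 0.7,
    amp = ski_default_amps()[[technique]],
    phase = vapply(tmpl, function(cc) cc$p, numeric(1))[ski_channels()],
    noise_sd_accel = 0.05,
    noise_sd_gyro = 5,
    hf_noise_accel = 0.1,
    hf_noise_gyro = 10,
    trunk_lean_deg = 15,
    asymmetry_ratio = 1.0,
    lead_side = "R",
    tap_marker = TRUE,
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown))
    stop("unknown gen_params field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (nm in names(over)) {
    if (nm %in% c("amp", "phase")) {
      v <- over[[nm]]
      p[[nm]][names(v)] <- v
    } else p[[nm]] <- over[[nm]]
  }
  validate_gen_params(structure(p, class = "gen_params"))
}

validate_gen_params <- function(p) {
  stopifnot(inherits(p, "gen_params"))
  if (any(p$amp < 0)) stop("amplitudes must be non-negative", call. = FALSE)
  if (any(p$phase < 0 | p$phase >= 1))
    stop("phase offsets must lie in [0, 1)", call. = FALSE)
  if (p$duration_s <= 0) stop("duration_s must be positive", call. = FALSE)
  if (p$cycle_rate_hz <= 0) stop("cycle_rate_hz must be positive", call. = FALSE)
  if (!p$lead_side %in% c("L", "R"))
    stop("lead_side must be 'L' or 'R'", call. = FALSE)
  gravity_components(p$trunk_lean_deg)  # range check
  if (p$asymmetry_ratio <= 0) stop("asymmetry_ratio must be positive", call. = FALSE)
  p
}

#' @export
print.gen_params <- function(x, ...) {
  cat(sprintf("<gen_params> %s (%s), %.0f s @ %.2f cycles/s, lean %.0f deg, seed %s\n",
              x$technique, x$family, x$duration_s, x$cycle_rate_hz,
              x$trunk_lean_deg, format(x$seed)))
  cat("  amp:", paste(sprintf("%s=%g", names(x$amp), x$amp), collapse = " "), "\n")
  invisible(x)
}

# Inverse of the default zero-phase filter response at frequency f, used
# to pre-equalise each harmonic so the *filtered* signal carries the
# parameterised amplitude. The default 1 Hz gyro filter passes only ~6%
# of a 1.4 Hz component, so raw 2nd-harmonic gyro amplitudes can be far
# larger than the filtered ones (as with real unfiltered gyro data).
equalise_gain <- function(f, channel_class, sample_rate_hz) {
  spec <- if (channel_class == "accel") filter_spec(2.0) else filter_spec(1.0)
  m <- butter_response(spec, f, sample_rate_hz)^2  # zero-phase = squared
  1 / m
}

# Raw oscillatory waveform for one channel over cycle phase v (vector).
# The *target* (filtered-domain) waveform -- harmonic template times the
# optional left-side asymmetry envelope -- is expanded into its Fourier
# lines over one cycle, and each line is pre-equalised by the inverse
# default filter response so that default filtering returns the target.
# Lines the filter would have to boost more than `max_gain` are dropped
# unless they belong to the core template (their target contribution is
# negligible, and dropping them keeps raw amplitudes bounded).
channel_wave <- function(v, comp, amp, channel_class, f0, sample_rate_hz,
                         env_fun = NULL, max_harmonic = 8L, max_gain = 300) {
  norm <- sum(comp$rel)
  N <- 2048L
  vg <- (0:(N - 1L)) / N
  templ <- numeric(N)
  for (j in seq_along(comp$k))
    templ <- templ + (comp$rel[j] / norm) * cos(2 * pi * comp$k[j] * (vg - comp$p))
  y <- amp * templ
  if (!is.null(env_fun)) y <- y * env_fun(vg)
  cf <- stats::fft(y) / N
  out <- rep(Re(cf[1]), length(v))  # DC passes with gain 1
  for (k in seq_len(max_harmonic)) {
    if (Mod(cf[k + 1L]) < 1e-12 * max(amp, 1e-12)) next
    g <- equalise_gain(k * f0, channel_class, sample_rate_hz)
    if (g > max_gain && !(k %in% comp$k)) next
    out <- out + 2 * Re(cf[k + 1L] * g * exp(2i * pi * k * v))
  }
  out
}

#' Generate a synthetic technique recording
#'
#' Synthesises a six-channel recording at 100 Hz from low-order harmonic
#' templates of the cycle frequency. Each channel's peak amplitude,
#' peaks-per-cycle multiplicity and peak timing follow the technique's
#' signature; amplitudes are specified on the analysis (filtered) scale
#' and each harmonic is pre-equalised by the inverse zero-phase response
#' of the default filters ([apply_lowpass()]) so that the filtered
#' recording exhibits the parameterised peak magnitudes.
#'
#' Gravity offsets from [gravity_components()] are added to `fwd_a` and
#' `up_a`; per-channel white noise and an 8 Hz contaminating harmonic
#' (removed by the default filters) are superimposed. Left/right
#' structure arises from the half-cycle alternation of `side_a` (skating)
#' or the sign alternation of `roll`/`yaw` (classical kicks);
#' `asymmetry_ratio` scales the left-side half-cycle amplitudes of
#' `fwd_a`, `up_a` and `roll` via a smooth half-cycle envelope. For G2,
#' `lead_side = "L"` inverts the `yaw` and `roll` curves (the signature
#' of an athlete leading on the left). If `tap_marker` is `TRUE` the
#' recording is prefixed by three 5 g, 50 ms half-sine tap spikes at
#' 0.5 s spacing followed by 2 s of quiet standing.
#'
#' Output is bit-reproducible for a fixed `seed`; the RNG stream order is
#' fixed (white noise channel by channel in container order, then the six
#' 8 Hz contaminant phases).
#'
#' @param params A `gen_params` object from [default_params()].
#' @param sample_rate_hz Sampling rate (default 100).
#' @return A [signal_series()]; `meta$truth` carries the ground truth
#'   (technique, cycle rate, movement start sample, anchor-event samples,
#'   left half-cycle phase window).
#' @export
generate_imu <- function(params, sample_rate_hz = 100) {
  params <- validate_gen_params(params)
  fs <- sample_rate_hz
  f0 <- params$cycle_rate_hz
  if (params$duration_s < 1 / f0)
    stop("duration_s too short for one full cycle", call. = FALSE)

  # isolate the generator's RNG stream from the caller's
  if (exists(".Random.seed", envir = globalenv()))
    old_seed <- get(".Random.seed", envir = globalenv())
  else old_seed <- NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(params$seed)

  n_mov <- round(params$duration_s * fs)
  t_mov <- (seq_len(n_mov) - 1) / fs
  v <- f0 * t_mov  # cycle phase
  tmpl <- ski_templates()[[params$technique]]

  has_sides <- params$technique != "DP"
  # smooth left-half amplitude envelope centred on the left anchor event
  l_centre <- if (params$family == "classical") 0 else 0.25
  r_asym <- params$asymmetry_ratio
  env_fun <- function(vv) 1 + (r_asym - 1) * pmax(cos(2 * pi * (vv - l_centre)), 0)
  ramp <- pmin(1, t_mov / 1.0)  # 1 s onset ramp

  mov <- list()
  for (ch in ski_channels()) {
    cls <- if (ch %in% accel_channels()) "accel" else "gyro"
    comp <- tmpl[[ch]]
    comp$p <- params$phase[[ch]]
    use_env <- has_sides && ch %in% c("fwd_a", "up_a", "roll") && r_asym != 1
    w <- channel_wave(v, comp, params$amp[[ch]], cls, f0, fs,
                      env_fun = if (use_env) env_fun else NULL)
    if (params$technique == "G2" && params$lead_side == "L" &&
        ch %in% c("roll", "yaw"))
      w <- -w
    mov[[ch]] <- w * ramp
  }

  # optional marker prefix: taps at 0.1/0.6/1.1 s then 2 s quiet standing
  n_pre <- if (params$tap_marker) round(3.2 * fs) else 0L
  chans <- lapply(ski_channels(), function(ch) c(numeric(n_pre), mov[[ch]]))
  names(chans) <- ski_channels()
  n_tot <- n_pre + n_mov
  if (params$tap_marker) {
    spike_len <- max(1L, round(0.05 * fs))
    half_sine <- 5 * sin(pi * (seq_len(spike_len) - 0.5) / spike_len)
    for (s0 in c(0.1, 0.6, 1.1)) {
      i0 <- round(s0 * fs) + 1L
      chans$fwd_a[i0:(i0 + spike_len - 1L)] <-
        chans$fwd_a[i0:(i0 + spike_len - 1L)] + half_sine
    }
  }

  grav <- gravity_components(params$trunk_lean_deg)
  chans$fwd_a <- chans$fwd_a + grav[["fwd_g"]]
  chans$up_a <- chans$up_a + grav[["up_g"]]

  tt <- (seq_len(n_tot) - 1) / fs
  for (ch in ski_channels()) {
    cls_accel <- ch %in% accel_channels()
    sd <- if (cls_accel) params$noise_sd_accel else params$noise_sd_gyro
    if (sd > 0) chans[[ch]] <- chans[[ch]] + stats::rnorm(n_tot, 0, sd)
  }
  for (ch in ski_channels()) {
    amp_hf <- if (ch %in% accel_channels()) params$hf_noise_accel else params$hf_noise_gyro
    if (amp_hf > 0)
      chans[[ch]] <- chans[[ch]] + amp_hf * sin(2 * pi * 8 * tt + stats::runif(1, 0, 2 * pi))
  }

  anchor_ch <- switch(params$family,
                      classical = if (params$technique == "DP") "pitch" else "yaw",
                      skating = "side_a")
  anchor_p <- params$phase[[anchor_ch]]
  # anchor-event (cycle start) times within the movement segment
  ev <- anchor_p / f0 + (0:floor((params$duration_s - anchor_p / f0) * f0)) / f0
  ev <- ev[ev < params$duration_s]

  signal_series(
    fwd_a = chans$fwd_a, side_a = chans$side_a, up_a = chans$up_a,
    roll = chans$roll, pitch = chans$pitch, yaw = chans$yaw,
    sample_rate_hz = fs,
    meta = list(
      technique = params$technique,
      generator = "skitech harmonic template",
      seed = params$seed,
      truth = list(
        technique = params$technique,
        family = params$family,
        cycle_rate_hz = f0,
        movement_start = n_pre + 1L,
        anchor_channel = anchor_ch,
        anchor_samples = n_pre + round(ev * fs) + 1L,
        n_cycles = max(0L, length(ev) - 1L),
        left_half_centre = l_centre,
        asymmetry_ratio = params$asymmetry_ratio,
        lead_side = params$lead_side
      )
    )
  )
}

#' Generate a labelled fixture set across all techniques
#'
#' Produces `n_per_technique` recordings per technique with realistic
#' variation: cycle rate jittered by +/-20%, trunk lean drawn from
#' 0-30 degrees, noise scaled by 0.5-2x, per-channel amplitudes scaled by
#' 0.8-1.2x, and random lead side for G2. Deterministic in `seed`.
#'
#' @param seed Integer seed controlling the whole set.
#' @param n_per_technique Number of recordings per technique (>= 1).
#' @param duration_s Duration of each recording (default 20 s).
#' @return A list of elements `list(series=, label=, params=)`.
#' @export
make_fixture_set <- function(seed, n_per_technique, duration_s = 20) {
  stopifnot(n_per_technique >= 1)
  if (exists(".Random.seed", envir = globalenv()))
    old_seed <- get(".Random.seed", envir = globalenv())
  else old_seed <- NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  out <- list()
  for (tech in technique_labels()) {
    for (i in seq_len(n_per_technique)) {
      base <- default_params(tech)
      amp_jit <- stats::runif(6, 0.8, 1.2)
      names(amp_jit) <- ski_channels()
      p <- default_params(
        tech,
        duration_s = duration_s,
        cycle_rate_hz = base$cycle_rate_hz * stats::runif(1, 0.8, 1.2),
        trunk_lean_deg = stats::runif(1, 0, 30),
        noise_sd_accel = base$noise_sd_accel * stats::runif(1, 0.5, 2),
        noise_sd_gyro = base$noise_sd_gyro * stats::runif(1, 0.5, 2),
        amp = base$amp * amp_jit[names(base$amp)],
        lead_side = if (tech == "G2") sample(c("L", "R"), 1) else "R",
        seed = sample.int(.Machine$integer.max, 1)
      )
      out[[length(out) + 1L]] <- list(series = generate_imu(p),
                                      label = tech, params = p)
    }
  }
  out
}
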