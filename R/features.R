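# Per-cycle signature features.
#
# All medians are taken across cycles: individual athletes show visible
# cycle-to-cycle irregularity, and medians keep a single odd cycle from
# flipping a feature.

# circular median of lags expressed as cycle fractions in (-0.5, 0.5]:
# the sample minimising the summed circular distance (ties -> smaller lag)
circ_median <- function(lags) {
  lags <- ((lags + 0.5) %% 1) - 0.5
  if (length(lags) == 1L) return(lags)
  cost <- vapply(lags, function(m) {
    d <- abs(lags - m)
    sum(pmin(d, 1 - d))
  }, numeric(1))
  best <- lags[cost == min(cost)]
  sort(best)[1]
}

wrap_half <- function(x) {
  w <- ((x + 0.5) %% 1) - 0.5
  ifelse(w == -0.5, 0.5, w)
}

# signed circular distance from each `from` event to its nearest `to`
# event, in cycle fractions
nearest_lag <- function(from_idx, to_idx, period_samples) {
  vapply(from_idx, function(i) {
    d <- wrap_half((to_idx - i) / period_samples)
    d[which.min(abs(d))]
  }, numeric(1))
}

# median over cycles of the per-cycle max of |x|
per_cycle_peak <- function(x, boundaries) {
  nb <- length(boundaries)
  stats::median(vapply(seq_len(nb - 1L), function(i) {
    max(abs(x[boundaries[i]:(boundaries[i + 1L] - 1L)]))
  }, numeric(1)))
}

# width of an extremum at half prominence, in samples (linear
# interpolation at the crossings)
half_prom_width <- function(x, idx, prom, polarity = "peak") {
  xx <- if (polarity == "trough") -x else x
  level <- xx[idx] - prom / 2
  n <- length(xx)
  l <- idx
  while (l > 1L && xx[l - 1L] > level) l <- l - 1L
  left <- if (l == 1L) 1 else l - 1 + (level - xx[l - 1L]) / (xx[l] - xx[l - 1L])
  r <- idx
  while (r < n && xx[r + 1L] > level) r <- r + 1L
  right <- if (r == n) n else r + (xx[r] - level) / (xx[r] - xx[r + 1L])
  right - left
}

#' Extract the per-recording signature feature vector
#'
#' Computes, from a filtered recording and its cycle segmentation, the
#' quantities that discriminate the seven techniques:
#'
#' * `pitch_peak_dps`, `roll_peak_dps`, `yaw_peak_dps`: median per-cycle
#'   peak magnitude of the angular-rate channels (d/s); the pitch peak
#'   level separates poling from non-poling techniques.
#' * `sidea_peak_g`, `sidea_cv`, `sidea_regular`: skating shows a
#'   regular alternating `side_a` peak/trough cycle;`sidea_regular` is
#'   true when alternating extrema exist, their amplitude coefficient of
#'   variation is below `cv_max` and the median extremum magnitude
#'   reaches `sidea_min_g`.
#' * `fwd_peaks_per_cycle`, `fwd_major_minor`: `fwd_a` peak multiplicity
#'   per cycle, counting peaks with prominence at least 25% of the
#'   cycle's largest; a "minor" peak has 25-75% of the major prominence,
#'   and `fwd_major_minor` is true when cycles typically show one of
#'   each (distinct major and minor peaks).
#' * `pitch_yaw_ratio`: poling-level pitch peaks per yaw peak (2
#'   for double-time skating, 1 for offset/single-time, 0 when there is
#'   no poling).
#' * `yaw_pitch_lag`: circular median lag from the pitch peak to the
#'   *nearest* yaw extremum, in cycle fractions in (-0.5, 0.5];
#'   negative means yaw precedes pitch (single-time skating), positive
#'   means yaw follows (offset skating). Using the nearest extremum
#'   (peak or trough) makes the sign invariant to the yaw/roll inversion
#'   of athletes leading on the left.
#' * `yaw_trough_width_ratio`: yaw trough width over yaw peak width at
#'   half prominence (above 1 when pole return is faster than the poling
#'   push, a single-time skating trait).
#' * `pitch_precedes_fwd`: whether the poling pitch peak precedes the
#'   nearest `fwd_a` peak (true for every poling technique).
#'
#' @param series A filtered [signal_series()].
#' @param seg A [segment_cycles()] result with at least 2 cycles.
#' @param sidea_min_g,cv_max Thresholds behind `sidea_regular`
#'   (defaults 0.1 g and 0.5).
#' @param poling_level_dps Minimum pitch peak level counted as a poling
#'   peak, in d/s (default 45).
#' @param timing_prom_dps Prominence for timing-related pitch/yaw peaks
#'   (default 20).
#' @return An object of class `ski_features` (named list of the fields
#'   above plus `n_cycles` and `cycle_rate_hz`).
#' @export
extract_features <- function(series, seg, sidea_min_g = 0.1, cv_max = 0.5,
                             poling_level_dps = 45, timing_prom_dps = 20) {
  validate_signal_series(series)
  stopifnot(inherits(seg, "cycle_segmentation"))
  if (seg$n_cycles < 2L) stop("need at least 2 cycles", call. = FALSE)
  fs <- series$sample_rate_hz
  b <- seg$boundaries
  span <- range(b)
  period <- (span[2] - span[1]) / seg$n_cycles

  fv <- list(
    pitch_peak_dps = per_cycle_peak(series$pitch, b),
    roll_peak_dps = per_cycle_peak(series$roll, b),
    yaw_peak_dps = per_cycle_peak(series$yaw, b)
  )

  # side_a regularity
  sp <- detect_peaks(series$side_a, 0.05, 0.3, fs)
  st <- detect_peaks(series$side_a, 0.05, 0.3, fs, polarity = "trough")
  ext_idx <- c(sp$indices, st$indices)
  ext_pol <- c(rep(1L, length(sp$indices)), rep(-1L, length(st$indices)))
  o <- order(ext_idx)
  ext_idx <- ext_idx[o]; ext_pol <- ext_pol[o]
  in_span <- ext_idx >= span[1] & ext_idx < span[2]
  ext_idx <- ext_idx[in_span]; ext_pol <- ext_pol[in_span]
  amps <- abs(c(sp$values, st$values)[o][in_span])
  alternating <- length(ext_idx) >= 4L && all(diff(ext_pol) != 0L)
  fv$sidea_peak_g <- if (length(amps)) stats::median(amps) else 0
  fv$sidea_cv <- if (length(amps) >= 2L && mean(amps) > 0)
    stats::sd(amps) / mean(amps) else Inf
  fv$sidea_regular <- alternating && fv$sidea_cv < cv_max &&
    fv$sidea_peak_g >= sidea_min_g

  # fwd_a peak multiplicity (on the mean-removed channel; prominence is
  # offset-invariant but the floor is set relative to the strongest peak)
  fwd <- series$fwd_a - mean(series$fwd_a)
  all_fwd <- detect_peaks(fwd, .Machine$double.eps, 0.15, fs)
  if (length(all_fwd$indices)) {
    floor_prom <- 0.25 * max(all_fwd$prominences)
    keep <- all_fwd$prominences >= floor_prom
    fwd_idx <- all_fwd$indices[keep]
    fwd_prom <- all_fwd$prominences[keep]
  } else {
    fwd_idx <- integer(0); fwd_prom <- numeric(0)
  }
  counts <- majors <- minors <- integer(seg$n_cycles)
  for (i in seq_len(seg$n_cycles)) {
    in_cyc <- fwd_idx >= b[i] & fwd_idx < b[i + 1L]
    pr <- fwd_prom[in_cyc]
    if (!length(pr)) next
    top <- max(pr)
    counts[i] <- sum(pr >= 0.25 * top)
    majors[i] <- sum(pr >= 0.75 * top)
    minors[i] <- sum(pr >= 0.25 * top & pr < 0.75 * top)
  }
  fv$fwd_peaks_per_cycle <- stats::median(counts)
  fv$fwd_major_peaks_per_cycle <- stats::median(majors)
  fv$fwd_major_minor <- stats::median(majors) >= 1 && stats::median(minors) >= 1

  # poling pitch peaks (by peak level, matching the tables' d/s bounds)
  # vs yaw peaks
  pp <- detect_peaks(series$pitch, timing_prom_dps, 0.2, fs)
  yp <- detect_peaks(series$yaw, timing_prom_dps, 0.3, fs)
  n_pp <- sum(pp$indices >= span[1] & pp$indices < span[2] &
                pp$values >= poling_level_dps)
  n_yp <- sum(yp$indices >= span[1] & yp$indices < span[2])
  fv$pitch_yaw_ratio <- if (n_yp > 0) n_pp / n_yp else 0

  # timing features use the lower (timing) prominence so that weak-poling
  # techniques still yield pitch events
  pt <- detect_peaks(series$pitch, timing_prom_dps, 0.2, fs)
  pt_idx <- pt$indices[pt$indices >= span[1] & pt$indices < span[2]]
  yt <- detect_peaks(series$yaw, timing_prom_dps, 0.3, fs)
  ytr <- detect_peaks(series$yaw, timing_prom_dps, 0.3, fs, polarity = "trough")
  yaw_ext <- sort(c(yt$indices, ytr$indices))
  yaw_ext <- yaw_ext[yaw_ext >= span[1] & yaw_ext < span[2]]
  fv$yaw_pitch_lag <- if (length(pt_idx) && length(yaw_ext))
    circ_median(nearest_lag(pt_idx, yaw_ext, period)) else NA_real_

  # yaw trough/peak width ratio at half prominence
  fv$yaw_trough_width_ratio <- {
    wp <- if (length(yt$indices))
      stats::median(vapply(seq_along(yt$indices), function(i)
        half_prom_width(series$yaw, yt$indices[i], yt$prominences[i]),
        numeric(1))) else NA_real_
    wt <- if (length(ytr$indices))
      stats::median(vapply(seq_along(ytr$indices), function(i)
        half_prom_width(series$yaw, ytr$indices[i], ytr$prominences[i],
                        polarity = "trough"), numeric(1))) else NA_real_
    if (is.na(wp) || is.na(wt) || wp == 0) NA_real_ else wt / wp
  }

  fv$pitch_precedes_fwd <- if (length(pt_idx) && length(fwd_idx))
    circ_median(nearest_lag(pt_idx, fwd_idx, period)) > 0 else NA

  fv$n_cycles <- seg$n_cycles
  fv$cycle_rate_hz <- cycle_rate(seg)
  structure(fv, class = "ski_features")
}

#' @export
print.ski_features <- function(x, ...) {
  cat("<ski_features>\n")
  cat(sprintf("  pitch %.1f  roll %.1f  yaw %.1f d/s; side_a %.3f g (regular: %s)\n",
              x$pitch_peak_dps, x$roll_peak_dps, x$yaw_peak_dps,
              x$sidea_peak_g, x$sidea_regular))
  cat(sprintf("  fwd peaks/cycle %.1f (major+minor: %s); pitch:yaw %.2f; yaw-pitch lag %s\n",
              x$fwd_peaks_per_cycle, x$fwd_major_minor, x$pitch_yaw_ratio,
              if (is.na(x$yaw_pitch_lag)) "NA" else sprintf("%+.3f", x$yaw_pitch_lag)))
  invisible(x)
}

#' Yaw-pitch timing of the poling action
#'
#' Circular median over cycles of the lag from each poling pitch peak to
#' the nearest yaw extremum, in cycle fractions mapped to (-0.5, 0.5].
#' Negative values mean the yaw event precedes the pitch peak (the
#' single-time skating signature); positive values mean it follows (the
#' offset skating signature).
#'
#' @inheritParams extract_features
#' @return Lag in cycle fractions.
#' @export
yaw_pitch_timing <- function(series, seg, timing_prom_dps = 20) {
  fv <- extract_features(series, seg, timing_prom_dps = timing_prom_dps)
  if (is.na(fv$yaw_pitch_lag))
    stop("missing pitch or yaw peaks for timing", call. = FALSE)
  fv$yaw_pitch_lag
}

#' Does the poling pitch peak precede the forward-acceleration peak?
#'
#' True when the circular median lag from each pitch peak to the nearest
#' `fwd_a` peak is positive, i.e. the poling action peaks before the
#' forward push it produces — the ordering common to every poling
#' technique.
#'
#' @inheritParams extract_features
#' @return Logical.
#' @export
pitch_fwd_order <- function(series, seg) {
  fv <- extract_features(series, seg)
  if (is.na(fv$pitch_precedes_fwd))
    stop("missing pitch or fwd_a peaks for ordering", call. = FALSE)
  fv$pitch_precedes_fwd
}
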