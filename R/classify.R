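#' Rule thresholds for technique classification
#'
#' The numeric bounds of the signature tables: a pitch peak above 75 d/s
#' identifies poling (50 d/s for offset skating, which poles only every
#' second push); diagonal stride's pitch stays below 50 d/s; free skate's
#' below 40 d/s; kick roll/yaw reaches 20 d/s (double pole stays below);
#' the offset-skate roll peak exceeds 50 d/s. `ratio_tol` and
#' `lag_zero_band` are package conventions for "ratio of 2" and "lag of
#' either sign" since the source tables are qualitative there.
#'
#' @param poling_pitch_dps,g2_poling_pitch_dps,ds_pitch_max_dps,g5_pitch_max_dps,kick_roll_min_dps,g2_roll_min_dps,ratio_tol,lag_zero_band
#'   Override any threshold.
#' @return An object of class `rule_thresholds`.
#' @export
rule_thresholds <- function(poling_pitch_dps = 75,
                            g2_poling_pitch_dps = 50,
                            ds_pitch_max_dps = 50,
                            g5_pitch_max_dps = 40,
                            kick_roll_min_dps = 20,
                            g2_roll_min_dps = 50,
                            ratio_tol = 0.35,
                            lag_zero_band = 0.02) {
  th <- list(poling_pitch_dps = poling_pitch_dps,
             g2_poling_pitch_dps = g2_poling_pitch_dps,
             ds_pitch_max_dps = ds_pitch_max_dps,
             g5_pitch_max_dps = g5_pitch_max_dps,
             kick_roll_min_dps = kick_roll_min_dps,
             g2_roll_min_dps = g2_roll_min_dps,
             ratio_tol = ratio_tol,
             lag_zero_band = lag_zero_band)
  if (any(unlist(th) <= 0)) stop("thresholds must be positive", call. = FALSE)
  structure(th, class = "rule_thresholds")
}

rule_ops <- list(
  ge = `>=`, gt = `>`, le = `<=`, lt = `<`,
  eq = function(a, b) isTRUE(all.equal(a, b)),
  abs_le = function(a, b) abs(a) <= b,
  is_true = function(a, b) isTRUE(a), is_false = function(a, b) isFALSE(a)
)

#' Classify a feature vector into a technique
#'
#' Applies the decision tree distilled from the signature tables:
#'
#' 1. Family: a regular alternating `side_a` cycle means skating,
#'    otherwise classical.
#' 2. Classical: low pitch (< 50 d/s) with a kick roll signature is
#'    diagonal stride; poling-level pitch (>= 75 d/s) with a kick is
#'    kick double pole, without is double pole.
#' 3. Skating: pitch below 40 d/s means no poling, free skate; a
#'    pitch-to-yaw peak ratio near 2 means double time; otherwise the
#'    yaw-pitch lag sign separates single time (yaw precedes pitch) from
#'    offset (yaw follows pitch), with the forward-acceleration
#'    major/minor pattern as tie-break inside the zero band (a distinct
#'    major+minor pair is the single-time trait; offset shows a double
#'    peak).
#'
#' The offset gear is reached without ever testing the 75 d/s poling
#' bound, so its lower poling level (50-75 d/s) is never rejected.
#' Feature combinations matching no technique yield `label = NA` with the
#' evidence collected so far, never an error.
#'
#' @param fv A [extract_features()] result.
#' @param th A [rule_thresholds()] set.
#' @return An object of class `ski_classification`: `label` (or `NA`),
#'   `evidence` (data frame: rule, value, threshold, op, passed),
#'   `confidence` (fraction of consulted rules passed).
#' @export
classify_features <- function(fv, th = rule_thresholds()) {
  stopifnot(inherits(fv, "ski_features"))
  stopifnot(inherits(th, "rule_thresholds"))
  ev <- data.frame(rule = character(0), value = numeric(0),
                   threshold = numeric(0), op = character(0),
                   passed = logical(0), stringsAsFactors = FALSE)
  note <- function(rule, value, threshold, op) {
    passed <- rule_ops[[op]](value, threshold)
    ev <<- rbind(ev, data.frame(rule = rule, value = as.numeric(value),
                                threshold = as.numeric(threshold), op = op,
                                passed = passed, stringsAsFactors = FALSE))
    passed
  }

  label <- NA_character_
  if (!isTRUE(fv$sidea_regular)) {
    # classical branch: evidence rows are oriented to the branch taken,
    # so `passed` means "supports the decision path"
    note("family_classical", as.numeric(fv$sidea_regular), 0, "eq")
    ds_pitch <- fv$pitch_peak_dps < th$ds_pitch_max_dps
    kick <- fv$roll_peak_dps >= th$kick_roll_min_dps
    if (ds_pitch && kick) {
      note("pitch_below_ds_max", fv$pitch_peak_dps, th$ds_pitch_max_dps, "lt")
      note("kick_roll_present", fv$roll_peak_dps, th$kick_roll_min_dps, "ge")
      label <- "DS"
    } else if (fv$pitch_peak_dps >= th$poling_pitch_dps) {
      note("poling_pitch", fv$pitch_peak_dps, th$poling_pitch_dps, "ge")
      if (kick) {
        note("kick_roll_present", fv$roll_peak_dps, th$kick_roll_min_dps, "ge")
        label <- "KDP"
      } else {
        note("no_kick_roll", fv$roll_peak_dps, th$kick_roll_min_dps, "lt")
        label <- "DP"
      }
    } else {
      note("pitch_below_ds_max", fv$pitch_peak_dps, th$ds_pitch_max_dps, "lt")
      note("kick_roll_present", fv$roll_peak_dps, th$kick_roll_min_dps, "ge")
      note("poling_pitch", fv$pitch_peak_dps, th$poling_pitch_dps, "ge")
    }
  } else {
    note("family_skating", as.numeric(fv$sidea_regular), 1, "eq")
    if (fv$pitch_peak_dps < th$g5_pitch_max_dps) {
      note("no_poling_pitch", fv$pitch_peak_dps, th$g5_pitch_max_dps, "lt")
      label <- "G5"
    } else {
      note("poling_present", fv$pitch_peak_dps, th$g5_pitch_max_dps, "ge")
      if (abs(fv$pitch_yaw_ratio - 2) <= th$ratio_tol) {
        note("pitch_yaw_ratio_two", fv$pitch_yaw_ratio - 2, th$ratio_tol, "abs_le")
        label <- "G3"
      } else if (!is.na(fv$yaw_pitch_lag)) {
        note("pitch_yaw_ratio_one", fv$pitch_yaw_ratio - 1, th$ratio_tol, "abs_le")
        if (fv$yaw_pitch_lag < -th$lag_zero_band) {
          note("yaw_precedes_pitch", fv$yaw_pitch_lag, -th$lag_zero_band, "lt")
          label <- "G4"
        } else if (fv$yaw_pitch_lag > th$lag_zero_band) {
          note("yaw_follows_pitch", fv$yaw_pitch_lag, th$lag_zero_band, "gt")
          label <- "G2"
        } else if (isTRUE(fv$fwd_major_minor)) {
          # lag inside the zero band: the distinct major+minor fwd_a
          # pattern is the single-time trait, the double peak the offset
          note("fwd_major_minor", as.numeric(fv$fwd_major_minor), 1, "eq")
          label <- "G4"
        } else {
          note("fwd_double_peak", as.numeric(fv$fwd_major_minor), 0, "eq")
          label <- "G2"
        }
      } else {
        note("pitch_yaw_ratio_two", fv$pitch_yaw_ratio - 2, th$ratio_tol, "abs_le")
      }
    }
  }

  structure(list(
    label = label,
    evidence = ev,
    confidence = if (nrow(ev)) mean(ev$passed) else 0
  ), class = "ski_classification")
}

#' Classify a raw recording end to end
#'
#' The full pipeline: locate and trim the three-tap synchronisation
#' marker (plus the quiet-standing gap that follows it), low-pass filter,
#' drop half a second at each end to clear filter transients, attempt
#' both family segmentations, extract features from each and keep the
#' classification with the higher confidence (ties go to the
#' segmentation whose family matches the feature-implied family). If
#' neither family segments, returns a `label = NA` result carrying
#' diagnostic evidence instead of raising.
#'
#' @param series A raw [signal_series()] of at least 5 s.
#' @param accel_spec,gyro_spec Filter specs (see [apply_lowpass()]).
#' @param th A [rule_thresholds()] set.
#' @return A `ski_classification` with a `segmentation` summary field
#'   (`n_cycles`, `cycle_rate_hz`, `anchor_channel`, `family`), the
#'   feature vector in `$features`, and the segmentation object in
#'   `$seg`.
#' @examples
#' \donttest{
#' s <- generate_imu(default_params("DP", seed = 3))
#' classify_series(s)
#' }
#' @export
classify_series <- function(series,
                            accel_spec = filter_spec(2.0),
                            gyro_spec = filter_spec(1.0),
                            th = rule_thresholds()) {
  validate_signal_series(series)
  if (duration_s(series) < 5)
    stop("recording must be at least 5 s", call. = FALSE)
  fs <- series$sample_rate_hz

  mk <- find_tap_marker(series)
  work <- series
  if (!is.na(mk)) {
    ends <- attr(mk, "tap_ends")
    start <- min(n_samples(series),
                 as.integer(ends[length(ends)] + round(2.05 * fs)))
    for (ch in ski_channels()) work[[ch]] <- work[[ch]][start:n_samples(series)]
  }
  filt <- apply_lowpass(work, accel_spec, gyro_spec)
  guard <- round(0.5 * fs)
  nf <- n_samples(filt)
  if (nf > 4L * guard) {
    for (ch in ski_channels())
      filt[[ch]] <- filt[[ch]][(guard + 1L):(nf - guard)]
  }

  candidates <- list()
  for (fam in c("skating", "classical")) {
    seg <- tryCatch(segment_cycles(filt, fam), error = function(e) NULL)
    if (is.null(seg) || seg$n_cycles < 2L) next
    fv <- tryCatch(extract_features(filt, seg), error = function(e) NULL)
    if (is.null(fv)) next
    res <- classify_features(fv, th)
    res$features <- fv
    res$seg <- seg
    res$segmentation <- list(n_cycles = seg$n_cycles,
                             cycle_rate_hz = cycle_rate(seg),
                             anchor_channel = seg$anchor_channel,
                             family = fam)
    candidates[[fam]] <- res
  }

  if (!length(candidates)) {
    return(structure(list(
      label = NA_character_,
      evidence = data.frame(rule = "segmentation", value = 0, threshold = 2,
                            op = "ge", passed = FALSE, stringsAsFactors = FALSE),
      confidence = 0,
      features = NULL, seg = NULL,
      segmentation = list(n_cycles = 0L, cycle_rate_hz = NA_real_,
                          anchor_channel = NA_character_, family = NA_character_)
    ), class = "ski_classification"))
  }

  labelled <- Filter(function(r) !is.na(r$label), candidates)
  pool <- if (length(labelled)) labelled else candidates
  conf <- vapply(pool, function(r) r$confidence, numeric(1))
  best <- pool[conf == max(conf)]
  if (length(best) > 1L) {
    fam_match <- vapply(best, function(r) {
      implied <- if (isTRUE(r$features$sidea_regular)) "skating" else "classical"
      identical(r$segmentation$family, implied)
    }, logical(1))
    if (any(fam_match)) best <- best[fam_match]
  }
  best[[1]]
}

#' @export
print.ski_classification <- function(x, ...) {
  lab <- if (is.na(x$label)) "none (unclassified)" else x$label
  cat(sprintf("<ski_classification> label: %s (confidence %.2f)\n",
              lab, x$confidence))
  if (!is.null(x$segmentation) && x$segmentation$n_cycles > 0)
    cat(sprintf("  %d cycles at %.2f Hz (anchor %s, %s family)\n",
                x$segmentation$n_cycles, x$segmentation$cycle_rate_hz,
                x$segmentation$anchor_channel, x$segmentation$family))
  invisible(x)
}

#' @export
summary.ski_classification <- function(object, ...) {
  print(object)
  cat("  evidence:\n")
  ev <- object$evidence
  for (i in seq_len(nrow(ev)))
    cat(sprintf("    %-22s %8.3f %s %g  [%s]\n", ev$rule[i], ev$value[i],
                ev$op[i], ev$threshold[i], if (ev$passed[i]) "pass" else "fail"))
  invisible(object)
}
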