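#' Detect local maxima by topographic prominence
#'
#' Finds local maxima whose topographic prominence (height above the
#' higher of the two bounding minima, walking outward until a strictly
#' higher sample is met or the signal ends) is at least `min_prominence`,
#' and enforces a minimum pairwise separation by greedily keeping the
#' larger peak (earlier sample on ties). Plateaus count as a single peak
#' at their first sample. Troughs are found by negating the signal
#' (`polarity = "trough"`).
#'
#' @param x Numeric vector (one channel).
#' @param min_prominence Positive prominence threshold, in the channel's
#'   units.
#' @param min_separation_s Minimum separation between kept peaks in
#'   seconds (default 0, no constraint).
#' @param sample_rate_hz Sampling rate used to convert the separation to
#'   samples (default 100).
#' @param polarity `"peak"` (default) or `"trough"`.
#' @return An object of class `peak_list`: list with `indices` (1-based,
#'   strictly increasing), `values` (signal values at the indices),
#'   `prominences`, `polarity` and `channel` fields.
#' @export
detect_peaks <- function(x, min_prominence, min_separation_s = 0,
                         sample_rate_hz = 100, polarity = c("peak", "trough")) {
  polarity <- match.arg(polarity)
  if (length(x) == 0L) stop("empty channel", call. = FALSE)
  stopifnot(min_prominence > 0)
  xx <- if (polarity == "trough") -x else x
  n <- length(xx)

  # candidate local maxima (plateau -> first sample)
  cand <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (xx[i] > xx[i - 1L]) {
      j <- i
      while (j < n && xx[j + 1L] == xx[j]) j <- j + 1L
      if (j < n && xx[j + 1L] < xx[j]) cand <- c(cand, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(cand))
    return(structure(list(indices = integer(0), values = numeric(0),
                          prominences = numeric(0), polarity = polarity,
                          channel = NA_character_), class = "peak_list"))

  prom <- vapply(cand, function(p) {
    h <- xx[p]
    lmin <- h
    for (k in seq(p - 1L, 1L)) {
      if (xx[k] > h) break
      if (xx[k] < lmin) lmin <- xx[k]
    }
    rmin <- h
    if (p < n) for (k in seq(p + 1L, n)) {
      if (xx[k] > h) break
      if (xx[k] < rmin) rmin <- xx[k]
    }
    h - max(lmin, rmin)
  }, numeric(1))

  keep <- prom >= min_prominence
  cand <- cand[keep]; prom <- prom[keep]
  if (length(cand) && min_separation_s > 0) {
    min_gap <- min_separation_s * sample_rate_hz
    ord <- order(-xx[cand], cand)  # larger first, earlier on ties
    sel <- logical(length(cand))
    for (ii in ord) {
      if (!any(sel & abs(cand - cand[ii]) < min_gap)) sel[ii] <- TRUE
    }
    cand <- cand[sel]; prom <- prom[sel]
  }
  o <- order(cand)
  structure(list(indices = cand[o], values = x[cand[o]],
                 prominences = prom[o], polarity = polarity,
                 channel = NA_character_),
            class = "peak_list")
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("<peak_list> %d %ss\n", length(x$indices), x$polarity))
  invisible(x)
}

#' Segment a filtered recording into technique cycles
#'
#' Skating cycles are anchored on the distinct `side_a` peaks (one per
#' full left+right cycle); left and right half-cycles are the windows
#' centred on the alternating `side_a` peaks (left) and troughs (right).
#' Classical cycles are anchored on the `yaw` kick peaks when the yaw
#' peak amplitude reaches 20 d/s (diagonal stride and kick double pole);
#' for double pole, which has no kick and minimal yaw, the anchor falls
#' back to the `pitch` poling peak and no side labels are assigned.
#' Cycles are half-open peak-to-peak intervals `[b_i, b_{i+1})` in
#' 0-based convention (stored 1-based as R indices).
#'
#' @param series A *filtered* [signal_series()] (see [apply_lowpass()]).
#' @param family `"classical"` or `"skating"`.
#' @param min_prom_sidea Anchor prominence for skating `side_a` peaks in
#'   g (default 0.1).
#' @param min_prom_yaw Anchor prominence for classical `yaw` kick peaks
#'   in d/s (default 20; double pole's yaw stays below this).
#' @return An object of class `cycle_segmentation`: `boundaries` (sorted
#'   anchor-peak sample indices), `halves` (data frame with `start`,
#'   `end`, `side` in `{"L","R","none"}`), `anchor_channel`, `family`,
#'   `n_cycles`, `sample_rate_hz`.
#' @export
segment_cycles <- function(series, family = c("classical", "skating"),
                           min_prom_sidea = 0.1, min_prom_yaw = 20) {
  validate_signal_series(series)
  family <- match.arg(family)
  fs <- series$sample_rate_hz
  min_sep <- 0.5  # s; technique cycles are ~1 s or longer

  if (family == "skating") {
    anchor <- "side_a"
    pks <- detect_peaks(series$side_a, min_prom_sidea, min_sep, fs)
    trs <- detect_peaks(series$side_a, min_prom_sidea, min_sep, fs,
                        polarity = "trough")
    sided <- TRUE
  } else {
    pks <- detect_peaks(series$yaw, min_prom_yaw, min_sep, fs)
    # anchor on yaw only when the kick signature is present: the table's
    # 20 d/s bound is on the peak *level*, so test the median peak value
    if (length(pks$indices) >= 2L &&
        stats::median(pks$values) >= min_prom_yaw) {
      anchor <- "yaw"
      trs <- detect_peaks(series$yaw, min_prom_yaw, min_sep, fs,
                          polarity = "trough")
      sided <- TRUE
    } else {
      anchor <- "pitch"
      pks <- detect_peaks(series$pitch, 20, min_sep, fs)
      trs <- NULL
      sided <- FALSE
    }
  }
  if (length(pks$indices) < 2L)
    stop("no cyclical structure: fewer than 2 anchor peaks on ", anchor,
         call. = FALSE)

  boundaries <- pks$indices
  halves <- if (sided && length(trs$indices)) {
    ext <- data.frame(
      idx = c(pks$indices, trs$indices),
      side = c(rep("L", length(pks$indices)), rep("R", length(trs$indices)))
    )
    ext <- ext[order(ext$idx), ]
    # half-cycles centred on each interior extremum
    m <- nrow(ext)
    if (m >= 3L) {
      data.frame(
        start = floor((ext$idx[1:(m - 2)] + ext$idx[2:(m - 1)]) / 2),
        end = floor((ext$idx[2:(m - 1)] + ext$idx[3:m]) / 2),
        side = ext$side[2:(m - 1)],
        stringsAsFactors = FALSE
      )
    } else data.frame(start = integer(0), end = integer(0), side = character(0))
  } else {
    nb <- length(boundaries)
    data.frame(start = boundaries[-nb], end = boundaries[-1],
               side = rep("none", nb - 1L), stringsAsFactors = FALSE)
  }

  structure(list(
    boundaries = boundaries,
    halves = halves,
    anchor_channel = anchor,
    family = family,
    n_cycles = length(boundaries) - 1L,
    sample_rate_hz = fs
  ), class = "cycle_segmentation")
}

#' @export
print.cycle_segmentation <- function(x, ...) {
  cat(sprintf("<cycle_segmentation> %d cycles (%s family, anchor %s)\n",
              x$n_cycles, x$family, x$anchor_channel))
  if (nrow(x$halves) && any(x$halves$side != "none"))
    cat("  sides:", paste(x$halves$side, collapse = ""), "\n")
  invisible(x)
}

#' Cycle rate of a segmentation
#'
#' Number of cycles divided by the time between the first and last cycle
#' boundary, in Hz.
#'
#' @param seg A [segment_cycles()] result.
#' @param sample_rate_hz Sampling rate (defaults to the one stored in
#'   `seg`).
#' @return Cycle rate in Hz.
#' @export
cycle_rate <- function(seg, sample_rate_hz = seg$sample_rate_hz) {
  stopifnot(inherits(seg, "cycle_segmentation"))
  nb <- length(seg$boundaries)
  if (nb < 2L) stop("need at least 2 boundaries", call. = FALSE)
  (nb - 1L) / ((seg$boundaries[nb] - seg$boundaries[1]) / sample_rate_hz)
}

#' Poling rate and poling peaks per cycle
#'
#' Counts pitch peaks whose level reaches the poling bound (45 d/s:
#' above the free skate's low pitch, below every poling technique's
#' signature level) over the segmented span, and reports both the rate
#' per second and the ratio of poling peaks to cycles. Zero peaks give
#' rate 0, never an error.
#'
#' @param series A filtered [signal_series()].
#' @param seg A [segment_cycles()] result.
#' @param min_peak_dps Minimum pitch peak level counted as poling, in
#'   d/s (default 45).
#' @return List with `rate_hz` and `peaks_per_cycle`.
#' @export
poling_rate <- function(series, seg, min_peak_dps = 45) {
  validate_signal_series(series)
  stopifnot(inherits(seg, "cycle_segmentation"))
  fs <- series$sample_rate_hz
  span <- range(seg$boundaries)
  pk <- detect_peaks(series$pitch, 20, 0.2, fs)
  in_span <- pk$indices >= span[1] & pk$indices < span[2] &
    pk$values >= min_peak_dps
  n_pk <- sum(in_span)
  dur <- (span[2] - span[1]) / fs
  list(rate_hz = n_pk / dur, peaks_per_cycle = n_pk / seg$n_cycles)
}
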