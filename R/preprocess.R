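#' Low-pass Butterworth filter specification
#'
#' Signal conditioning uses low-pass Butterworth filters: 2.0 Hz for the
#' acceleration channels and 1.0 Hz for the angular-rate channels by
#' default, applied forward-backward (zero phase) so that filtered peaks
#' stay aligned with the underlying movement events.
#'
#' @param cutoff_hz Positive cutoff (half-power) frequency in Hz.
#' @param order Filter order (default 4, a common biomechanics choice).
#' @param zero_phase Apply forward-backward (default `TRUE`). The
#'   effective magnitude response is then the square of the single-pass
#'   response and the net group delay is zero.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(cutoff_hz, order = 4, zero_phase = TRUE) {
  stopifnot(is.numeric(cutoff_hz), length(cutoff_hz) == 1L, cutoff_hz > 0,
            is.numeric(order), length(order) == 1L, order >= 1)
  structure(list(cutoff_hz = cutoff_hz, order = as.integer(order),
                 kind = "lowpass-butterworth",
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("<filter_spec> %s, cutoff %g Hz, order %d%s\n",
              x$kind, x$cutoff_hz, x$order,
              if (x$zero_phase) ", zero-phase" else ""))
  invisible(x)
}

butter_coefs <- function(spec, sample_rate_hz) {
  nyq <- sample_rate_hz / 2
  if (spec$cutoff_hz >= nyq)
    stop("cutoff must be below the Nyquist frequency", call. = FALSE)
  signal::butter(spec$order, spec$cutoff_hz / nyq, type = "low")
}

# Zero-phase (or single-pass) filtering with odd-reflection edge padding.
# Padding length scales with the filter's time constant (3 * fs / cutoff
# samples) so the reflected extension covers the transient of low cutoffs.
filt1 <- function(x, spec, sample_rate_hz) {
  bf <- butter_coefs(spec, sample_rate_hz)
  n <- length(x)
  pad <- min(n - 1L, max(3L * spec$order,
                         ceiling(6 * sample_rate_hz / spec$cutoff_hz)))
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- as.numeric(signal::filter(bf, xp))
  if (spec$zero_phase) y <- rev(as.numeric(signal::filter(bf, rev(y))))
  y[(pad + 1):(pad + n)]
}

#' Apply the default low-pass conditioning to a recording
#'
#' Filters the three acceleration channels with `accel_spec` and the
#' three angular-rate channels with `gyro_spec`. With `zero_phase` specs
#' the filter runs forward and backward, giving zero net delay and the
#' squared magnitude response. DC gain is 1, so the gravity component on
#' the acceleration channels is preserved (no gravity correction is
#' attempted). Output length equals input length; the specs used are
#' recorded in `meta$filter`.
#'
#' @param series A [signal_series()].
#' @param accel_spec,gyro_spec [filter_spec()]s for the acceleration and
#'   angular-rate channels (defaults 2.0 Hz and 1.0 Hz, order 4,
#'   zero-phase).
#' @return The filtered [signal_series()].
#' @export
apply_lowpass <- function(series,
                          accel_spec = filter_spec(2.0),
                          gyro_spec = filter_spec(1.0)) {
  validate_signal_series(series)
  stopifnot(inherits(accel_spec, "filter_spec"), inherits(gyro_spec, "filter_spec"))
  ord <- max(accel_spec$order, gyro_spec$order)
  if (n_samples(series) <= 3L * ord)
    stop("series too short to filter (need > 3 * order samples)", call. = FALSE)
  out <- series
  for (ch in accel_channels())
    out[[ch]] <- filt1(series[[ch]], accel_spec, series$sample_rate_hz)
  for (ch in gyro_channels())
    out[[ch]] <- filt1(series[[ch]], gyro_spec, series$sample_rate_hz)
  out$meta$filter <- list(accel = unclass(accel_spec), gyro = unclass(gyro_spec))
  out
}

# Single-pass magnitude response of the designed filter at frequency f.
butter_response <- function(spec, f, sample_rate_hz) {
  bf <- butter_coefs(spec, sample_rate_hz)
  w <- 2 * pi * f / sample_rate_hz
  vapply(w, function(wi) {
    e <- exp(-1i * wi * (seq_along(bf$b) - 1))
    ea <- exp(-1i * wi * (seq_along(bf$a) - 1))
    Mod(sum(bf$b * e) / sum(bf$a * ea))
  }, numeric(1))
}

#' Measure the realised half-power frequency of a filter design
#'
#' Locates, by bisection on the evaluated single-pass magnitude
#' response, the frequency at which the response crosses 1/sqrt(2)
#' (-3 dB). For a correctly designed Butterworth low-pass this equals the
#' requested cutoff to well within 0.5%; the function exists to verify
#' the realised design rather than trust the request.
#'
#' @param spec A [filter_spec()].
#' @param sample_rate_hz Sampling rate the filter is designed for.
#' @return Measured half-power frequency in Hz.
#' @export
measure_cutoff <- function(spec, sample_rate_hz) {
  stopifnot(inherits(spec, "filter_spec"))
  target <- 1 / sqrt(2)
  lo <- 1e-6
  hi <- sample_rate_hz / 2 * (1 - 1e-9)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (butter_response(spec, mid, sample_rate_hz) > target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Locate the three-tap synchronisation marker
#'
#' Recording sessions are synchronised by tapping the sensor unit sharply
#' three times before movement starts. The marker is found on the raw
#' (unfiltered) acceleration magnitude: three spikes exceeding the
#' detection threshold above the 1 g gravity baseline, with consecutive
#' spacings between `min_gap_s` and `max_gap_s`.
#'
#' @param series An unfiltered [signal_series()].
#' @param threshold_g Spike threshold above the 1 g baseline (default 3).
#' @param min_gap_s,max_gap_s Allowed spacing between consecutive taps in
#'   seconds (defaults 0.2 and 1.5).
#' @return 1-based sample index of the first tap, or `NA_integer_` if no
#'   valid triple exists (a sentinel, not an error).
#' @export
find_tap_marker <- function(series, threshold_g = 3, min_gap_s = 0.2,
                            max_gap_s = 1.5) {
  validate_signal_series(series)
  mag <- sqrt(series$fwd_a^2 + series$side_a^2 + series$up_a^2)
  hot <- mag - 1 > threshold_g
  if (!any(hot)) return(NA_integer_)
  # collapse consecutive hot samples into one event at the event start
  idx <- which(hot)
  starts <- idx[c(TRUE, diff(idx) > 1L)]
  ends <- idx[c(diff(idx) > 1L, TRUE)]
  if (length(starts) < 3L) return(NA_integer_)
  fs <- series$sample_rate_hz
  for (i in seq_len(length(starts) - 2L)) {
    g1 <- (starts[i + 1] - starts[i]) / fs
    g2 <- (starts[i + 2] - starts[i + 1]) / fs
    if (g1 >= min_gap_s && g1 <= max_gap_s && g2 >= min_gap_s && g2 <= max_gap_s) {
      out <- starts[i]
      attr(out, "tap_starts") <- starts[i:(i + 2)]
      attr(out, "tap_ends") <- ends[i:(i + 2)]
      return(out)
    }
  }
  NA_integer_
}

#' Extract an analysis block from a recording
#'
#' Analysis conventionally proceeds on ten-second blocks of steady
#' technique. Returns the half-open sample window
#' `[start_s * rate, (start_s + duration_s) * rate)`.
#'
#' @param series A [signal_series()].
#' @param start_s Block start in seconds (>= 0).
#' @param duration_s Block duration in seconds (default 10).
#' @return A [signal_series()] of the requested window; `meta$block`
#'   records the offsets.
#' @export
select_block <- function(series, start_s, duration_s = 10) {
  validate_signal_series(series)
  stopifnot(start_s >= 0, duration_s > 0)
  fs <- series$sample_rate_hz
  from <- floor(start_s * fs) + 1L
  to <- floor((start_s + duration_s) * fs)
  if (to > n_samples(series))
    stop("block [", start_s, ", ", start_s + duration_s,
         ") s is out of range for a ", duration_s(series), " s series",
         call. = FALSE)
  out <- series
  for (ch in ski_channels()) out[[ch]] <- series[[ch]][from:to]
  out$meta$block <- list(start_s = start_s, duration_s = duration_s)
  out
}
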