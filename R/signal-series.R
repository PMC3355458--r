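#' Six-channel IMU signal container
#'
#' A `signal_series` holds one uniformly sampled recording from a
#' trunk-mounted inertial unit: three linear-acceleration channels in g
#' (`fwd_a` forward/backward, `side_a` left/right, `up_a` up/down) and three
#' angular-rate channels in degrees/second (`roll`, `pitch`, `yaw`).
#' Channel order and names are fixed; all six channels must have identical
#' length of at least one sample.
#'
#' The acceleration channels carry both movement-induced acceleration and
#' the gravity component due to unit orientation: with the athlete upright
#' `fwd_a` reads close to +1 g, and rotating the unit forward transfers the
#' gravity component onto `up_a`.
#'
#' @param fwd_a,side_a,up_a Numeric vectors, linear acceleration in g.
#' @param roll,pitch,yaw Numeric vectors, angular rate in degrees/second.
#' @param sample_rate_hz Positive sampling rate in Hz (default 100).
#' @param meta Named list of free-form annotations (athlete id, technique
#'   label if known, generator seed, processing history).
#' @return An object of class `signal_series`.
#' @examples
#' s <- signal_series(fwd_a = c(1, 1, 1), side_a = numeric(3),
#'                    up_a = numeric(3), roll = numeric(3),
#'                    pitch = numeric(3), yaw = numeric(3))
#' n_samples(s)
#' @export
signal_series <- function(fwd_a, side_a, up_a, roll, pitch, yaw,
                          sample_rate_hz = 100, meta = list()) {
  obj <- structure(
    list(
      fwd_a = as.numeric(fwd_a), side_a = as.numeric(side_a),
      up_a = as.numeric(up_a), roll = as.numeric(roll),
      pitch = as.numeric(pitch), yaw = as.numeric(yaw),
      sample_rate_hz = as.numeric(sample_rate_hz),
      meta = meta
    ),
    class = "signal_series"
  )
  validate_signal_series(obj)
}

#' @rdname signal_series
#' @param x A `signal_series`.
#' @export
validate_signal_series <- function(x) {
  stopifnot(inherits(x, "signal_series"))
  lens <- vapply(x[ski_channels()], length, integer(1))
  if (length(unique(lens)) != 1L || lens[[1]] < 1L)
    stop("all six channels must have identical length >= 1", call. = FALSE)
  if (!is.numeric(x$sample_rate_hz) || length(x$sample_rate_hz) != 1L ||
      !is.finite(x$sample_rate_hz) || x$sample_rate_hz <= 0)
    stop("sample_rate_hz must be a single positive number", call. = FALSE)
  x
}

# fixed channel order; accel channels are in g, gyro channels in d/s
ski_channels <- function() c("fwd_a", "side_a", "up_a", "roll", "pitch", "yaw")
accel_channels <- function() c("fwd_a", "side_a", "up_a")
gyro_channels <- function() c("roll", "pitch", "yaw")

#' @rdname signal_series
#' @export
n_samples <- function(x) {
  stopifnot(inherits(x, "signal_series"))
  length(x$fwd_a)
}

#' @rdname signal_series
#' @export
duration_s <- function(x) {
  stopifnot(inherits(x, "signal_series"))
  n_samples(x) / x$sample_rate_hz
}

#' Sample times of a signal series
#'
#' Times are implicit: sample `i` (0-based) occurs at `i / sample_rate_hz`
#' seconds.
#'
#' @param x A `signal_series`.
#' @return Numeric vector of times in seconds.
#' @export
time_points <- function(x) {
  stopifnot(inherits(x, "signal_series"))
  (seq_len(n_samples(x)) - 1) / x$sample_rate_hz
}

#' @export
as.data.frame.signal_series <- function(x, ...) {
  data.frame(
    time_s = time_points(x),
    fwd_a_g = x$fwd_a, side_a_g = x$side_a, up_a_g = x$up_a,
    roll_dps = x$roll, pitch_dps = x$pitch, yaw_dps = x$yaw
  )
}

#' @export
print.signal_series <- function(x, ...) {
  cat(sprintf("<signal_series> %d samples @ %g Hz (%.2f s)\n",
              n_samples(x), x$sample_rate_hz, duration_s(x)))
  rng <- function(v) sprintf("[%.3g, %.3g]", min(v), max(v))
  cat(sprintf("  accel (g):  fwd_a %s  side_a %s  up_a %s\n",
              rng(x$fwd_a), rng(x$side_a), rng(x$up_a)))
  cat(sprintf("  gyro (d/s): roll %s  pitch %s  yaw %s\n",
              rng(x$roll), rng(x$pitch), rng(x$yaw)))
  if (!is.null(x$meta$technique))
    cat(sprintf("  technique: %s\n", x$meta$technique))
  invisible(x)
}

#' Plot the six channels of a recording
#'
#' Draws the three acceleration channels and the three angular-rate
#' channels in a 2x3 panel layout. Gyroscope panels default to the display
#' ranges conventionally used for this kind of data: pitch on -150..150
#' d/s, roll and yaw on -75..75 d/s (pitch is typically much larger than
#' the other two rotations during skiing).
#'
#' @param x A `signal_series`.
#' @param fixed_ranges Use the conventional display ranges for the gyro
#'   panels (default `TRUE`); otherwise autoscale.
#' @param ... Passed to [graphics::plot.default()].
#' @export
plot.signal_series <- function(x, fixed_ranges = TRUE, ...) {
  t <- time_points(x)
  op <- graphics::par(mfrow = c(2, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  panels <- list(
    fwd_a = c(NA, NA), side_a = c(NA, NA), up_a = c(NA, NA),
    roll = c(-75, 75), pitch = c(-150, 150), yaw = c(-75, 75)
  )
  units <- c(fwd_a = "g", side_a = "g", up_a = "g",
             roll = "d/s", pitch = "d/s", yaw = "d/s")
  for (ch in ski_channels()) {
    ylim <- if (fixed_ranges && !anyNA(panels[[ch]])) panels[[ch]] else NULL
    graphics::plot(t, x[[ch]], type = "l", xlab = "time (s)",
                   ylab = sprintf("%s (%s)", ch, units[[ch]]),
                   main = ch, ylim = ylim, ...)
  }
  invisible(x)
}
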