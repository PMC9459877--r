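#' Construct a synchronized IMU time series
#'
#' One sensor's record: a uniform time base, accelerometer samples in g and
#' gyroscope samples in deg/s, plus where the sensor was worn.
#'
#' @param time numeric vector of sample times in seconds, strictly
#'   increasing with a constant step (to 1 part in 1e4).
#' @param accel n x 3 numeric matrix of accelerations in g.
#' @param gyro n x 3 numeric matrix of angular rates in deg/s.
#' @param placement one of `"waist"`, `"thigh"`, `"lower_shank"`.
#' @param attachment one of `"body"`, `"clothing"`.
#' @param side one of `"right"`, `"left"`.
#' @param sample_rate sampling rate in Hz; inferred from `time` if omitted.
#' @return An object of class `imu_series`.
#' @export
imu_series <- function(time, accel, gyro,
                       placement = c("waist", "thigh", "lower_shank"),
                       attachment = c("body", "clothing"),
                       side = c("right", "left"),
                       sample_rate = NULL) {
  placement <- match.arg(placement)
  attachment <- match.arg(attachment)
  side <- match.arg(side)
  accel <- as.matrix(accel); gyro <- as.matrix(gyro)
  n <- length(time)
  if (n < 2L)
    gait_stop("an imu_series needs at least 2 samples", "gaitsva_insufficient_data")
  if (nrow(accel) != n || nrow(gyro) != n || ncol(accel) != 3L || ncol(gyro) != 3L)
    gait_stop("time, accel and gyro lengths do not match (need n x 3 matrices)",
              "gaitsva_invalid_parameter")
  if (!all(is.finite(time)) || !all(is.finite(accel)) || !all(is.finite(gyro)))
    gait_stop("non-finite values in IMU data", "gaitsva_invalid_parameter")
  dts <- diff(time)
  if (any(dts <= 0))
    gait_stop("time must be strictly increasing", "gaitsva_invalid_parameter")
  dt <- stats::median(dts)
  if (max(abs(dts - dt)) > 1e-4 * dt)
    gait_stop("time step is not constant to 1 part in 1e4", "gaitsva_invalid_parameter")
  if (is.null(sample_rate)) sample_rate <- 1 / dt
  structure(list(time = as.numeric(time), accel = unname(accel), gyro = unname(gyro),
                 placement = placement, attachment = attachment, side = side,
                 sample_rate = sample_rate),
            class = "imu_series")
}

#' @export
print.imu_series <- function(x, ...) {
  cat(sprintf("<imu_series> %s/%s (%s), %d samples @ %g Hz (%.1f s)\n",
              x$placement, x$attachment, x$side, length(x$time),
              x$sample_rate, diff(range(x$time))))
  invisible(x)
}

accel_magnitude <- function(series) sqrt(rowSums(series$accel^2))

# index range of a labelled activity window on a series' time base
window_indices <- function(time, start_s, end_s) {
  which(time >= start_s & time < end_s)
}
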