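#' Estimate orientation quaternions with a gated Madgwick filter
#'
#' Fuses gyroscope integration with gradient-descent corrections toward
#' the accelerometer's gravity direction (the IMU variant of Madgwick's
#' algorithm; no magnetometer). Two implementation choices matter for
#' walking data and are documented in the package vignette:
#'
#' * The gyro increment uses the exact exponential-map (axis-angle) update
#'   with trapezoid-averaged rates, so drift-free rate data integrate
#'   without the cubic per-cycle error of the Euler quaternion step.
#' * The gradient correction (step size `beta`) is applied only during
#'   quasi-static periods -- when, over a trailing window, the
#'   acceleration magnitude stays near 1 g and the gyro stays quiet.
#'   During vigorous movement the specific force is dominated by motion,
#'   not gravity, and an ungated correction pulls the attitude toward a
#'   systematically wrong direction; gating anchors the attitude during
#'   still phases and integrates through the dynamic ones.
#'
#' @param series an aligned [imu_series] (accel in g, gyro in deg/s).
#' @param beta gradient step size in rad/s (>= 0).
#' @param q_init `"from-accel"` to initialize from the first accelerometer
#'   sample's tilt, or a length-4 unit quaternion.
#' @param gyro_bias length-3 gyro bias in deg/s subtracted before
#'   integration (typically estimated from a standing segment).
#' @param gate `NULL` to disable gating, or a list with `window` (s),
#'   `accel_tol` (g) and `gyro_tol` (deg/s).
#' @return An object of class `quaternion_series`: `time` and an n x 4
#'   matrix `q` of scalar-first unit quaternions in the estimator's own
#'   convention: sensor-frame vectors are rotated into the world frame via
#'   the conjugate sandwich `v_world = q* v q` (equivalently `q` maps world
#'   vectors into the sensor frame under the standard sandwich). The series
#'   is sign-continuous.
#' @export
madgwick_orientation <- function(series, beta = 0.1, q_init = "from-accel",
                                 gyro_bias = c(0, 0, 0),
                                 gate = list(window = 0.5, accel_tol = 0.05,
                                             gyro_tol = 15)) {
  stopifnot(inherits(series, "imu_series"))
  n <- length(series$time)
  acc <- series$accel
  if (all(acc == 0) && all(series$gyro == 0))
    gait_stop("all-zero series: cannot estimate orientation", "gaitsva_invalid_input")
  if (beta < 0) gait_stop("`beta` must be >= 0", "gaitsva_invalid_parameter")
  dt <- 1 / series$sample_rate
  if (length(gyro_bias) == 1L) gyro_bias <- rep(gyro_bias, 3)
  gyr <- sweep(series$gyro, 2, gyro_bias) * pi / 180   # rad/s

  # the internal filter state maps sensor -> world under the standard
  # sandwich; the returned series is its conjugate (see @return)
  if (identical(q_init, "from-accel")) {
    a1 <- acc[1, ]
    na1 <- sqrt(sum(a1^2))
    if (na1 == 0) {
      q <- c(1, 0, 0, 0)
    } else {
      u <- a1 / na1; z <- c(0, 0, 1)
      axis <- c(u[2], -u[1], 0)              # u x z
      s <- sqrt(sum(axis^2))
      q <- if (s < 1e-12) c(1, 0, 0, 0) else
        quat_from_axis_angle(axis, atan2(s, u[3]))
    }
  } else {
    q <- quat_conjugate(quat_normalize(as.numeric(q_init)))
  }

  # quasi-static mask: every sample in the trailing window must be quiet
  still <- rep(TRUE, n)
  if (!is.null(gate)) {
    nm <- sqrt(rowSums(acc^2))
    gm <- sqrt(rowSums(series$gyro^2))
    ok <- abs(nm - 1) <= gate$accel_tol & gm <= gate$gyro_tol
    w <- max(1L, as.integer(round(gate$window * series$sample_rate)))
    cs <- cumsum(ok)
    still <- rep(FALSE, n)
    if (n > w) still[(w + 1L):n] <- (cs[(w + 1L):n] - cs[seq_len(n - w)]) == w
  }

  zero_acc_warned <- FALSE
  Q <- matrix(0, n, 4)
  Q[1, ] <- quat_conjugate(q)
  for (i in 2:n) {
    # exponential-map gyro increment with trapezoid-averaged rate
    wbar <- 0.5 * (gyr[i - 1, ] + gyr[i, ]) * dt
    ang <- sqrt(sum(wbar^2))
    dq <- if (ang > 1e-12) c(cos(ang / 2), sin(ang / 2) * wbar / ang) else c(1, 0, 0, 0)
    q <- quat_multiply(q, dq)
    if (beta > 0 && still[i]) {
      av <- acc[i, ]
      na <- sqrt(sum(av^2))
      if (na == 0) {
        if (!zero_acc_warned) {
          warning("zero-norm accelerometer sample: gyro-only step")
          zero_acc_warned <- TRUE
        }
      } else {
        a2 <- av / na
        q0 <- q[1]; q1 <- q[2]; q2 <- q[3]; q3 <- q[4]
        f <- c(2 * (q1 * q3 - q0 * q2) - a2[1],
               2 * (q0 * q1 + q2 * q3) - a2[2],
               2 * (0.5 - q1^2 - q2^2) - a2[3])
        s <- c(-2 * q2 * f[1] + 2 * q1 * f[2],
               2 * q3 * f[1] + 2 * q0 * f[2] - 4 * q1 * f[3],
               -2 * q0 * f[1] + 2 * q3 * f[2] - 4 * q2 * f[3],
               2 * q1 * f[1] + 2 * q2 * f[2])
        ns <- sqrt(sum(s^2))
        if (ns > 0) q <- q - beta * dt * s / ns
      }
    }
    q <- q / sqrt(sum(q^2))
    qc <- quat_conjugate(q)
    if (sum(qc * Q[i - 1, ]) < 0) { qc <- -qc; q <- -q }   # sign continuity
    Q[i, ] <- qc
  }
  structure(list(time = series$time, q = Q, sample_rate = series$sample_rate),
            class = "quaternion_series")
}

#' @export
print.quaternion_series <- function(x, ...) {
  cat(sprintf("<quaternion_series> %d samples @ %g Hz\n", nrow(x$q), x$sample_rate))
  invisible(x)
}

check_unit_quaternions <- function(qs, tol = 1e-6) {
  norms <- sqrt(rowSums(qs$q^2))
  if (any(abs(norms - 1) > tol))
    gait_stop("quaternions are not unit length", "gaitsva_invalid_quaternion")
  invisible(TRUE)
}

#' Sensor-to-vertical angle from orientation quaternions
#'
#' `theta = acos(2 q0 q2 + 2 q1 q3) - 90` degrees: the arccos argument is
#' the cosine of the angle between the world-frame sensor x-axis and up
#' (clamped to \[-1, 1\] to absorb rounding), so theta measures how far the
#' sensor x-axis dips below the horizontal plane. It is 0 for a vertical
#' segment, oscillates about 0 during walking, and -- unlike the z-axis
#' angle -- distinguishes leaning forward from leaning backward. Under the
#' package's axis conventions the medial-lateral angular rate equals
#' `+d theta/dt`.
#'
#' @param qs a `quaternion_series`.
#' @return Numeric vector of angles in degrees, in \[-90, 90\].
#' @export
sva_from_quaternion <- function(qs) {
  check_unit_quaternions(qs)
  q <- qs$q
  arg <- 2 * q[, 1] * q[, 3] + 2 * q[, 2] * q[, 4]
  acos(pmin(1, pmax(-1, arg))) * 180 / pi - 90
}

#' Angle between the sensor z-axis and up
#'
#' `theta_z = acos(q0^2 - q1^2 - q2^2 + q3^2)` in degrees, in \[0, 180\].
#' Provided as an auxiliary only: being an inverse cosine of the z-axis
#' elevation it cannot distinguish a limb leaning forward from one leaning
#' backward, which is why the x-axis-based SVA is used for gait.
#'
#' @inheritParams sva_from_quaternion
#' @return Numeric vector of angles in degrees.
#' @export
sva_z_from_quaternion <- function(qs) {
  check_unit_quaternions(qs)
  q <- qs$q
  arg <- q[, 1]^2 - q[, 2]^2 - q[, 3]^2 + q[, 4]^2
  acos(pmin(1, pmax(-1, arg))) * 180 / pi
}

#' Medial-lateral angular velocity
#'
#' After alignment the y-axis is the medial-lateral axis, so the sagittal
#' angular velocity is simply the gyroscope y channel (deg/s).
#'
#' @param series an aligned [imu_series].
#' @return Numeric vector, deg/s.
#' @export
angular_velocity_ml <- function(series) {
  stopifnot(inherits(series, "imu_series"))
  series$gyro[, 2]
}

# bundle of derived per-sample signals for one sensor
sva_series <- function(time, theta, theta_z, omega, placement, attachment) {
  structure(list(time = time, theta = theta, theta_z = theta_z, omega = omega,
                 placement = placement, attachment = attachment),
            class = "sva_series")
}

#' @export
print.sva_series <- function(x, ...) {
  cat(sprintf("<sva_series> %s/%s, %d samples, theta range [%.1f, %.1f] deg\n",
              x$placement, x$attachment, length(x$theta),
              min(x$theta), max(x$theta)))
  invisible(x)
}
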