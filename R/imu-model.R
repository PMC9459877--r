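#' Sensor mounting specification
#'
#' Where a sensor sits and how it is (mis)oriented. The nominal segment
#' frame has x in the sagittal plane (horizontal when the segment is
#' vertical), y medial-lateral and z up along the segment;
#' `mounting_rotation` rotates nominal-frame signals into the sensor's
#' actual frame, modelling the unknown initial orientation that alignment
#' must undo. `lever_arm` is the signed offset (metres) of the sensor from
#' the segment's rotation axis along the segment (negative below the
#' pivot, as for a shank sensor under the knee).
#'
#' @param placement,attachment,side sensor position enums.
#' @param mounting_rotation 3 x 3 proper rotation matrix.
#' @param lever_arm signed lever arm in metres; defaults per placement
#'   (waist +0.10, thigh -0.18, lower shank -0.42).
#' @return A list of class `mounting_spec`.
#' @export
mounting_spec <- function(placement = c("waist", "thigh", "lower_shank"),
                          attachment = c("body", "clothing"),
                          side = c("right", "left"),
                          mounting_rotation = diag(3),
                          lever_arm = NULL) {
  placement <- match.arg(placement)
  attachment <- match.arg(attachment)
  side <- match.arg(side)
  if (!is_rotation_matrix(mounting_rotation))
    gait_stop("`mounting_rotation` must be a proper rotation (orthonormal, det +1)",
              "gaitsva_invalid_parameter")
  if (is.null(lever_arm))
    lever_arm <- c(waist = 0.10, thigh = -0.18, lower_shank = -0.42)[[placement]]
  if (!is.finite(lever_arm))
    gait_stop("`lever_arm` must be finite", "gaitsva_invalid_parameter")
  structure(list(placement = placement, attachment = attachment, side = side,
                 mounting_rotation = mounting_rotation, lever_arm = lever_arm),
            class = "mounting_spec")
}

# 4th-order central finite difference (one-sided copy at the edges); exact
# enough (relative error ~1e-4 at gait frequencies) that derived gyro
# signals match analytic angle derivatives to well under 0.1 %
fd_derivative <- function(x, dt) {
  n <- length(x)
  y <- numeric(n)
  if (n >= 5) {
    y[3:(n - 2)] <- (-x[5:n] + 8 * x[4:(n - 1)] - 8 * x[2:(n - 3)] + x[1:(n - 4)]) / (12 * dt)
    y[2] <- (x[3] - x[1]) / (2 * dt)
    y[n - 1] <- (x[n] - x[n - 2]) / (2 * dt)
    y[1] <- (x[2] - x[1]) / dt
    y[n] <- (x[n] - x[n - 1]) / dt
  } else {
    y[] <- c(diff(x) / dt, 0)[seq_len(n)]
  }
  y
}

#' Synthesize IMU signals from segment kinematics
#'
#' Forward model inverse to the orientation pipeline. For the requested
#' placement, the segment's sagittal attitude is the rotation about the
#' medial-lateral axis implied by the stored segment-to-vertical angle.
#' The accelerometer measures specific force in g: gravity in the segment
#' frame plus the lever-arm linear acceleration obtained by double
#' finite-differencing of the angle, plus the segment's world-frame
#' translational acceleration, all rotated by the mounting rotation, plus
#' white noise. The gyroscope measures the medial-lateral angular rate
#' (deg/s) plus a constant bias and white noise, likewise mounting-rotated.
#' In the static noise-free case the accelerometer magnitude is exactly
#' 1 g.
#'
#' @param kin a [segment_kinematics] object.
#' @param mount a [mounting_spec()].
#' @param noise list with `accel_sd` (g), `gyro_sd` (deg/s) and `gyro_bias`
#'   (deg/s, length 1 or 3).
#' @param seed integer seed.
#' @return An [imu_series].
#' @export
imu_from_kinematics <- function(kin, mount = mounting_spec(),
                                noise = list(accel_sd = 0.02, gyro_sd = 1,
                                             gyro_bias = 0),
                                seed = 1L) {
  stopifnot(inherits(kin, "segment_kinematics"), inherits(mount, "mounting_spec"))
  n <- length(kin$time)
  if (n < 3L)
    gait_stop("need at least 3 samples to synthesize IMU data",
              "gaitsva_insufficient_data")
  withr_seed(seed)
  dt <- 1 / kin$sample_rate
  g0 <- 9.80665
  theta <- kin$angles[[mount$placement]]
  # attitude: sensor->world rotation about y by alpha = theta (so that the
  # SVA computed from the orientation quaternion reproduces theta, and the
  # medial-lateral gyro channel equals d theta/dt)
  alpha <- theta * pi / 180
  omega <- fd_derivative(alpha, dt)         # rad/s, gyro y channel
  alpha_dd <- fd_derivative(omega, dt)      # rad/s^2
  ca <- cos(alpha); sa <- sin(alpha)
  L <- mount$lever_arm
  # sensor position p = L * z_segment(world); p'' in world coordinates
  pdd_x <- L * (alpha_dd * ca - omega^2 * sa)
  pdd_z <- L * (-alpha_dd * sa - omega^2 * ca)
  lin <- kin$lin_accel[[mount$placement]]
  if (is.null(lin)) lin <- matrix(0, n, 2)
  fw_x <- (pdd_x + lin[, 1]) / g0
  fw_z <- 1 + (pdd_z + lin[, 2]) / g0
  # world -> nominal segment frame: R_y(alpha)^T
  acc_seg <- cbind(ca * fw_x - sa * fw_z, 0, sa * fw_x + ca * fw_z)
  gyr_seg <- cbind(0, omega * 180 / pi, 0)
  bias <- noise$gyro_bias
  if (is.null(bias)) bias <- 0
  if (length(bias) == 1L) bias <- rep(bias, 3)
  acc_sen <- acc_seg %*% t(mount$mounting_rotation) +
    matrix(stats::rnorm(3 * n, 0, noise$accel_sd %||% 0), n, 3)
  gyr_sen <- sweep(gyr_seg %*% t(mount$mounting_rotation), 2, bias, "+") +
    matrix(stats::rnorm(3 * n, 0, noise$gyro_sd %||% 0), n, 3)
  imu_series(kin$time, acc_sen, gyr_sen,
             placement = mount$placement, attachment = mount$attachment,
             side = mount$side, sample_rate = kin$sample_rate)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
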