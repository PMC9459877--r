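#' Alignment rotations
#'
#' Container for the two sensor-to-anatomical alignment rotations: a
#' gravity rotation bringing the standing mean acceleration onto the
#' world z-axis, and a rotation about z bringing the dominant sagittal
#' acceleration direction onto the x-axis.
#'
#' @param r_gravity,r_sagittal 3 x 3 proper rotation matrices; `r_sagittal`
#'   must leave the world z-axis fixed.
#' @return List of class `alignment_rotations`.
#' @export
alignment_rotations <- function(r_gravity = diag(3), r_sagittal = diag(3)) {
  if (!is_rotation_matrix(r_gravity) || !is_rotation_matrix(r_sagittal))
    gait_stop("alignment rotations must be proper rotation matrices",
              "gaitsva_invalid_parameter")
  if (max(abs(r_sagittal %*% c(0, 0, 1) - c(0, 0, 1))) > 1e-8)
    gait_stop("`r_sagittal` must leave the world z-axis fixed",
              "gaitsva_invalid_parameter")
  structure(list(r_gravity = r_gravity, r_sagittal = r_sagittal),
            class = "alignment_rotations")
}

#' Estimate the gravity-alignment rotation from standing data
#'
#' While the wearer stands still the only measured acceleration is
#' gravity, so the mean accelerometer vector marks "up" in the sensor
#' frame. The returned rotation is built with Rodrigues' formula about the
#' axis perpendicular to both the mean acceleration and the z-axis, by the
#' angle between them, so that the rotated mean acceleration points along
#' (0, 0, +1).
#'
#' @param standing an [imu_series] covering a standing segment (at least
#'   2 s); the mean acceleration magnitude must lie in the quasi-static
#'   band 0.8 g to 1.2 g.
#' @return A 3 x 3 rotation matrix.
#' @export
estimate_gravity_rotation <- function(standing) {
  stopifnot(inherits(standing, "imu_series"))
  if (diff(range(standing$time)) < 2)
    gait_stop("standing segment must cover at least 2 s", "gaitsva_insufficient_data")
  a <- colMeans(standing$accel)
  na <- sqrt(sum(a^2))
  if (na < 0.8 || na > 1.2)
    gait_stop(sprintf(
      "mean acceleration magnitude %.2f g outside the quasi-static band [0.8, 1.2]; not a standing segment",
      na), "gaitsva_not_standing")
  u <- a / na
  z <- c(0, 0, 1)
  cosang <- sum(u * z)
  if (cosang < cos(179 * pi / 180))
    gait_stop("mean acceleration is antiparallel to z (rotation axis degenerate)",
              "gaitsva_degenerate_axis")
  axis <- c(u[2] * z[3] - u[3] * z[2],
            u[3] * z[1] - u[1] * z[3],
            u[1] * z[2] - u[2] * z[1])     # u x z
  s <- sqrt(sum(axis^2))
  if (s < 1e-12) return(diag(3))
  k <- axis / s
  ang <- atan2(s, cosang)
  # Rodrigues: R = I + sin(ang) K + (1 - cos(ang)) K^2
  Km <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(ang) * Km + (1 - cos(ang)) * (Km %*% Km)
}

#' Estimate the sagittal-alignment rotation from dynamic data
#'
#' After gravity alignment, movements performed in the sagittal plane
#' (sit-to-stand, leg raises, walking) accelerate the sensor mostly along
#' one horizontal direction. That direction is estimated as the first
#' principal axis of the zero-meaned horizontal acceleration components,
#' and the returned rotation about the world z-axis maps it onto the
#' x-axis. The sign is chosen so that the strongest horizontal
#' accelerations (the top decile by magnitude, summed) project positively
#' on the new x-axis; aggregating over the strongest samples makes the
#' sign immune to single-sample noise extremes.
#'
#' @param dynamic a gravity-aligned [imu_series] covering at least 5 s of
#'   sagittal movement.
#' @param min_horizontal_sd minimum SD (g) of the horizontal acceleration
#'   below which the excitation is considered insufficient.
#' @param sign_idx optional integer subset of samples used for the sign
#'   decision only (e.g. the walking segment, whose anterior-posterior
#'   accelerations are the most stereotyped); the principal direction
#'   itself always uses all samples.
#' @return A 3 x 3 rotation matrix about z.
#' @export
estimate_sagittal_rotation <- function(dynamic, min_horizontal_sd = 0.03,
                                       sign_idx = NULL) {
  stopifnot(inherits(dynamic, "imu_series"))
  if (diff(range(dynamic$time)) < 5)
    gait_stop("dynamic segment must cover at least 5 s", "gaitsva_insufficient_data")
  h <- dynamic$accel[, 1:2, drop = FALSE]
  hc <- sweep(h, 2, colMeans(h))
  if (sqrt(mean(rowSums(hc^2))) < min_horizontal_sd)
    gait_stop("horizontal acceleration variance too low: no sagittal excitation",
              "gaitsva_insufficient_excitation")
  ev <- eigen(crossprod(hc), symmetric = TRUE)
  dir <- ev$vectors[, 1]
  hs <- if (is.null(sign_idx)) hc else hc[sign_idx, , drop = FALSE]
  hm <- rowSums(hs^2)
  top <- hm >= stats::quantile(hm, 0.9)
  if (sum(hs[top, , drop = FALSE] %*% dir) < 0) dir <- -dir
  phi <- atan2(dir[2], dir[1])
  rot_z(-phi)
}

#' Apply alignment rotations to an IMU series
#'
#' Rotates accelerometer and gyroscope samples into the participant
#' anatomical frame: gravity rotation first, then the sagittal rotation
#' about z. Rotations are isometries, so per-sample vector norms are
#' preserved.
#'
#' @param series an [imu_series].
#' @param rot an [alignment_rotations()] object.
#' @return The rotated [imu_series].
#' @export
apply_alignment <- function(series, rot) {
  stopifnot(inherits(series, "imu_series"), inherits(rot, "alignment_rotations"))
  R <- rot$r_sagittal %*% rot$r_gravity
  series$accel <- series$accel %*% t(R)
  series$gyro <- series$gyro %*% t(R)
  series
}

# convenience: subset an imu_series by sample indices (keeps uniform grid)
slice_series <- function(series, idx) {
  series$time <- series$time[idx]
  series$accel <- series$accel[idx, , drop = FALSE]
  series$gyro <- series$gyro[idx, , drop = FALSE]
  series
}
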