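#' Quaternion utilities
#'
#' Scalar-first unit quaternions represent rotations; `quat_rotate(q, v)`
#' applies `q (0,v) q*`, i.e. rotates sensor-frame vectors into the world
#' frame under the package convention.
#'
#' @param q,p numeric length-4 quaternions (scalar first), or for
#'   [quat_rotate()] an n x 4 matrix of quaternions.
#' @param v numeric length-3 vector, or an n x 3 matrix matched row-wise
#'   with `q`.
#' @return [quat_multiply()], [quat_conjugate()], [quat_normalize()] and
#'   [quat_from_axis_angle()] return length-4 quaternions; [quat_rotate()]
#'   returns a vector or matrix of rotated 3-vectors.
#' @examples
#' q <- quat_from_axis_angle(c(0, 1, 0), pi / 2)
#' quat_rotate(q, c(1, 0, 0))  # x-axis maps to (0, 0, -1)
#' @name quaternions
NULL

#' @rdname quaternions
#' @export
quat_multiply <- function(q, p) {
  c(q[1] * p[1] - q[2] * p[2] - q[3] * p[3] - q[4] * p[4],
    q[1] * p[2] + q[2] * p[1] + q[3] * p[4] - q[4] * p[3],
    q[1] * p[3] - q[2] * p[4] + q[3] * p[1] + q[4] * p[2],
    q[1] * p[4] + q[2] * p[3] - q[3] * p[2] + q[4] * p[1])
}

#' @rdname quaternions
#' @export
quat_conjugate <- function(q) c(q[1], -q[2], -q[3], -q[4])

#' @rdname quaternions
#' @export
quat_normalize <- function(q) {
  n <- sqrt(sum(q^2))
  if (n == 0) gait_stop("cannot normalize a zero quaternion", "gaitsva_invalid_quaternion")
  q / n
}

#' @param axis numeric length-3 rotation axis (need not be unit length).
#' @param angle rotation angle in radians.
#' @rdname quaternions
#' @export
quat_from_axis_angle <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n == 0) {
    if (abs(angle) > 1e-12)
      gait_stop("zero axis with non-zero angle", "gaitsva_invalid_parameter")
    return(c(1, 0, 0, 0))
  }
  c(cos(angle / 2), sin(angle / 2) * axis / n)
}

#' @rdname quaternions
#' @export
quat_rotate <- function(q, v) {
  if (is.matrix(q)) {
    if (!is.matrix(v)) v <- matrix(v, nrow(q), 3, byrow = TRUE)
    q0 <- q[, 1]; q1 <- q[, 2]; q2 <- q[, 3]; q3 <- q[, 4]
    vx <- v[, 1]; vy <- v[, 2]; vz <- v[, 3]
  } else {
    q0 <- q[1]; q1 <- q[2]; q2 <- q[3]; q3 <- q[4]
    vx <- v[1]; vy <- v[2]; vz <- v[3]
  }
  # R(q) %*% v with R the standard rotation matrix of q (v_world = q v q*)
  rx <- (1 - 2 * (q2^2 + q3^2)) * vx + 2 * (q1 * q2 - q0 * q3) * vy + 2 * (q1 * q3 + q0 * q2) * vz
  ry <- 2 * (q1 * q2 + q0 * q3) * vx + (1 - 2 * (q1^2 + q3^2)) * vy + 2 * (q2 * q3 - q0 * q1) * vz
  rz <- 2 * (q1 * q3 - q0 * q2) * vx + 2 * (q2 * q3 + q0 * q1) * vy + (1 - 2 * (q1^2 + q2^2)) * vz
  if (is.matrix(q)) cbind(rx, ry, rz, deparse.level = 0) else c(rx, ry, rz)
}

# rotation matrix (sensor -> world) from a unit quaternion
quat_to_matrix <- function(q) {
  q0 <- q[1]; q1 <- q[2]; q2 <- q[3]; q3 <- q[4]
  matrix(c(
    1 - 2 * (q2^2 + q3^2), 2 * (q1 * q2 - q0 * q3), 2 * (q1 * q3 + q0 * q2),
    2 * (q1 * q2 + q0 * q3), 1 - 2 * (q1^2 + q3^2), 2 * (q2 * q3 - q0 * q1),
    2 * (q1 * q3 - q0 * q2), 2 * (q2 * q3 + q0 * q1), 1 - 2 * (q1^2 + q2^2)
  ), 3, 3, byrow = TRUE)
}

# rotation about the world y-axis; Ry(a) tips the z-axis toward +x for a > 0
rot_y <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, 0, sa, 0, 1, 0, -sa, 0, ca), 3, 3, byrow = TRUE)
}

# rotation about the world z-axis
rot_z <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

is_rotation_matrix <- function(R, tol = 1e-8) {
  is.matrix(R) && all(dim(R) == c(3, 3)) &&
    max(abs(crossprod(R) - diag(3))) < tol && abs(det(R) - 1) < tol
}

# uniformly random rotation axis, bounded angle; used for mounting errors
random_rotation <- function(max_angle, min_angle = 0) {
  ax <- stats::rnorm(3)
  ang <- stats::runif(1, min_angle, max_angle)
  quat_to_matrix(quat_from_axis_angle(ax, ang))
}
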