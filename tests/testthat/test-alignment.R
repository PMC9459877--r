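make_standing_series <- function(accel_mean, n = 150, fs = 50, sd = 0) {
  acc <- matrix(rep(accel_mean, each = n), n, 3) + matrix(rnorm(3 * n, 0, sd), n, 3)
  imu_series((0:(n - 1)) / fs, acc, matrix(0, n, 3), "lower_shank", "body")
}

test_that("gravity rotation reproduces the Rodrigues construction", {
  # already aligned: identity
  expect_equal(estimate_gravity_rotation(make_standing_series(c(0, 0, 1))),
               diag(3), tolerance = 1e-12)
  # x-axis gravity: rotation maps (1,0,0) to (0,0,1)
  R <- estimate_gravity_rotation(make_standing_series(c(1, 0, 0)))
  expect_equal(as.numeric(R %*% c(1, 0, 0)), c(0, 0, 1), tolerance = 1e-12)
  # oracle case: mean (0, 0.6, 0.8) rotates about (1,0,0) by acos(0.8)
  R <- estimate_gravity_rotation(make_standing_series(c(0, 0.6, 0.8)))
  expect_equal(as.numeric(R %*% c(0, 0.6, 0.8)), c(0, 0, 1), tolerance = 1e-12)
  oracle <- gaitsva:::quat_to_matrix(quat_from_axis_angle(c(1, 0, 0), acos(0.8)))
  expect_equal(R, oracle, tolerance = 1e-9)
})

test_that("gravity rotation rejects non-standing and degenerate input", {
  expect_error(estimate_gravity_rotation(make_standing_series(c(0, 0, 2))),
               class = "gaitsva_not_standing")
  expect_error(estimate_gravity_rotation(make_standing_series(c(0, 0, 0.4))),
               class = "gaitsva_not_standing")
  expect_error(estimate_gravity_rotation(make_standing_series(c(0, 0, -1))),
               class = "gaitsva_degenerate_axis")
  short <- make_standing_series(c(0, 0, 1), n = 50)
  expect_error(estimate_gravity_rotation(short), class = "gaitsva_insufficient_data")
})

make_dynamic_series <- function(phi_deg, n = 400, fs = 50, amp = 0.5) {
  t <- (0:(n - 1)) / fs
  base <- sin(2 * pi * 1.3 * t)
  # positively skewed oscillation: strongest accelerations point along +dir
  mag <- amp * (base + 0.8 * pmax(base, 0))
  phi <- phi_deg * pi / 180
  acc <- cbind(mag * cos(phi), mag * sin(phi), 1)
  imu_series(t, acc, matrix(0, n, 3), "lower_shank", "body")
}

test_that("sagittal rotation recovers the principal horizontal direction", {
  # motion along x: identity
  expect_equal(estimate_sagittal_rotation(make_dynamic_series(0)), diag(3),
               tolerance = 1e-9)
  # motion along y: +-90 degrees about z, recovered within 1e-9
  R <- estimate_sagittal_rotation(make_dynamic_series(90))
  expect_equal(abs(R[1, 2]), 1, tolerance = 1e-9)
  expect_equal(R[3, ], c(0, 0, 1), tolerance = 1e-12)
  # 30 degrees off x: rotation by -30 degrees about z, within 0.1 degree
  R <- estimate_sagittal_rotation(make_dynamic_series(30))
  ang <- atan2(R[2, 1], R[1, 1]) * 180 / pi
  expect_lt(abs(ang + 30), 0.1)
  # sign rule: the largest-magnitude sample must project positively on new x
  d <- make_dynamic_series(30)
  h <- d$accel[, 1:2]
  hc <- sweep(h, 2, colMeans(h))
  imax <- which.max(rowSums(hc^2))
  newx <- (R %*% c(hc[imax, ], 0))[1]
  expect_gt(newx, 0)
})

test_that("insufficient sagittal excitation raises an error", {
  quiet <- make_dynamic_series(0, amp = 0.001)
  expect_error(estimate_sagittal_rotation(quiet),
               class = "gaitsva_insufficient_excitation")
  short <- make_dynamic_series(0, n = 100)
  expect_error(estimate_sagittal_rotation(short),
               class = "gaitsva_insufficient_data")
})

test_that("applying alignment preserves per-sample norms (isometry)", {
  set.seed(1)
  n <- 100
  s <- imu_series((0:(n - 1)) / 50, matrix(rnorm(3 * n), n, 3),
                  matrix(rnorm(3 * n, 0, 50), n, 3), "thigh", "clothing")
  rot <- alignment_rotations(
    r_gravity = gaitsva:::quat_to_matrix(quat_from_axis_angle(c(1, 1, 0), 0.5)),
    r_sagittal = gaitsva:::rot_z(1.1))
  a <- apply_alignment(s, rot)
  expect_equal(rowSums(a$accel^2), rowSums(s$accel^2), tolerance = 1e-12)
  expect_equal(rowSums(a$gyro^2), rowSums(s$gyro^2), tolerance = 1e-12)
  # identity rotations leave the series unchanged
  id <- apply_alignment(s, alignment_rotations())
  expect_equal(id$accel, s$accel)
})

test_that("alignment rotations validate their invariants", {
  expect_error(alignment_rotations(r_sagittal = gaitsva:::rot_y(0.3)),
               class = "gaitsva_invalid_parameter")
  expect_error(alignment_rotations(r_gravity = matrix(1, 3, 3)),
               class = "gaitsva_invalid_parameter")
})

test_that("on synthetic sessions the composed alignment undoes the mounting", {
  sim <- default_sim()
  res <- default_run()
  t <- sim$truth$body$time
  stand <- which(t < 28)
  for (key in names(res$aligned)) {
    # aligned standing mean acceleration back to (0,0,1) g
    a <- colMeans(res$aligned[[key]]$accel[stand, ])
    tilt <- acos(a[3] / sqrt(sum(a^2))) * 180 / pi
    expect_lt(tilt, 1)
    # composed alignment inverts the mounting rotation (within 2 deg/axis)
    Rc <- res$rotations[[key]]$r_sagittal %*% res$rotations[[key]]$r_gravity
    M <- Rc %*% sim$truth$mountings[[key]]$mounting_rotation
    # yaw-pitch-roll residuals of the (near-identity) product
    yaw <- atan2(M[2, 1], M[1, 1]) * 180 / pi
    pitch <- -asin(max(-1, min(1, M[3, 1]))) * 180 / pi
    roll <- atan2(M[3, 2], M[3, 3]) * 180 / pi
    expect_lt(max(abs(c(yaw, pitch, roll))), 2)
  }
})
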