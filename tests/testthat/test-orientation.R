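static_series <- function(accel, n = 600, fs = 50, gyro = c(0, 0, 0)) {
  imu_series((0:(n - 1)) / fs,
             matrix(rep(accel, each = n), n, 3),
             matrix(rep(gyro, each = n), n, 3), "lower_shank", "body")
}

test_that("identity is a fixed point of the orientation filter", {
  qs <- madgwick_orientation(static_series(c(0, 0, 1)), beta = 0.1)
  expect_equal(max(abs(sweep(qs$q, 2, c(1, 0, 0, 0)))), 0, tolerance = 1e-9)
})

test_that("beta = 0 reduces to exact gyro integration (closed-form oracle)", {
  # constant rate about y for t seconds -> axis-angle(y, omega t)
  fs <- 50; n <- 151; omega <- 40  # deg/s over 3 s -> 120 degrees
  s <- static_series(c(0, 0, 1), n = n, gyro = c(0, omega, 0))
  qs <- madgwick_orientation(s, beta = 0, q_init = c(1, 0, 0, 0))
  t_end <- (n - 1) / fs
  # stored convention (world -> sensor): the conjugate of the rotation
  q_true <- quat_from_axis_angle(c(0, 1, 0), -omega * pi / 180 * t_end)
  ang_err <- 2 * acos(min(1, abs(sum(qs$q[n, ] * q_true)))) * 180 / pi
  expect_lt(ang_err, 0.1)
})

test_that("static tilt converges from arbitrary initial orientation", {
  # accel for a 20-degree SVA: the attitude is a rotation about y by +20 deg
  theta_true <- 20
  alpha <- theta_true * pi / 180
  accel <- c(-sin(alpha), 0, cos(alpha))
  s <- static_series(accel, n = 500)
  for (tilt0 in c(30, -40)) {
    q0 <- quat_from_axis_angle(c(0.2, 1, 0.1), tilt0 * pi / 180)
    qs <- madgwick_orientation(s, beta = 0.1, q_init = q0)
    theta <- sva_from_quaternion(qs)
    expect_lt(abs(theta[500] - theta_true), 0.5)
  }
})

test_that("SVA formula reproduces its defining cases", {
  mk <- function(q) structure(list(time = 0, q = matrix(q, 1, 4), sample_rate = 50),
                              class = "quaternion_series")
  expect_equal(sva_from_quaternion(mk(c(1, 0, 0, 0))), 0)
  # 90-degree rotation about y maps x to straight down/up: theta = -90
  expect_equal(sva_from_quaternion(mk(c(cos(pi / 4), 0, sin(pi / 4), 0))), -90)
  # half-angle 15 deg: 2 q0 q2 = sin(30 deg) = 0.5 -> theta = 60 - 90 = -30
  expect_equal(sva_from_quaternion(mk(c(cos(pi / 12), 0, sin(pi / 12), 0))), -30,
               tolerance = 1e-12)
  expect_error(sva_from_quaternion(mk(c(2, 0, 0, 0))),
               class = "gaitsva_invalid_quaternion")
})

test_that("z-axis angle matches explicit vector rotation for random quaternions", {
  mk <- function(Q) structure(list(time = seq_len(nrow(Q)), q = Q, sample_rate = 50),
                              class = "quaternion_series")
  expect_equal(sva_z_from_quaternion(mk(matrix(c(1, 0, 0, 0), 1))), 0)
  q90 <- quat_from_axis_angle(c(0, 1, 0), pi / 2)
  expect_equal(sva_z_from_quaternion(mk(matrix(q90, 1))), 90, tolerance = 1e-9)
  set.seed(99)
  Q <- t(replicate(500, random_quaternion()))
  tz <- sva_z_from_quaternion(mk(Q))
  zrot <- quat_rotate(Q, c(0, 0, 1))
  oracle <- acos(pmin(1, pmax(-1, zrot[, 3]))) * 180 / pi
  expect_equal(tz, oracle, tolerance = 1e-9)
})

test_that("SVA matches the brute-force rotation of the sensor x-axis", {
  mk <- function(Q) structure(list(time = seq_len(nrow(Q)), q = Q, sample_rate = 50),
                              class = "quaternion_series")
  set.seed(123)
  Q <- t(replicate(1000, random_quaternion()))
  theta <- sva_from_quaternion(mk(Q))
  # sensor -> world rotation is the conjugate sandwich q* v q
  xrot <- quat_rotate(cbind(Q[, 1], -Q[, 2:4]), c(1, 0, 0))
  ang_up <- acos(pmin(1, pmax(-1, xrot[, 3]))) * 180 / pi
  # theta = (angle of world x-axis from up) - 90, i.e. 90 minus its angle
  # from the downward vertical
  expect_equal(theta, ang_up - 90, tolerance = 1e-9)
  expect_equal(theta, 90 - (180 - ang_up), tolerance = 1e-9)
  expect_true(all(theta >= -90 & theta <= 90))
})

test_that("quaternion norms and sign continuity hold on a noisy session", {
  res <- default_run()
  s <- res$aligned$lower_shank_body
  qs <- madgwick_orientation(s, beta = 0.1,
                             gyro_bias = res$gyro_bias$lower_shank_body)
  norms <- sqrt(rowSums(qs$q^2))
  expect_lt(max(abs(norms - 1)), 1e-9)
  dots <- rowSums(qs$q[-1, ] * qs$q[-nrow(qs$q), ])
  expect_true(all(dots >= 0))
})

test_that("angular velocity output is the gyro y channel", {
  s <- static_series(c(0, 0, 1), n = 100, gyro = c(3, -7, 2))
  expect_equal(angular_velocity_ml(s), rep(-7, 100))
})

test_that("omega matches the filtered analytic angle derivative within 1% RMS", {
  sim <- nf_sim()
  res <- nf_run()
  fs <- 50
  sel <- walking_window(sim)
  # analytic medial-lateral rate: -d(theta)/dt of the true shank angle
  truth_rate <- gaitsva:::fd_derivative(sim$truth$body$angles$lower_shank, 1 / fs)
  truth_filt <- lowpass_filter(truth_rate, cutoff = 3, sample_rate = fs)
  omega <- res$sva$lower_shank_body$omega
  rel <- sqrt(mean((omega[sel] - truth_filt[sel])^2)) /
    sqrt(mean(truth_filt[sel]^2))
  expect_lt(rel, 0.01)
})

test_that("noise-free shank SVA recovers the generated angle to 1 deg RMS", {
  sim <- nf_sim()
  res <- nf_run()
  sel <- walking_window(sim)
  err <- res$sva$lower_shank_body$theta[sel] - sim$truth$body$angles$lower_shank[sel]
  expect_lt(sqrt(mean(err^2)), 1)
})

test_that("invalid orientation inputs error", {
  zero <- imu_series((0:99) / 50, matrix(0, 100, 3), matrix(0, 100, 3),
                     "waist", "body")
  expect_error(madgwick_orientation(zero), class = "gaitsva_invalid_input")
  s <- static_series(c(0, 0, 1))
  expect_error(madgwick_orientation(s, beta = -1), class = "gaitsva_invalid_parameter")
})
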