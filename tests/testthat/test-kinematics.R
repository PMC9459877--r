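test_that("generator is deterministic in the seed and varies across seeds", {
  k1 <- generate_kinematics(gait_params(n_cycles = 5), seed = 11)
  k2 <- generate_kinematics(gait_params(n_cycles = 5), seed = 11)
  k3 <- generate_kinematics(gait_params(n_cycles = 5), seed = 12)
  expect_identical(k1, k2)
  expect_false(isTRUE(all.equal(k1$angles, k3$angles)))
})

test_that("event times honour the stance fraction and ordering by construction", {
  for (sf in c(0.55, 0.60, 0.65)) {
    p <- gait_params(n_cycles = 8, stance_fraction = sf, cycle_duration = 1.2,
                     variability = 0.03)
    k <- generate_kinematics(p, seed = 2)
    ev <- k$events
    # per cycle: ms < ic < to < next ms
    expect_true(all(ev$ms_time < ev$ic_time))
    expect_true(all(ev$ic_time < ev$to_time))
    expect_true(all(utils::head(ev$to_time, -1) < utils::tail(ev$ms_time, -1)))
    # IC-to-TO span equals stance_fraction x (individual) cycle duration
    durs <- diff(ev$ms_time)
    expect_equal(ev$to_time[-nrow(ev)] - ev$ic_time[-nrow(ev)], sf * durs,
                 tolerance = 1e-9)
  }
})

test_that("zero amplitude degenerates to constant angles with events still emitted", {
  p <- gait_params(n_cycles = 4, amplitude = c(waist = 0, thigh = 0, lower_shank = 0),
                   variability = 0, amplitude_variability = 0)
  k <- generate_kinematics(p, seed = 1)
  expect_equal(diff(range(k$angles$lower_shank)), 0)
  expect_equal(nrow(k$events), 4)
})

test_that("invalid gait parameters are rejected", {
  expect_error(gait_params(cycle_duration = -1), class = "gaitsva_invalid_parameter")
  expect_error(gait_params(n_cycles = 0), class = "gaitsva_invalid_parameter")
  expect_error(gait_params(stance_fraction = 1.2), class = "gaitsva_invalid_parameter")
  expect_error(gait_params(amplitude = c(waist = -1, thigh = 10, lower_shank = 10)),
               class = "gaitsva_invalid_parameter")
})

test_that("shank angular velocity peaks at MS with prominent minima at IC and TO", {
  p <- gait_params(n_cycles = 6, variability = 0, amplitude_variability = 0)
  k <- generate_kinematics(p, seed = 1)
  fs <- p$sample_rate
  # angular rate about the medial-lateral axis is d(theta)/dt
  omega <- gaitsva:::fd_derivative(k$angles$lower_shank, 1 / fs)
  ev <- k$events
  for (i in 2:5) {
    win <- which(k$time >= ev$ms_time[i] - 0.12 & k$time < ev$ms_time[i + 1] - 0.12)
    w <- omega[win]
    # global |omega| max at MS (within one sample)
    i_ms <- which.min(abs(k$time[win] - ev$ms_time[i]))
    expect_lte(abs(which.max(abs(w)) - i_ms), 1)
    # local minima at IC and TO
    mins <- gaitsva:::prominent_minima(w, 10)
    t_mins <- k$time[win][mins]
    expect_lt(min(abs(t_mins - ev$ic_time[i])), 0.045)
    expect_lt(min(abs(t_mins - ev$to_time[i])), 0.045)
  }
})

test_that("rigid fabric coupling reproduces the body angle", {
  p <- gait_params(n_cycles = 10, variability = 0)
  k <- generate_kinematics(p, seed = 4)
  rigid <- fabric_coupling(stiffness = 9000, damping = 20, gain = 1, noise_sd = 0)
  kc <- clothing_transform(k, rigid, seed = 1)
  expect_lt(max(abs(kc$angles$lower_shank - k$angles$lower_shank)), 0.5)
  expect_identical(kc$events, k$events)
})

test_that("quasi-static fabric response scales by the gain", {
  # very slow sinusoid: the spring-damper tracks with amplitude ratio = gain
  fs <- 50
  t <- seq(0, 40, by = 1 / fs)
  slow <- 10 * sin(2 * pi * 0.1 * t)
  kin <- structure(list(time = t,
                        angles = data.frame(waist = slow, thigh = slow,
                                            lower_shank = slow),
                        events = NULL, stance_fraction = 0.6, sample_rate = fs,
                        lin_accel = NULL),
                   class = "segment_kinematics")
  cp <- fabric_coupling(stiffness = 900, damping = 30, gain = 1.2, noise_sd = 0)
  kc <- clothing_transform(kin, cp, seed = 1)
  sel <- t > 15
  ratio <- max(abs(kc$angles$lower_shank[sel])) / max(abs(slow[sel]))
  expect_equal(ratio, 1.2, tolerance = 0.02)
})

test_that("underdamped step response matches the closed-form overshoot", {
  fs <- 50
  t <- seq(0, 20, by = 1 / fs)
  step <- ifelse(t >= 5, 10, 0)
  kin <- structure(list(time = t,
                        angles = data.frame(waist = step, thigh = step,
                                            lower_shank = step),
                        events = NULL, stance_fraction = 0.6, sample_rate = fs,
                        lin_accel = NULL),
                   class = "segment_kinematics")
  wn <- 20; zeta <- 0.3
  cp <- fabric_coupling(stiffness = wn^2, damping = 2 * zeta * wn, gain = 1,
                        noise_sd = 0)
  kc <- clothing_transform(kin, cp, seed = 1)
  overshoot <- (max(kc$angles$lower_shank) - 10) / 10
  expected <- exp(-pi * zeta / sqrt(1 - zeta^2))
  expect_lt(abs(overshoot - expected) / expected, 0.05)
})

test_that("increasing fabric noise monotonically degrades the angle agreement", {
  p <- gait_params(n_cycles = 20)
  k <- generate_kinematics(p, seed = 6)
  cors <- vapply(c(0, 1, 2.5, 5), function(ns) {
    cp <- fabric_coupling(stiffness = 2500, damping = 50, gain = 1.1,
                          noise_sd = ns, noise_cutoff = 2.5)
    kc <- clothing_transform(k, cp, seed = 9)
    stats::cor(kc$angles$lower_shank, k$angles$lower_shank)
  }, numeric(1))
  expect_true(all(diff(cors) < 0))
})

test_that("unstable or invalid coupling parameters error out", {
  expect_error(fabric_coupling(stiffness = -1), class = "gaitsva_invalid_parameter")
  expect_error(fabric_coupling(damping = -1), class = "gaitsva_invalid_parameter")
  expect_error(fabric_coupling(gain = -0.1), class = "gaitsva_invalid_parameter")
})
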