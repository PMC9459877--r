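test_that("mid-swing detection finds constructed peaks and only those", {
  fs <- 50
  t <- (0:(6 * fs - 1)) / fs
  mag <- rep(1, length(t))
  centres <- c(1.0, 2.2, 3.4)
  for (ct in centres) mag <- mag + 1.5 * exp(-((t - ct) / 0.08)^2)
  # constant magnitude -> nothing
  expect_length(detect_midswing(rep(1, 300), fs, threshold = 1.8), 0)
  ms <- detect_midswing(mag, fs, threshold = 1.8, min_separation = 1.0)
  expect_equal(ms, round(centres * fs) + 1L)
})

test_that("the larger of two close peaks wins (min-separation rule)", {
  fs <- 50
  t <- (0:(4 * fs - 1)) / fs
  mag <- 1 + 1.5 * exp(-((t - 1.0) / 0.08)^2) + 1.2 * exp(-((t - 1.5) / 0.08)^2)
  ms <- detect_midswing(mag, fs, threshold = 1.8, min_separation = 1.0)
  expect_equal(ms, round(1.0 * fs) + 1L)
})

test_that("detector is idempotent and monotone in the threshold", {
  sim <- default_sim()
  run <- default_run()
  mag <- gaitsva:::accel_magnitude(run$aligned$lower_shank_body)
  fs <- 50
  ms <- detect_midswing(mag, fs, threshold = 1.8)
  # idempotence: a series containing only the retained peaks reproduces them
  iso <- rep(1, length(mag))
  iso[ms] <- mag[ms]
  # make each retained peak a genuine local maximum
  expect_equal(detect_midswing(iso, fs, threshold = 1.8), ms)
  # raising the threshold never yields more peaks
  counts <- vapply(c(1.5, 1.8, 2.1, 2.5, 3.0), function(th)
    length(detect_midswing(mag, fs, threshold = th)), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("threshold at or below 1 g is rejected", {
  expect_error(detect_midswing(rep(1, 100), 50, threshold = 1),
               class = "gaitsva_invalid_parameter")
})

test_that("fixed-length segmentation follows the mean-gap rule", {
  # MS at samples 1, 51, 101 (0, 50, 100 zero-based), series of 150
  cyc <- segment_cycles(c(1L, 51L, 101L), 150L, 50)
  expect_equal(cyc$cycle_length, 50L)
  expect_equal(cyc$cycles$start, c(1L, 51L, 101L))  # 101 + 50 - 1 = 150 fits
  # uneven gaps: mean of 48 and 54 rounds to 51
  cyc <- segment_cycles(c(1L, 49L, 103L), 150L, 50)
  expect_equal(cyc$cycle_length, 51L)
  expect_equal(cyc$cycles$start, c(1L, 49L))        # 103 + 51 - 1 > 150 dropped
  expect_error(segment_cycles(c(10L), 150L, 50), class = "gaitsva_cannot_segment")
})

test_that("IC/TO detection hits constructed minima exactly and flags flat cycles", {
  L <- 60
  w <- rep(10, 3 * L)
  truth_ic <- c(); truth_to <- c()
  for (k in 0:2) {
    s <- k * L
    w[s + 13] <- -30  # sharp IC dip
    w[s + 49] <- -25  # sharp TO dip
    truth_ic <- c(truth_ic, s + 13); truth_to <- c(truth_to, s + 49)
  }
  cyc <- segment_cycles(c(1L, 1L + L, 1L + 2L * L), 3L * L, 50)
  cyc <- detect_ic_to(w, cyc, prominence = 8)
  expect_equal(cyc$cycles$ic, as.integer(truth_ic))
  expect_equal(cyc$cycles$to, as.integer(truth_to))
  expect_false(any(cyc$cycles$flagged))
  # flat signal: all cycles flagged, none hard-fail
  cyc2 <- detect_ic_to(rep(0, 3 * L), segment_cycles(c(1L, 1L + L), 3L * L, 50))
  expect_true(all(cyc2$cycles$flagged))
})

test_that("propagation produces per-cycle matrices with correct moments", {
  cyc <- segment_cycles(c(1L, 11L, 21L), 40L, 50)
  x <- rep(sin(2 * pi * (0:9) / 10), 4)
  pr <- propagate_segmentation(cyc, x)
  expect_equal(dim(pr$matrix), c(3, 10))
  # identical repeated cycles: SD identically 0
  expect_equal(pr$sd, rep(0, 10))
  expect_equal(pr$mean, x[1:10])
  # single cycle: mean equals the cycle itself
  one <- segment_cycles(c(1L, 11L), 20L, 50)
  one$cycles <- one$cycles[1, , drop = FALSE]
  p1 <- propagate_segmentation(one, x[1:20])
  expect_equal(p1$mean, x[1:10])
  expect_equal(p1$sd, rep(0, 10))
  # sample SD matches the generating SD for gaussian rows
  set.seed(8)
  n <- 400
  xs <- rnorm(n * 10, 0, 2)
  big <- segment_cycles(seq(1L, by = 10L, length.out = n), n * 10L, 50)
  pb <- propagate_segmentation(big, xs)
  expect_equal(mean(pb$sd), 2, tolerance = 0.05)
  # mismatched time base
  expect_error(propagate_segmentation(cyc, x[1:15]),
               class = "gaitsva_synchronization_error")
})

test_that("stance fraction arithmetic and empty-result error", {
  cyc <- segment_cycles(c(1L, 51L, 101L), 160L, 50)
  cyc$cycles$ic <- cyc$cycles$start + 10L
  cyc$cycles$to <- cyc$cycles$start + 40L
  st <- stance_fraction(cyc)
  expect_equal(st$per_cycle, rep(0.6, 3))
  expect_equal(st$mean, 0.6)
  cyc$cycles$flagged <- TRUE
  expect_error(stance_fraction(cyc), class = "gaitsva_empty_result")
})

test_that("events are recovered within two samples on a synthetic session", {
  sim <- default_sim()
  res <- default_run()
  fs <- 50
  ev <- sim$truth$events
  cyc <- res$cycles$body
  ms_true <- round(ev$ms_time * fs) + 1L
  ms_err <- vapply(ms_true, function(m) min(abs(cyc$ms_indices - m)), numeric(1))
  expect_gte(mean(ms_err <= 2), 0.95)
  m <- vapply(cyc$cycles$start, function(s) which.min(abs(ms_true - s)),
              integer(1))
  ic_true <- round(ev$ic_time * fs) + 1L
  to_true <- round(ev$to_time * fs) + 1L
  expect_gte(mean(abs(cyc$cycles$ic - ic_true[m]) <= 2, na.rm = TRUE), 0.95)
  expect_gte(mean(abs(cyc$cycles$to - to_true[m]) <= 2, na.rm = TRUE), 0.95)
  # recovered stance fraction close to the generator's setting
  expect_lt(abs(stance_fraction(cyc)$mean - 0.6), 0.05)
})
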