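# Gait angle/angular-velocity templates --------------------------------------
#
# The shank template is defined through the medial-lateral angular velocity
# over one gait cycle (phase 0 = mid-swing), as a truncated Fourier series
# (6 harmonics). The coefficients are obtained once per parameter set by an
# equality-constrained ridge least-squares fit to a bump-mixture target:
#
#   * a broad positive swing peak at phase 0 (mid-swing),
#   * negative dips at the initial-contact and toe-off phases,
#   * a mild mid-stance hump.
#
# Constraints: the series AND its zero-phase 3 Hz Butterworth-filtered image
# (whose harmonics are the raw ones scaled by real gains) are stationary at
# exactly the MS, IC and TO phases. This makes the detected filtered gyro
# minima coincide with the ground-truth event phases. The ridge penalty
# weights each harmonic by the angle distortion the reference 3 Hz
# zero-phase filter would inflict on it, keeping the angle trajectory
# concentrated in the filter pass-band.

K_HARMONICS <- 6L

# Fourier evaluation helpers: coefficients cc = (a1, b1, a2, b2, ...) of
# omega(phi) = sum a_k cos(2 pi k phi) + b_k sin(2 pi k phi)   [deg/s]
fourier_omega <- function(tpl, phi) {
  out <- 0
  for (k in seq_len(tpl$K)) {
    out <- out + tpl$cc[2 * k - 1] * cos(2 * pi * k * phi) +
      tpl$cc[2 * k] * sin(2 * pi * k * phi)
  }
  out
}

# theta(phi) = integral of omega dt = d * integral omega dphi  [deg]
# (the medial-lateral rate is d theta/dt)
fourier_theta <- function(tpl, phi, d) {
  out <- 0
  for (k in seq_len(tpl$K)) {
    a <- tpl$cc[2 * k - 1]; b <- tpl$cc[2 * k]
    out <- out + a * sin(2 * pi * k * phi) * d / (2 * pi * k) -
      b * cos(2 * pi * k * phi) * d / (2 * pi * k)
  }
  out
}

shank_template <- function(stance_fraction = 0.6, cycle_duration = 1.25,
                           reference_cutoff = 3, sample_rate = 50,
                           peak = 1, dip = 0.45, kap_ms = 5, kap_d = 18,
                           mid = 0.12) {
  K <- K_HARMONICS
  p_ic <- (1 - stance_fraction) / 2
  p_to <- p_ic + stance_fraction
  phi <- seq(0, 1, length.out = 513)[-513]
  bump <- function(mu, kap) exp(kap * (cos(2 * pi * (phi - mu)) - 1))
  target <- peak * bump(0, kap_ms) - dip * bump(p_ic, kap_d) -
    1.05 * dip * bump(p_to, kap_d) + mid * bump(0.5, 2)
  X <- do.call(cbind, lapply(seq_len(K), function(k)
    cbind(cos(2 * pi * k * phi), sin(2 * pi * k * phi))))
  gains <- vapply(seq_len(K), function(k)
    butter2_filtfilt_gain(k / cycle_duration, reference_cutoff, sample_rate),
    numeric(1))
  dbasis <- function(p, g = rep(1, K)) unlist(lapply(seq_len(K), function(k)
    g[k] * c(-2 * pi * k * sin(2 * pi * k * p), 2 * pi * k * cos(2 * pi * k * p))))
  A <- rbind(dbasis(0), dbasis(p_ic), dbasis(p_to),
             dbasis(0, gains), dbasis(p_ic, gains), dbasis(p_to, gains))
  loss <- 1 - gains
  lam <- (loss * cycle_duration / (2 * pi * seq_len(K)))^2 * 3e5
  L <- diag(rep(lam, each = 2))
  M <- rbind(cbind(crossprod(X) + L, t(A)), cbind(A, matrix(0, 6, 6)))
  cc <- solve(M, c(crossprod(X, target), rep(0, 6)))[seq_len(2 * K)]
  tpl <- list(cc = cc, K = K, p_ic = p_ic, p_to = p_to)
  # normalize so the angle half-range is 1 degree; callers scale by amplitude
  th <- fourier_theta(tpl, phi, cycle_duration)
  tpl$cc <- tpl$cc / ((max(th) - min(th)) / 2)
  tpl$theta_offset <- -mean(fourier_theta(tpl, phi, cycle_duration))
  tpl
}

# Smooth fixed templates for the thigh and waist angles (unit half-range).
# The thigh swings once per cycle (hip flexion/extension); the pelvis/waist
# oscillates twice per cycle (once per step) with a small amplitude.
.thigh_halfrange <- local({
  phi <- seq(0, 1, length.out = 4096)
  r <- -sin(2 * pi * phi) + 0.22 * cos(4 * pi * phi - 1.0)
  (max(r) - min(r)) / 2
})
thigh_template_theta <- function(phi) {
  (-sin(2 * pi * phi) + 0.22 * cos(4 * pi * phi - 1.0)) / .thigh_halfrange
}

.waist_halfrange <- local({
  phi <- seq(0, 1, length.out = 4096)
  r <- 0.9 * cos(4 * pi * phi - 0.5) + 0.35 * sin(2 * pi * phi)
  (max(r) - min(r)) / 2
})
waist_template_theta <- function(phi) {
  (0.9 * cos(4 * pi * phi - 0.5) + 0.35 * sin(2 * pi * phi)) / .waist_halfrange
}

# world-frame translational acceleration bump at mid-swing (unit peak),
# zero-mean over the cycle
pivot_bump <- function(phi, kappa = 14) {
  b <- exp(kappa * (cos(2 * pi * phi) - 1))
  b - besselI(kappa, 0, expon.scaled = TRUE)
}
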