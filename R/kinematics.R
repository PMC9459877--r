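#' Gait kinematics parameters
#'
#' Defaults describe comfortable adult walking: 1.25 s gait cycles with a
#' 60 % stance phase, segment-to-vertical angle half-ranges largest at the
#' shank and smallest at the waist, a few percent cycle-to-cycle timing
#' jitter and a slow amplitude drift.
#'
#' @param cycle_duration mean gait-cycle duration in seconds.
#' @param n_cycles number of gait cycles.
#' @param stance_fraction fraction of the cycle between initial contact and
#'   toe-off, in (0, 1).
#' @param amplitude named numeric: segment angle half-ranges in degrees for
#'   `waist`, `thigh`, `lower_shank`. Zero is allowed (standing-like
#'   degenerate gait).
#' @param variability cycle-to-cycle relative SD of cycle duration.
#' @param amplitude_variability relative amplitude of the slow sinusoidal
#'   amplitude modulation.
#' @param sample_rate sampling rate in Hz.
#' @param pivot_accel named numeric, peak world-frame translational
#'   acceleration (in g) of each segment's mounting point at mid-swing.
#'   This models the swing-leg deceleration that dominates shank
#'   accelerometry and gives the mid-swing detection peak.
#' @return A list of class `gait_params`.
#' @export
gait_params <- function(cycle_duration = 1.25, n_cycles = 50,
                        stance_fraction = 0.6,
                        amplitude = c(waist = 5, thigh = 18, lower_shank = 22),
                        variability = 0.02, amplitude_variability = 0.03,
                        sample_rate = 50,
                        pivot_accel = c(waist = 0.25, thigh = 0.55, lower_shank = 1.4)) {
  stopifnot_scalar_pos(cycle_duration, "cycle_duration")
  stopifnot_scalar_pos(sample_rate, "sample_rate")
  if (!is.numeric(n_cycles) || n_cycles < 1)
    gait_stop("`n_cycles` must be >= 1", "gaitsva_invalid_parameter")
  if (!is.numeric(stance_fraction) || stance_fraction <= 0 || stance_fraction >= 1)
    gait_stop("`stance_fraction` must be in (0, 1)", "gaitsva_invalid_parameter")
  amplitude <- amplitude[c("waist", "thigh", "lower_shank")]
  if (anyNA(amplitude) || any(amplitude < 0))
    gait_stop("`amplitude` needs non-negative waist/thigh/lower_shank entries",
              "gaitsva_invalid_parameter")
  if (variability < 0 || amplitude_variability < 0)
    gait_stop("variability parameters must be >= 0", "gaitsva_invalid_parameter")
  structure(list(cycle_duration = cycle_duration, n_cycles = as.integer(n_cycles),
                 stance_fraction = stance_fraction, amplitude = amplitude,
                 variability = variability,
                 amplitude_variability = amplitude_variability,
                 sample_rate = sample_rate, pivot_accel = pivot_accel),
            class = "gait_params")
}

#' Generate ground-truth walking kinematics
#'
#' Builds smooth sagittal segment-to-vertical angle trajectories for the
#' waist, thigh and lower shank over `n_cycles` gait cycles, with embedded
#' ground-truth mid-swing (MS), initial-contact (IC) and toe-off (TO) times.
#' Each cycle starts at MS; by construction the IC-to-TO span equals
#' `stance_fraction * cycle duration`, the shank medial-lateral angular
#' velocity attains its per-cycle maximum magnitude at MS, and it has
#' prominent local minima exactly at IC and TO (preserved under the
#' reference 3 Hz zero-phase low-pass filter).
#'
#' @param params a [gait_params()] list.
#' @param seed integer seed; identical seeds give bitwise identical output.
#' @return An object of class `segment_kinematics`: uniform `time`,
#'   `angles` (data frame with columns `waist`, `thigh`, `lower_shank`,
#'   degrees), `events` (data frame `cycle`, `ms_time`, `ic_time`,
#'   `to_time`, seconds), `stance_fraction`, `sample_rate`, and
#'   `lin_accel`, a per-placement list of world-frame (x, z) translational
#'   accelerations in m/s^2.
#' @export
generate_kinematics <- function(params = gait_params(), seed = 1L) {
  if (!inherits(params, "gait_params")) params <- do.call(gait_params, params)
  withr_seed(seed)
  fs <- params$sample_rate
  dt <- 1 / fs
  nc <- params$n_cycles
  # per-cycle durations with truncated gaussian jitter
  jit <- stats::rnorm(nc, 0, params$variability)
  jit <- pmin(pmax(jit, -3 * params$variability), 3 * params$variability)
  durs <- params$cycle_duration * (1 + jit)
  starts <- cumsum(c(0, durs[-nc]))
  total <- sum(durs)
  n <- floor(total * fs) + 1L
  time <- (seq_len(n) - 1L) * dt
  # phase: piecewise linear within cycles
  cyc <- findInterval(time, c(starts, total), rightmost.closed = TRUE)
  cyc <- pmin(pmax(cyc, 1L), nc)
  phase <- (time - starts[cyc]) / durs[cyc]
  phase <- pmin(pmax(phase, 0), 1)
  # slow amplitude modulation (smooth, identical for all segments)
  f1 <- 0.11 / params$cycle_duration; f2 <- 0.257 / params$cycle_duration
  ph12 <- stats::runif(2, 0, 2 * pi)
  amod <- 1 + params$amplitude_variability *
    (0.6 * sin(2 * pi * f1 * time + ph12[1]) + 0.4 * sin(2 * pi * f2 * time + ph12[2]))

  tpl <- shank_template(params$stance_fraction, params$cycle_duration, sample_rate = fs)
  shank <- (fourier_theta(tpl, phase, params$cycle_duration) + tpl$theta_offset) *
    params$amplitude[["lower_shank"]] * amod
  thigh <- thigh_template_theta(phase) * params$amplitude[["thigh"]] * amod
  waist <- waist_template_theta(phase) * params$amplitude[["waist"]] * amod

  events <- data.frame(
    cycle = seq_len(nc),
    ms_time = starts,
    ic_time = starts + tpl$p_ic * durs,
    to_time = starts + tpl$p_to * durs
  )
  g0 <- 9.80665
  pb <- pivot_bump(phase)
  dir <- c(x = 0.5, z = sqrt(1 - 0.5^2))
  lin <- lapply(params$pivot_accel, function(a)
    cbind(x = a * g0 * dir[["x"]] * pb, z = a * g0 * dir[["z"]] * pb))

  structure(list(time = time,
                 angles = data.frame(waist = waist, thigh = thigh,
                                     lower_shank = shank),
                 events = events,
                 stance_fraction = params$stance_fraction,
                 sample_rate = fs,
                 lin_accel = lin,
                 params = params),
            class = "segment_kinematics")
}

#' @export
print.segment_kinematics <- function(x, ...) {
  cat(sprintf("<segment_kinematics> %d samples @ %g Hz, %d cycles, stance %.0f%%\n",
              length(x$time), x$sample_rate, nrow(x$events),
              100 * x$stance_fraction))
  invisible(x)
}

#' Fabric coupling parameters
#'
#' Linear spring-damper-with-gain model of how a clothing-mounted sensor's
#' angle tracks the underlying body segment, plus band-limited fabric
#' wobble noise. Defaults per placement are calibration choices giving the
#' qualitative behaviour reported for loose trousers: clothing angles with
#' the same cycle shape but a wider range, and waist pairs agreeing less
#' well than thigh or shank pairs.
#'
#' @param stiffness spring constant, 1/s^2 (must be positive and below
#'   `(2 * sample_rate)^2` for the fixed-step integrator).
#' @param damping damping coefficient, 1/s (non-negative).
#' @param gain dimensionless static amplitude ratio clothing/body.
#' @param noise_sd SD in degrees of the additive band-limited fabric noise
#'   during full-speed movement. The noise is motion-modulated: fabric
#'   flutter is driven by segment movement, so the noise amplitude scales
#'   with the (smoothed) body angular speed and vanishes while standing
#'   still.
#' @param noise_cutoff bandwidth of the fabric noise in Hz.
#' @return A list of class `fabric_coupling`.
#' @export
fabric_coupling <- function(stiffness = 350, damping = 10, gain = 1.1,
                            noise_sd = 2, noise_cutoff = 2) {
  stopifnot_scalar_pos(stiffness, "stiffness")
  if (damping < 0) gait_stop("`damping` must be >= 0", "gaitsva_invalid_parameter")
  if (gain < 0) gait_stop("`gain` must be >= 0", "gaitsva_invalid_parameter")
  if (noise_sd < 0) gait_stop("`noise_sd` must be >= 0", "gaitsva_invalid_parameter")
  stopifnot_scalar_pos(noise_cutoff, "noise_cutoff")
  structure(list(stiffness = stiffness, damping = damping, gain = gain,
                 noise_sd = noise_sd, noise_cutoff = noise_cutoff),
            class = "fabric_coupling")
}

#' @rdname fabric_coupling
#' @param placement sensor placement.
#' @export
default_fabric_coupling <- function(placement = c("waist", "thigh", "lower_shank")) {
  placement <- match.arg(placement)
  # resonance (sqrt(stiffness)) above the gait harmonic band so the cycle
  # shape is preserved; moderate damping; gain > 1 widens the angle range
  switch(placement,
    waist = fabric_coupling(stiffness = 1600, damping = 40, gain = 1.05,
                            noise_sd = 2.4, noise_cutoff = 1.5),
    thigh = fabric_coupling(stiffness = 2000, damping = 45, gain = 1.12,
                            noise_sd = 2.0, noise_cutoff = 2.0),
    lower_shank = fabric_coupling(stiffness = 2500, damping = 50, gain = 1.18,
                                  noise_sd = 1.5, noise_cutoff = 2.5))
}

#' Transform body kinematics into clothing kinematics
#'
#' Integrates the damped second-order tracking system
#' `theta_c'' = -stiffness * (theta_c - gain * theta_b) - damping * theta_c'`
#' with a fixed-step semi-implicit Euler scheme at the sample rate, starting
#' from `theta_c(0) = gain * theta_b(0)` and matched initial velocity, and
#' adds band-limited (6 Hz) fabric noise. Ground-truth event times are
#' copied unchanged from the body kinematics; the shared translational
#' acceleration of the mounting point is kept.
#'
#' @param kin a [segment_kinematics] object (body kinematics).
#' @param coupling a single [fabric_coupling()] applied to all segments, or
#'   a named list with entries `waist`, `thigh`, `lower_shank`.
#' @param seed integer seed for the fabric noise.
#' @return A `segment_kinematics` object with clothing angle trajectories.
#' @export
clothing_transform <- function(kin, coupling = NULL, seed = 1L) {
  stopifnot(inherits(kin, "segment_kinematics"))
  placements <- names(kin$angles)
  if (is.null(coupling))
    coupling <- stats::setNames(lapply(placements, default_fabric_coupling), placements)
  if (inherits(coupling, "fabric_coupling"))
    coupling <- stats::setNames(rep(list(coupling), length(placements)), placements)
  withr_seed(seed)
  dt <- 1 / kin$sample_rate
  out <- kin
  for (p in placements) {
    cp <- coupling[[p]]
    if (!inherits(cp, "fabric_coupling"))
      gait_stop(sprintf("no fabric_coupling supplied for placement '%s'", p),
                "gaitsva_invalid_parameter")
    thb <- kin$angles[[p]]
    n <- length(thb)
    thc <- numeric(n)
    thc[1] <- cp$gain * thb[1]
    v <- if (n > 1) cp$gain * (thb[2] - thb[1]) / dt else 0
    # semi-implicit fixed-step scheme (spring explicit, damping implicit),
    # sub-stepped so omega_n * dtau stays small even for very stiff fabric;
    # the body angle is interpolated linearly across sub-steps
    m <- max(1L, ceiling(dt * sqrt(cp$stiffness) / 0.2))
    dtau <- dt / m
    x <- thc[1]
    for (i in 2:n) {
      b0 <- cp$gain * thb[i - 1]
      db <- cp$gain * (thb[i] - thb[i - 1]) / m
      for (j in seq_len(m)) {
        v <- (v - dtau * cp$stiffness * (x - (b0 + db * (j - 0.5)))) /
          (1 + dtau * cp$damping)
        x <- x + dtau * v
      }
      thc[i] <- x
    }
    if (!all(is.finite(thc)))
      gait_stop(sprintf(
        "fabric integration diverged (placement %s, stiffness %.0f, damping %.1f)",
        p, cp$stiffness, cp$damping), "gaitsva_numerical_failure")
    if (cp$noise_sd > 0) {
      wn <- stats::rnorm(n)
      bl <- lowpass_filter(wn, cutoff = cp$noise_cutoff,
                           sample_rate = kin$sample_rate)
      bl <- bl / stats::sd(bl)
      # fabric flutter is driven by movement: modulate by the smoothed body
      # angular speed (full amplitude above ~30 deg/s)
      rate <- abs(fd_derivative(thb, dt))
      env <- pmin(1, lowpass_filter(rate, cutoff = 1,
                                    sample_rate = kin$sample_rate) / 30)
      env <- pmax(env, 0)
      thc <- thc + bl * env * cp$noise_sd
    }
    out$angles[[p]] <- thc
  }
  out$coupling <- coupling
  out
}

# local seed handling: set the RNG deterministically without touching the
# caller's RNG state
withr_seed <- function(seed) {
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    if (is.na(seed)) gait_stop("`seed` must be an integer", "gaitsva_invalid_parameter")
    set.seed(seed)
  }
  invisible(NULL)
}
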