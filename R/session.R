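#' Multi-sensor session container
#'
#' A synchronized recording from several IMUs plus the activity annotation.
#'
#' @param sensors named list of [imu_series], keyed `placement_attachment`
#'   (e.g. `"lower_shank_body"`). All sensors must share one time base.
#' @param activities data frame with columns `label` (one of `standing`,
#'   `sitting`, `sit_to_stand`, `leg_raise`, `walking`), `start_s`, `end_s`;
#'   intervals must be non-overlapping and within the record.
#' @param metadata list; free-form (subject id, clothing type, ...).
#' @return An object of class `sensor_session`.
#' @export
sensor_session <- function(sensors, activities, metadata = list()) {
  if (!length(sensors)) gait_stop("no sensors", "gaitsva_invalid_parameter")
  t0 <- sensors[[1]]$time
  for (s in sensors) {
    if (!inherits(s, "imu_series"))
      gait_stop("all sensors must be imu_series objects", "gaitsva_invalid_parameter")
    if (length(s$time) != length(t0) || max(abs(s$time - t0)) > 1e-9)
      gait_stop("sensors do not share one time base", "gaitsva_synchronization_error")
  }
  req <- c("label", "start_s", "end_s")
  if (!all(req %in% names(activities)))
    gait_stop("activities need columns label, start_s, end_s", "gaitsva_schema_error")
  act <- activities[order(activities$start_s), , drop = FALSE]
  if (any(act$end_s <= act$start_s) ||
      any(utils::head(act$end_s, -1) > utils::tail(act$start_s, -1) + 1e-9))
    gait_stop("activity intervals must be increasing and non-overlapping",
              "gaitsva_invalid_parameter")
  structure(list(sensors = sensors, activities = act,
                 sample_rate = sensors[[1]]$sample_rate, metadata = metadata),
            class = "sensor_session")
}

#' @export
print.sensor_session <- function(x, ...) {
  cat(sprintf("<sensor_session> %d sensors, %.1f s @ %g Hz\n",
              length(x$sensors), diff(range(x$sensors[[1]]$time)), x$sample_rate))
  cat("  sensors:", paste(names(x$sensors), collapse = ", "), "\n")
  cat("  activities:", paste(sprintf("%s[%.0f-%.0fs]", x$activities$label,
                                     x$activities$start_s, x$activities$end_s),
                             collapse = " "), "\n")
  invisible(x)
}

#' Default recording protocol
#'
#' The study protocol: five activities of about two minutes each --
#' standing still, sitting on a chair, five sit-to-stand cycles, five leg
#' raises, and walking back and forth. Standing anchors the gravity
#' alignment; the dynamic activities excite the sagittal plane for the
#' second alignment rotation.
#'
#' @param walking_cycles if not `NULL`, the walking duration is set so the
#'   segment contains exactly this many full gait cycles (plus ramp-in and
#'   ramp-out).
#' @param durations named numeric of segment durations in seconds.
#' @return Data frame with columns `activity`, `duration`, `n_cycles`.
#' @export
default_protocol <- function(walking_cycles = NULL,
                             durations = c(standing = 120, sitting = 120,
                                           sit_to_stand = 120, leg_raise = 120,
                                           walking = 120)) {
  data.frame(activity = names(durations),
             duration = as.numeric(durations),
             n_cycles = ifelse(names(durations) == "walking" &
                                 !is.null(walking_cycles),
                               walking_cycles %||% NA_real_, NA_real_))
}

# smoothstep: C1 ramp on [0, 1]
smoothstep <- function(u) { u <- pmin(1, pmax(0, u)); u * u * (3 - 2 * u) }

WALK_RAMP_IN <- 2.0   # seconds of ramped pre-gait before the first counted cycle
WALK_RAMP_OUT <- 1.0

# internal: full walking track (angles, lin accel, events) with amplitude
# ramps at both ends so sessions enter and leave walking smoothly from the
# standing pose
build_walking <- function(params, n_cycles, seed) {
  fs <- params$sample_rate; dt <- 1 / fs
  withr_seed(seed)
  jit <- stats::rnorm(n_cycles, 0, params$variability)
  jit <- pmin(pmax(jit, -3 * params$variability), 3 * params$variability)
  durs <- params$cycle_duration * (1 + jit)
  starts <- cumsum(c(0, durs[-n_cycles]))
  core <- sum(durs)
  total <- WALK_RAMP_IN + core + WALK_RAMP_OUT
  n <- ceiling(total * fs)
  time <- (seq_len(n) - 1L) * dt
  tc <- time - WALK_RAMP_IN                     # time since first cycle start
  cyc <- findInterval(tc, c(starts, core), rightmost.closed = TRUE)
  cyc <- pmin(pmax(cyc, 1L), n_cycles)
  phase <- ifelse(tc < 0, (tc / params$cycle_duration) %% 1,
           ifelse(tc >= core, ((tc - core) / params$cycle_duration) %% 1,
                  (tc - starts[cyc]) / durs[cyc]))
  phase <- pmin(pmax(phase, 0), 1)
  ph12 <- stats::runif(2, 0, 2 * pi)
  f1 <- 0.11 / params$cycle_duration; f2 <- 0.257 / params$cycle_duration
  amod <- 1 + params$amplitude_variability *
    (0.6 * sin(2 * pi * f1 * time + ph12[1]) + 0.4 * sin(2 * pi * f2 * time + ph12[2]))
  env <- smoothstep(time / 1.8) * smoothstep((total - time) / WALK_RAMP_OUT)
  scale <- amod * env
  tpl <- shank_template(params$stance_fraction, params$cycle_duration, sample_rate = fs)
  angles <- data.frame(
    waist = waist_template_theta(phase) * params$amplitude[["waist"]] * scale,
    thigh = thigh_template_theta(phase) * params$amplitude[["thigh"]] * scale,
    lower_shank = (fourier_theta(tpl, phase, params$cycle_duration) +
                     tpl$theta_offset) * params$amplitude[["lower_shank"]] * scale
  )
  g0 <- 9.80665
  pb <- pivot_bump(phase) * env
  dirx <- 0.5; dirz <- sqrt(1 - 0.25)
  lin <- lapply(params$pivot_accel, function(a)
    cbind(x = a * g0 * dirx * pb, z = a * g0 * dirz * pb))
  events <- data.frame(cycle = seq_len(n_cycles),
                       ms_time = WALK_RAMP_IN + starts,
                       ic_time = WALK_RAMP_IN + starts + tpl$p_ic * durs,
                       to_time = WALK_RAMP_IN + starts + tpl$p_to * durs)
  list(n = n, angles = angles, lin = lin, events = events, duration = n * dt)
}

# poses in degrees (waist, thigh, lower_shank)
POSE_SIT <- c(waist = 8, thigh = 80, lower_shank = 5)

#' Generate a synthetic six-sensor gait session
#'
#' Simulates a full multi-activity recording from three placements (waist,
#' thigh, lower shank) times two attachments (taped to the body, mounted in
#' clothing), with randomized mounting misorientations, per-sensor gyro
#' bias, sensor noise, and the fabric-coupling model for the clothing
#' sensors. Every non-walking activity starts and ends at the standing
#' pose with zero rate, and walking amplitude ramps in and out, so the
#' assembled angle trajectories are smooth across activity boundaries.
#'
#' @param protocol data frame with columns `activity`, `duration` and
#'   optionally `n_cycles` for walking segments (see [default_protocol()]).
#'   Must contain at least one `standing` and one `walking` segment.
#' @param seed master integer seed; all randomness derives from it.
#' @param gait a [gait_params()] list (its `n_cycles` is overridden by the
#'   protocol).
#' @param noise list with `accel_sd` (g), `gyro_sd` (deg/s),
#'   `gyro_bias_sd` (deg/s; one constant bias per sensor axis is drawn).
#' @param coupling `NULL` for per-placement defaults, or as in
#'   [clothing_transform()].
#' @param mounting_error_body,mounting_error_clothing max mounting
#'   misorientation angle (radians) for body / clothing sensors.
#' @param omit character vector of sensor keys (e.g. `"waist_clothing"`) to
#'   leave out of the session.
#' @param metadata metadata list stored in the session.
#' @return List with elements `session` (a [sensor_session]) and `truth`
#'   (ground-truth kinematics for both attachments, event table, mounting
#'   rotations, gyro biases and the actual activity windows).
#' @export
generate_session <- function(protocol = default_protocol(), seed = 1L,
                             gait = gait_params(),
                             noise = list(accel_sd = 0.02, gyro_sd = 1,
                                          gyro_bias_sd = 0.3),
                             coupling = NULL,
                             mounting_error_body = 10 * pi / 180,
                             mounting_error_clothing = 25 * pi / 180,
                             omit = character(),
                             metadata = list(subject = "S1",
                                             clothing_type = "synthetic loose trousers")) {
  if (!all(c("activity", "duration") %in% names(protocol)))
    gait_stop("protocol needs columns activity, duration", "gaitsva_schema_error")
  if (!"standing" %in% protocol$activity)
    gait_stop("protocol must include a standing segment (required for alignment)",
              "gaitsva_configuration_error")
  if (!"walking" %in% protocol$activity)
    gait_stop("protocol must include a walking segment",
              "gaitsva_configuration_error")
  fs <- gait$sample_rate; dt <- 1 / fs
  seed <- as.integer(seed)

  # assemble per-activity tracks -------------------------------------------
  segs <- vector("list", nrow(protocol))
  events_all <- NULL
  t_cursor <- 0
  for (i in seq_len(nrow(protocol))) {
    act <- protocol$activity[i]
    dur <- protocol$duration[i]
    if (act == "walking") {
      ncyc <- protocol$n_cycles[i] %||% NA_real_
      if (is.null(ncyc) || is.na(ncyc))
        ncyc <- max(1L, floor((dur - WALK_RAMP_IN - WALK_RAMP_OUT) /
                                gait$cycle_duration))
      wk <- build_walking(gait, as.integer(ncyc), seed + 17L * i)
      ev <- wk$events
      ev[c("ms_time", "ic_time", "to_time")] <-
        ev[c("ms_time", "ic_time", "to_time")] + t_cursor
      events_all <- rbind(events_all, ev)
      segs[[i]] <- list(label = act, n = wk$n, angles = wk$angles, lin = wk$lin)
    } else {
      n <- ceiling(dur * fs)
      u <- (seq_len(n) - 1L) / (n - 1L)
      shape <- switch(act,
        standing = rep(0, n),
        sitting = { # settle into the chair, hold, rise again
          down <- smoothstep(u * dur / 2.0)
          up <- smoothstep((1 - u) * dur / 2.0)
          pmin(down, up)
        },
        # five smooth excursion cycles, zero value and rate at the ends
        sit_to_stand = sin(pi * ((5 * u) %% 1))^2,
        leg_raise = sin(pi * ((5 * u) %% 1))^2,
        gait_stop(sprintf("unknown activity '%s'", act), "gaitsva_configuration_error"))
      ang <- switch(act,
        standing = data.frame(waist = shape, thigh = shape, lower_shank = shape),
        sitting = ,
        sit_to_stand = data.frame(waist = POSE_SIT[["waist"]] * shape,
                                  thigh = POSE_SIT[["thigh"]] * shape,
                                  lower_shank = POSE_SIT[["lower_shank"]] * shape),
        leg_raise = data.frame(waist = -4 * shape, thigh = 55 * shape,
                               lower_shank = -25 * shape))
      segs[[i]] <- list(label = act, n = n, angles = ang, lin = NULL)
    }
    segs[[i]]$start <- t_cursor
    t_cursor <- t_cursor + segs[[i]]$n * dt
  }
  n_total <- sum(vapply(segs, function(s) as.integer(s$n), integer(1)))
  time <- (seq_len(n_total) - 1L) * dt
  angles <- do.call(rbind, lapply(segs, `[[`, "angles"))
  rownames(angles) <- NULL
  placements <- c("waist", "thigh", "lower_shank")
  lin <- stats::setNames(lapply(placements, function(p) {
    do.call(rbind, lapply(segs, function(s)
      if (is.null(s$lin)) matrix(0, s$n, 2) else s$lin[[p]]))
  }), placements)
  activities <- data.frame(
    label = vapply(segs, `[[`, character(1), "label"),
    start_s = vapply(segs, `[[`, numeric(1), "start"),
    end_s = vapply(segs, function(s) s$start + s$n * dt, numeric(1)))

  kin_body <- structure(list(time = time, angles = angles,
                             events = events_all,
                             stance_fraction = gait$stance_fraction,
                             sample_rate = fs, lin_accel = lin, params = gait),
                        class = "segment_kinematics")
  kin_clothing <- clothing_transform(kin_body, coupling, seed = seed + 101L)

  # sensors -----------------------------------------------------------------
  withr_seed(seed + 202L)
  sensors <- list(); mountings <- list(); biases <- list()
  idx <- 0L
  for (p in placements) for (a in c("body", "clothing")) {
    idx <- idx + 1L
    key <- paste(p, a, sep = "_")
    max_ang <- if (a == "body") mounting_error_body else mounting_error_clothing
    Rm <- random_rotation(max_ang, min_angle = max_ang / 5)
    bias <- stats::rnorm(3, 0, noise$gyro_bias_sd %||% 0)
    if (key %in% omit) next
    mount <- mounting_spec(p, a, "right", mounting_rotation = Rm)
    kin <- if (a == "body") kin_body else kin_clothing
    sensors[[key]] <- imu_from_kinematics(
      kin, mount,
      noise = list(accel_sd = noise$accel_sd, gyro_sd = noise$gyro_sd,
                   gyro_bias = bias),
      seed = seed * 100L + idx)
    mountings[[key]] <- mount
    biases[[key]] <- bias
  }
  session <- sensor_session(sensors, activities, metadata)
  truth <- list(body = kin_body, clothing = kin_clothing, events = events_all,
                mountings = mountings, gyro_bias = biases,
                coupling = kin_clothing$coupling, activities = activities,
                gait = gait, seed = seed)
  list(session = session, truth = truth)
}
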