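#' Pipeline configuration
#'
#' All tunable parameters of the analysis pipeline with their defaults:
#' 50 Hz sampling, a zero-phase 2nd-order Butterworth low-pass at 3 Hz for
#' the event-detection and reporting streams, mid-swing thresholds of
#' 1.8 g (body) and 2.0 g (clothing) with a 1 s minimum peak separation,
#' and the gated Madgwick orientation settings.
#'
#' @param sample_rate Hz.
#' @param filter_cutoff,filter_order zero-phase Butterworth low-pass.
#' @param ms_threshold_body,ms_threshold_clothing mid-swing detection
#'   thresholds in g.
#' @param ms_min_separation minimum MS peak separation, seconds.
#' @param ms_use_filtered detect MS on the filtered magnitude instead of
#'   the raw one (default `FALSE`: the raw magnitude peaks exactly at
#'   mid-swing, whereas filtering the channels shifts the magnitude peak).
#' @param madgwick_beta gradient step size, rad/s.
#' @param ic_to_prominence minimum gyro-minimum prominence, deg/s.
#' @param quasi_static_window,quasi_static_accel_tol,quasi_static_gyro_tol
#'   gating of Madgwick corrections (seconds, g, deg/s).
#' @param standing_min_duration,dynamic_min_duration minimum usable
#'   segment lengths, seconds.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sample_rate = 50, filter_cutoff = 3,
                            filter_order = 2,
                            ms_threshold_body = 1.8,
                            ms_threshold_clothing = 2.0,
                            ms_min_separation = 1.0,
                            ms_use_filtered = FALSE,
                            madgwick_beta = 0.1,
                            ic_to_prominence = 8,
                            quasi_static_window = 0.5,
                            quasi_static_accel_tol = 0.05,
                            quasi_static_gyro_tol = 15,
                            standing_min_duration = 2,
                            dynamic_min_duration = 5) {
  cfg <- list(sample_rate = sample_rate, filter_cutoff = filter_cutoff,
              filter_order = filter_order,
              ms_threshold_body = ms_threshold_body,
              ms_threshold_clothing = ms_threshold_clothing,
              ms_min_separation = ms_min_separation,
              ms_use_filtered = ms_use_filtered,
              madgwick_beta = madgwick_beta,
              ic_to_prominence = ic_to_prominence,
              quasi_static_window = quasi_static_window,
              quasi_static_accel_tol = quasi_static_accel_tol,
              quasi_static_gyro_tol = quasi_static_gyro_tol,
              standing_min_duration = standing_min_duration,
              dynamic_min_duration = dynamic_min_duration)
  for (nm in setdiff(names(cfg), "ms_use_filtered"))
    stopifnot_scalar_pos(cfg[[nm]], nm)
  if (cfg$filter_cutoff >= cfg$sample_rate / 2)
    gait_stop("filter cutoff must be below the Nyquist frequency",
              "gaitsva_invalid_parameter")
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `read_config()` returns a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

activity_indices <- function(session, labels, time) {
  act <- session$activities[session$activities$label %in% labels, , drop = FALSE]
  idx <- integer(0)
  for (i in seq_len(nrow(act)))
    idx <- c(idx, window_indices(time, act$start_s[i], act$end_s[i]))
  sort(unique(idx))
}

#' Run the full clothing-vs-body gait analysis pipeline
#'
#' Stages, in order: sensor-to-anatomical alignment (gravity rotation from
#' standing, sagittal rotation from the pooled dynamic activities), gyro
#' bias estimation from standing, gated Madgwick orientation and
#' sensor-to-vertical angles, zero-phase low-pass filtering of the
#' detection streams, gait-cycle extraction from the lower-shank sensors
#' (mid-swing acceleration peaks; IC/TO gyro minima), and per-placement
#' clothing-vs-body comparison (per-cycle Pearson correlations and angle
#' differences during standing, at IC and at the shank-vertical instant).
#' Placements without both attachments are reported as absent, not
#' errors. Every stage logs counts via `message()`.
#'
#' @param session a [sensor_session] with at least one standing and one
#'   walking segment.
#' @param config a [pipeline_config()].
#' @return Object of class `gait_analysis`; see [summary.gait_analysis()]
#'   and [comparison_table()].
#' @export
run_pipeline <- function(session, config = pipeline_config()) {
  stopifnot(inherits(session, "sensor_session"))
  if (!"standing" %in% session$activities$label)
    gait_stop("session has no standing segment", "gaitsva_configuration_error")
  if (!"walking" %in% session$activities$label)
    gait_stop("session has no walking segment", "gaitsva_configuration_error")
  time <- session$sensors[[1]]$time
  standing_idx <- activity_indices(session, "standing", time)
  dynamic_idx <- activity_indices(session, c("sit_to_stand", "leg_raise", "walking"),
                                  time)
  walking_idx <- activity_indices(session, "walking", time)

  aligned <- list(); rotations <- list(); sva <- list(); biases <- list()
  filtered_omega <- list(); accel_mag <- list()
  for (key in names(session$sensors)) {
    s <- session$sensors[[key]]
    r1 <- estimate_gravity_rotation(slice_series(s, standing_idx))
    g_aligned <- apply_alignment(s, alignment_rotations(r_gravity = r1))
    r2 <- estimate_sagittal_rotation(
      slice_series(g_aligned, dynamic_idx),
      sign_idx = which(dynamic_idx %in% walking_idx))
    rot <- alignment_rotations(r_gravity = r1, r_sagittal = r2)
    a <- apply_alignment(s, rot)
    bias <- colMeans(a$gyro[standing_idx, , drop = FALSE])
    sfilt <- lowpass_filter(a, cutoff = config$filter_cutoff,
                            order = config$filter_order)
    qs <- madgwick_orientation(
      a, beta = config$madgwick_beta, gyro_bias = bias,
      gate = list(window = config$quasi_static_window,
                  accel_tol = config$quasi_static_accel_tol,
                  gyro_tol = config$quasi_static_gyro_tol))
    sva[[key]] <- sva_series(a$time, sva_from_quaternion(qs),
                             sva_z_from_quaternion(qs),
                             angular_velocity_ml(sfilt),
                             s$placement, s$attachment)
    aligned[[key]] <- a
    rotations[[key]] <- rot
    biases[[key]] <- bias
    filtered_omega[[key]] <- angular_velocity_ml(sfilt)
    accel_mag[[key]] <- if (config$ms_use_filtered) accel_magnitude(sfilt)
                        else accel_magnitude(a)
  }
  message(sprintf("[align] %d sensors aligned; standing %.1f s, dynamic %.1f s",
                  length(aligned), length(standing_idx) / config$sample_rate,
                  length(dynamic_idx) / config$sample_rate))

  # gait cycles per attachment from the lower-shank sensors ------------------
  cycles <- list()
  for (att in c("body", "clothing")) {
    key <- paste0("lower_shank_", att)
    if (!key %in% names(aligned)) next
    thr <- if (att == "body") config$ms_threshold_body else config$ms_threshold_clothing
    mag <- accel_mag[[key]]
    mag_masked <- rep(0, length(mag))
    mag_masked[walking_idx] <- mag[walking_idx]
    ms <- detect_midswing(mag_masked, config$sample_rate, threshold = thr,
                          min_separation = config$ms_min_separation)
    if (length(ms) < 2L) {
      message(sprintf("[segment] %s: %d MS peak(s); cannot segment", att, length(ms)))
      next
    }
    cyc <- segment_cycles(ms, length(mag), config$sample_rate,
                          source_attachment = att)
    cyc <- detect_ic_to(filtered_omega[[key]], cyc,
                        prominence = config$ic_to_prominence)
    cycles[[att]] <- cyc
    message(sprintf(
      "[segment] %s: %d MS peaks, %d cycles of %d samples, %d flagged",
      att, length(ms), nrow(cyc$cycles), cyc$cycle_length, sum(cyc$cycles$flagged)))
  }
  if (is.null(cycles$body))
    gait_stop("no gait cycles could be extracted from the body-mounted shank",
              "gaitsva_cannot_segment")
  ref_cycles <- cycles$body

  # standing window for angle differences (up to 2 min)
  stand2 <- standing_idx[seq_len(min(length(standing_idx),
                                     120 * config$sample_rate))]
  vert_idx <- find_shank_vertical(sva[["lower_shank_body"]]$theta, ref_cycles)

  comparisons <- list()
  for (p in c("waist", "thigh", "lower_shank")) {
    kb <- paste0(p, "_body"); kc <- paste0(p, "_clothing")
    if (!(kb %in% names(sva)) || !(kc %in% names(sva))) {
      comparisons[[p]] <- NULL
      message(sprintf("[compare] %s: pair absent, skipped", p))
      next
    }
    mb <- propagate_segmentation(ref_cycles, sva[[kb]]$theta)
    mc <- propagate_segmentation(ref_cycles, sva[[kc]]$theta)
    pcc <- per_cycle_correlation(mb, mc)
    d_stand <- angle_difference_at(sva[[kb]], sva[[kc]], "standing",
                                   standing_idx = stand2)
    d_ic <- angle_difference_at(sva[[kb]], sva[[kc]], "ic", cycles = ref_cycles)
    d_sv <- angle_difference_at(sva[[kb]], sva[[kc]], "shank_vertical",
                                vertical_idx = vert_idx)
    comparisons[[p]] <- structure(
      list(placement = p, r_per_cycle = pcc$r_per_cycle, r_mean = pcc$r_mean,
           shapiro_p = pcc$shapiro_p, n_cycles = pcc$n_cycles,
           diff_standing = d_stand[c("mean", "sd")],
           diff_ic = d_ic[c("mean", "sd")],
           diff_shank_vertical = d_sv[c("mean", "sd")],
           mean_cycle_body = mb$mean, sd_cycle_body = mb$sd,
           mean_cycle_clothing = mc$mean, sd_cycle_clothing = mc$sd),
      class = "pair_comparison")
    message(sprintf("[compare] %s: mean r = %.3f over %d cycles",
                    p, pcc$r_mean, pcc$n_cycles))
  }

  structure(list(sva = sva, cycles = cycles, comparisons = comparisons,
                 rotations = rotations, gyro_bias = biases,
                 aligned = aligned, vertical_idx = vert_idx,
                 activities = session$activities, metadata = session$metadata,
                 config = config),
            class = "gait_analysis")
}

#' @export
print.pair_comparison <- function(x, ...) {
  cat(sprintf("<pair_comparison> %s: mean r %.3f (n = %d)\n", x$placement,
              x$r_mean, x$n_cycles))
  cat(sprintf("  diff standing %.2f +- %.2f deg | IC %.2f +- %.2f | shank-vertical %.2f +- %.2f\n",
              x$diff_standing$mean, x$diff_standing$sd, x$diff_ic$mean,
              x$diff_ic$sd, x$diff_shank_vertical$mean, x$diff_shank_vertical$sd))
  invisible(x)
}

#' Agreement table for a gait analysis
#'
#' One row per placement with the mean per-cycle correlation and the
#' three angle-difference columns (mean and SD, degrees): standing, at
#' initial contact and at the shank-vertical instant. Absent pairs appear
#' as `NA`.
#'
#' @param analysis a `gait_analysis`.
#' @return A data frame.
#' @export
comparison_table <- function(analysis) {
  stopifnot(inherits(analysis, "gait_analysis"))
  rows <- lapply(c("waist", "thigh", "lower_shank"), function(p) {
    cmp <- analysis$comparisons[[p]]
    if (is.null(cmp))
      return(data.frame(placement = p, n_cycles = NA, corr_coef = NA,
                        standing_mean = NA, standing_sd = NA, ic_mean = NA,
                        ic_sd = NA, shank_vertical_mean = NA,
                        shank_vertical_sd = NA))
    data.frame(placement = p, n_cycles = cmp$n_cycles, corr_coef = cmp$r_mean,
               standing_mean = cmp$diff_standing$mean,
               standing_sd = cmp$diff_standing$sd,
               ic_mean = cmp$diff_ic$mean, ic_sd = cmp$diff_ic$sd,
               shank_vertical_mean = cmp$diff_shank_vertical$mean,
               shank_vertical_sd = cmp$diff_shank_vertical$sd)
  })
  do.call(rbind, rows)
}

#' @export
print.gait_analysis <- function(x, ...) {
  nb <- if (!is.null(x$cycles$body)) nrow(x$cycles$body$cycles) else 0
  cat(sprintf("<gait_analysis> %d sensors, %d gait cycles (body shank)\n",
              length(x$sva), nb))
  for (cmp in x$comparisons) if (!is.null(cmp)) print(cmp)
  invisible(x)
}

#' @export
summary.gait_analysis <- function(object, ...) {
  tab <- comparison_table(object)
  st <- tryCatch(stance_fraction(object$cycles$body), error = function(e) NULL)
  out <- list(table = tab,
              stance_fraction_mean = if (is.null(st)) NA_real_ else st$mean,
              n_cycles_body = nrow(object$cycles$body$cycles),
              n_flagged_body = sum(object$cycles$body$cycles$flagged))
  class(out) <- "summary.gait_analysis"
  out
}

#' @export
print.summary.gait_analysis <- function(x, ...) {
  cat("Clothing vs body sensor agreement (per placement):\n")
  print(x$table, row.names = FALSE, digits = 3)
  cat(sprintf("\nBody-shank cycles: %d (%d flagged); mean stance fraction %.1f%%\n",
              x$n_cycles_body, x$n_flagged_body, 100 * x$stance_fraction_mean))
  invisible(x)
}

#' Plot a gait analysis
#'
#' `type = "mean_cycle"`: mean SVA cycle with an SD band for body and
#' clothing sensors of one placement. `type = "phase_portrait"`: angular
#' velocity against SVA for one cycle, both attachments.
#' `type = "correlation"`: box plots of the per-cycle correlation
#' coefficients per placement.
#'
#' @param x a `gait_analysis`.
#' @param type plot type.
#' @param placement placement for `mean_cycle` / `phase_portrait`.
#' @param cycle cycle row index for `phase_portrait`.
#' @param ... passed to the underlying plotting calls.
#' @export
plot.gait_analysis <- function(x, type = c("mean_cycle", "phase_portrait",
                                           "correlation"),
                               placement = "lower_shank", cycle = 1L, ...) {
  type <- match.arg(type)
  cmp <- x$comparisons[[placement]]
  if (type == "correlation") {
    rs <- lapply(x$comparisons, function(cc) cc$r_per_cycle)
    rs <- rs[!vapply(rs, is.null, logical(1))]
    graphics::boxplot(rs, ylab = "per-cycle Pearson r", ...)
    return(invisible(x))
  }
  if (is.null(cmp)) gait_stop("pair absent for that placement", "gaitsva_empty_result")
  if (type == "mean_cycle") {
    L <- length(cmp$mean_cycle_body)
    phi <- (seq_len(L) - 1) / L * 100
    ylim <- range(cmp$mean_cycle_body - cmp$sd_cycle_body,
                  cmp$mean_cycle_body + cmp$sd_cycle_body,
                  cmp$mean_cycle_clothing - cmp$sd_cycle_clothing,
                  cmp$mean_cycle_clothing + cmp$sd_cycle_clothing)
    graphics::plot(phi, cmp$mean_cycle_body, type = "l", col = "red", lwd = 2,
                   ylim = ylim, xlab = "gait cycle (%)",
                   ylab = "sensor-to-vertical angle (deg)",
                   main = placement, ...)
    graphics::polygon(c(phi, rev(phi)),
                      c(cmp$mean_cycle_body - cmp$sd_cycle_body,
                        rev(cmp$mean_cycle_body + cmp$sd_cycle_body)),
                      col = grDevices::adjustcolor("red", 0.2), border = NA)
    graphics::lines(phi, cmp$mean_cycle_clothing, col = "blue", lwd = 2)
    graphics::polygon(c(phi, rev(phi)),
                      c(cmp$mean_cycle_clothing - cmp$sd_cycle_clothing,
                        rev(cmp$mean_cycle_clothing + cmp$sd_cycle_clothing)),
                      col = grDevices::adjustcolor("blue", 0.2), border = NA)
    graphics::legend("topright", legend = c("body", "clothing"),
                     col = c("red", "blue"), lwd = 2, bty = "n")
  } else {
    ref <- x$cycles$body
    ci <- ref$cycles[cycle, ]
    for (att in c("body", "clothing")) {
      key <- paste0(placement, "_", att)
      pp <- assemble_phase_portrait(x$sva[[key]], ci, ref$cycle_length)
      if (att == "body") plot(pp, ...) else {
        graphics::lines(pp$theta, pp$omega, col = "blue")
      }
    }
  }
  invisible(x)
}
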