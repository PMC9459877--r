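# Session file formats --------------------------------------------------------
#
# A session on disk is a directory:
#   imu.csv        - long format, one row per sample per sensor:
#                    time_s, placement, attachment, side,
#                    ax_g, ay_g, az_g, gx_dps, gy_dps, gz_dps
#   activities.csv - label, start_s, end_s
#   metadata.yml   - sample_rate plus free-form metadata
# Ground truth (from the generator) adds:
#   events.csv     - cycle_index, ms_time, ic_time, to_time
#   mounting.csv   - placement, attachment, r11..r33 (row-major)
# Values are written with 9 decimal digits so write -> read round trips
# are value-identical at that precision.

SESSION_COLUMNS <- c("time_s", "placement", "attachment", "side",
                     "ax_g", "ay_g", "az_g", "gx_dps", "gy_dps", "gz_dps")

fmt9 <- function(x) formatC(x, digits = 9, format = "f")

#' Write / read a sensor session
#'
#' `write_session()` serialises a [sensor_session] to a directory of plain
#' CSV/YAML files; `read_session()` parses one back with strict schema
#' validation (missing columns, non-monotonic time and mixed sample rates
#' are reported as descriptive errors naming the offending file, field or
#' row).
#'
#' @param session a [sensor_session].
#' @param path directory to write to / read from (created if needed).
#' @return `read_session()` returns a [sensor_session]; `write_session()`
#'   returns `path` invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "sensor_session"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(names(session$sensors), function(key) {
    s <- session$sensors[[key]]
    data.frame(time_s = fmt9(s$time), placement = s$placement,
               attachment = s$attachment, side = s$side,
               ax_g = fmt9(s$accel[, 1]), ay_g = fmt9(s$accel[, 2]),
               az_g = fmt9(s$accel[, 3]), gx_dps = fmt9(s$gyro[, 1]),
               gy_dps = fmt9(s$gyro[, 2]), gz_dps = fmt9(s$gyro[, 3]))
  })
  utils::write.csv(do.call(rbind, rows), file.path(path, "imu.csv"),
                   row.names = FALSE, quote = FALSE)
  act <- session$activities
  act$start_s <- fmt9(act$start_s); act$end_s <- fmt9(act$end_s)
  utils::write.csv(act, file.path(path, "activities.csv"),
                   row.names = FALSE, quote = FALSE)
  yaml::write_yaml(c(list(sample_rate = session$sample_rate), session$metadata),
                   file.path(path, "metadata.yml"))
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  imu_file <- file.path(path, "imu.csv")
  act_file <- file.path(path, "activities.csv")
  if (!file.exists(imu_file))
    gait_stop(sprintf("no imu.csv under '%s'", path), "gaitsva_parse_error")
  df <- utils::read.csv(imu_file, stringsAsFactors = FALSE)
  missing <- setdiff(SESSION_COLUMNS, names(df))
  if (length(missing))
    gait_stop(sprintf("imu.csv is missing required column(s): %s",
                      paste(missing, collapse = ", ")), "gaitsva_schema_error")
  if (!file.exists(act_file))
    gait_stop("activities.csv not found", "gaitsva_parse_error")
  act <- utils::read.csv(act_file, stringsAsFactors = FALSE)
  miss2 <- setdiff(c("label", "start_s", "end_s"), names(act))
  if (length(miss2))
    gait_stop(sprintf("activities.csv is missing required column(s): %s",
                      paste(miss2, collapse = ", ")), "gaitsva_schema_error")
  meta_file <- file.path(path, "metadata.yml")
  meta <- if (file.exists(meta_file)) yaml::read_yaml(meta_file) else list()

  key <- paste(df$placement, df$attachment, sep = "_")
  sensors <- list()
  rates <- c()
  for (k in unique(key)) {
    rows <- which(key == k)
    tt <- df$time_s[rows]
    bad <- which(diff(tt) <= 0)
    if (length(bad))
      gait_stop(sprintf(
        "non-monotonic time for sensor %s at imu.csv data row %d (t = %.9f after %.9f)",
        k, rows[bad[1] + 1L], tt[bad[1] + 1L], tt[bad[1]]), "gaitsva_parse_error")
    s <- df[rows, ]
    sensors[[k]] <- imu_series(
      tt, cbind(s$ax_g, s$ay_g, s$az_g), cbind(s$gx_dps, s$gy_dps, s$gz_dps),
      placement = s$placement[1], attachment = s$attachment[1], side = s$side[1])
    rates <- c(rates, sensors[[k]]$sample_rate)
  }
  if (max(rates) - min(rates) > 1e-6 * mean(rates))
    gait_stop(sprintf("mixed sample rates across sensors: %s",
                      paste(sprintf("%.3f", unique(round(rates, 3))), collapse = ", ")),
              "gaitsva_parse_error")
  sensor_session(sensors, act, metadata = meta[setdiff(names(meta), "sample_rate")])
}

#' Write / read synthetic-session ground truth
#'
#' @param truth the `truth` element returned by [generate_session()].
#' @param path directory.
#' @return `read_ground_truth()` returns a list with `events` and
#'   `mountings`.
#' @export
write_ground_truth <- function(truth, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  ev <- truth$events
  utils::write.csv(
    data.frame(cycle_index = ev$cycle, ms_time = fmt9(ev$ms_time),
               ic_time = fmt9(ev$ic_time), to_time = fmt9(ev$to_time)),
    file.path(path, "events.csv"), row.names = FALSE, quote = FALSE)
  mrows <- lapply(names(truth$mountings), function(k) {
    m <- truth$mountings[[k]]
    R <- t(m$mounting_rotation)  # row-major serialisation
    cbind(data.frame(placement = m$placement, attachment = m$attachment),
          stats::setNames(as.data.frame(t(as.vector(R))),
                          c("r11", "r12", "r13", "r21", "r22", "r23",
                            "r31", "r32", "r33")))
  })
  utils::write.csv(do.call(rbind, mrows), file.path(path, "mounting.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  ev <- utils::read.csv(file.path(path, "events.csv"))
  mt <- utils::read.csv(file.path(path, "mounting.csv"))
  rcols <- c("r11", "r12", "r13", "r21", "r22", "r23", "r31", "r32", "r33")
  mountings <- lapply(seq_len(nrow(mt)), function(i) {
    R <- matrix(as.numeric(mt[i, rcols]), 3, 3, byrow = TRUE)
    list(placement = mt$placement[i], attachment = mt$attachment[i],
         mounting_rotation = R)
  })
  names(mountings) <- paste(mt$placement, mt$attachment, sep = "_")
  list(events = data.frame(cycle = ev$cycle_index, ms_time = ev$ms_time,
                           ic_time = ev$ic_time, to_time = ev$to_time),
       mountings = mountings)
}
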