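#' Detect mid-swing peaks in the acceleration magnitude
#'
#' During swing the lower shank briefly experiences accelerations well
#' above 1 g; the per-cycle maximum of the acceleration-magnitude signal
#' marks mid-swing (MS). Local maxima above `threshold` are found, and
#' within any `min_separation` window only the largest is kept (one MS per
#' stride at normal cadence).
#'
#' @param accel_mag numeric vector of per-sample acceleration magnitude
#'   in g.
#' @param sample_rate sampling rate in Hz.
#' @param threshold detection threshold in g; must exceed the 1 g gravity
#'   baseline. Conventional values: 1.8 g for body-mounted and 2.0 g for
#'   clothing-mounted shank sensors.
#' @param min_separation minimum separation between retained peaks in
#'   seconds.
#' @return Integer vector of MS sample indices (sorted, possibly empty).
#' @export
detect_midswing <- function(accel_mag, sample_rate, threshold = 1.8,
                            min_separation = 1.0) {
  if (threshold <= 1)
    gait_stop("`threshold` must exceed the 1 g gravity baseline",
              "gaitsva_invalid_parameter")
  n <- length(accel_mag)
  if (n < 3L) {
    warning("series too short for mid-swing detection; returning no peaks")
    return(integer(0))
  }
  d <- diff(sign(diff(accel_mag)))
  peaks <- which(d < 0 & abs(d) == 2) + 1L
  peaks <- peaks[accel_mag[peaks] > threshold]
  if (!length(peaks)) return(integer(0))
  sep <- min_separation * sample_rate
  keep <- integer(0)
  for (p in peaks[order(-accel_mag[peaks])]) {
    if (!length(keep) || min(abs(keep - p)) >= sep) keep <- c(keep, p)
  }
  sort(keep)
}

#' Cut a series into fixed-length gait cycles at mid-swing points
#'
#' The cycle length is the rounded mean gap between consecutive MS points
#' (one fixed length per record avoids time-normalisation); each MS point
#' starts one cycle, and cycles that would run past the end of the series
#' are dropped. Because every cycle has the same length, windows may
#' overlap slightly or leave small gaps where individual strides deviate
#' from the mean.
#'
#' @param ms_indices integer MS sample indices (at least 2).
#' @param series_length total number of samples available.
#' @param sample_rate sampling rate in Hz.
#' @param source_attachment which attachment the MS indices came from.
#' @return An object of class `gait_cycles`: `ms_indices`, `cycle_length`
#'   (samples), and a data frame `cycles` with columns `start`, `ic`,
#'   `to`, `flagged` (IC/TO filled by [detect_ic_to()]).
#' @export
segment_cycles <- function(ms_indices, series_length, sample_rate,
                           source_attachment = c("body", "clothing")) {
  source_attachment <- match.arg(source_attachment)
  if (length(ms_indices) < 2L)
    gait_stop("need at least 2 mid-swing points to segment cycles",
              "gaitsva_cannot_segment")
  if (is.unsorted(ms_indices, strictly = TRUE))
    gait_stop("`ms_indices` must be strictly increasing", "gaitsva_invalid_parameter")
  L <- as.integer(round(mean(diff(ms_indices))))
  starts <- ms_indices[ms_indices + L - 1L <= series_length]
  structure(list(ms_indices = as.integer(ms_indices), cycle_length = L,
                 cycles = data.frame(start = as.integer(starts),
                                     ic = NA_integer_, to = NA_integer_,
                                     flagged = FALSE),
                 sample_rate = sample_rate,
                 source_attachment = source_attachment),
            class = "gait_cycles")
}

#' @export
print.gait_cycles <- function(x, ...) {
  cat(sprintf("<gait_cycles> %d cycles of %d samples (%s), %d flagged\n",
              nrow(x$cycles), x$cycle_length, x$source_attachment,
              sum(x$cycles$flagged)))
  invisible(x)
}

# local minima of x with prominence >= minprom (prominence measured within
# the supplied window: the smaller of the highest values to either side)
prominent_minima <- function(x, minprom) {
  d <- diff(sign(diff(x)))
  mins <- which(d > 0 & abs(d) == 2) + 1L
  if (!length(mins)) return(integer(0))
  n <- length(x)
  keep <- vapply(mins, function(m) {
    lmax <- max(x[seq_len(m - 1L)])
    rmax <- max(x[(m + 1L):n])
    min(lmax, rmax) - x[m] >= minprom
  }, logical(1))
  mins[keep]
}

#' Locate initial contact and toe-off within each gait cycle
#'
#' IC and TO appear as prominent local minima of the lower-shank
#' medial-lateral gyroscope signal. Within each fixed-length cycle window
#' (which starts at MS), IC is taken as the first prominent minimum after
#' the start and TO as the last prominent minimum before the window end.
#' Cycles without two distinct prominent minima (e.g. flat or monotone
#' windows) are flagged and excluded from downstream statistics rather
#' than raising an error.
#'
#' @param omega numeric vector: the (low-pass filtered) medial-lateral
#'   angular velocity of the lower-shank sensor, deg/s, on the same sample
#'   grid the cycles index into.
#' @param cycles a [gait_cycles] object.
#' @param prominence minimum prominence in deg/s for a gyro minimum to
#'   count.
#' @return The `gait_cycles` object with `ic`, `to` and `flagged` filled.
#' @export
detect_ic_to <- function(omega, cycles, prominence = 8) {
  stopifnot(inherits(cycles, "gait_cycles"))
  L <- cycles$cycle_length
  for (i in seq_len(nrow(cycles$cycles))) {
    s <- cycles$cycles$start[i]
    w <- omega[s:(s + L - 1L)]
    mins <- prominent_minima(w, prominence)
    mins <- mins[mins > 1L & mins < L]
    if (length(mins) < 2L) {
      cycles$cycles$flagged[i] <- TRUE
      next
    }
    cycles$cycles$ic[i] <- s + mins[1L] - 1L
    cycles$cycles$to[i] <- s + mins[length(mins)] - 1L
  }
  cycles
}

#' Cut any synchronized stream into the same gait cycles
#'
#' The waist and thigh sensors are synchronised with the lower-shank
#' sensor, so the shank-derived cycle windows segment them too. Returns
#' the per-cycle matrix together with the pointwise mean and SD across
#' cycles (the mean-cycle band plotted in gait summaries).
#'
#' @param cycles a [gait_cycles] object.
#' @param values numeric vector on the same sample grid (e.g. an SVA
#'   theta series), or an `sva_series` (its `theta` is used).
#' @param include_flagged include flagged cycles in the matrix?
#' @return List with `matrix` (n_cycles x cycle_length), `mean`, `sd` and
#'   `cycle_rows` (row indices into `cycles$cycles`).
#' @export
propagate_segmentation <- function(cycles, values, include_flagged = FALSE) {
  stopifnot(inherits(cycles, "gait_cycles"))
  if (inherits(values, "sva_series")) values <- values$theta
  rows <- which(include_flagged | !cycles$cycles$flagged)
  L <- cycles$cycle_length
  if (any(cycles$cycles$start[rows] + L - 1L > length(values)))
    gait_stop("values series is shorter than the cycle windows: time bases differ",
              "gaitsva_synchronization_error")
  m <- t(vapply(rows, function(i) {
    s <- cycles$cycles$start[i]
    values[s:(s + L - 1L)]
  }, numeric(L)))
  list(matrix = m,
       mean = colMeans(m),
       sd = if (nrow(m) > 1) apply(m, 2, stats::sd) else rep(0, ncol(m)),
       cycle_rows = rows)
}

#' Stance fraction per gait cycle
#'
#' The stance phase spans IC to TO; healthy adult walking spends roughly
#' 60 % of the cycle in stance. Computed as `(to - ic) / cycle_length`
#' for every unflagged cycle.
#'
#' @param cycles a [gait_cycles] object with IC/TO filled.
#' @return List with `per_cycle` (fractions) and `mean`.
#' @export
stance_fraction <- function(cycles) {
  stopifnot(inherits(cycles, "gait_cycles"))
  ok <- !cycles$cycles$flagged & !is.na(cycles$cycles$ic) & !is.na(cycles$cycles$to)
  if (!any(ok))
    gait_stop("no valid cycles with IC/TO available", "gaitsva_empty_result")
  fr <- (cycles$cycles$to[ok] - cycles$cycles$ic[ok]) / cycles$cycle_length
  list(per_cycle = fr, mean = mean(fr))
}
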