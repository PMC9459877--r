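#' Per-cycle Pearson correlation between a sensor pair
#'
#' For every gait cycle, the Pearson correlation between the
#' clothing-mounted and body-mounted sensor-to-vertical angles over the
#' cycle window. A Shapiro-Wilk normality screen of the per-cycle
#' coefficients is computed and reported alongside but never blocks the
#' computation. Cycles with zero variance in either stream have an
#' undefined coefficient and are excluded with a warning.
#'
#' @param sva_body,sva_clothing per-cycle matrices (n_cycles x
#'   cycle_length) from [propagate_segmentation()], sharing dimensions.
#' @return List with `r_per_cycle`, `r_mean`, `n_cycles`,
#'   `shapiro_p` (or `NA` when not computable) and `excluded` (count of
#'   zero-variance cycles).
#' @export
per_cycle_correlation <- function(sva_body, sva_clothing) {
  if (is.list(sva_body) && !is.null(sva_body$matrix)) sva_body <- sva_body$matrix
  if (is.list(sva_clothing) && !is.null(sva_clothing$matrix)) sva_clothing <- sva_clothing$matrix
  if (!all(dim(sva_body) == dim(sva_clothing)))
    gait_stop("per-cycle matrices must share n_cycles and cycle_length",
              "gaitsva_invalid_parameter")
  n <- nrow(sva_body)
  r <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    b <- sva_body[i, ]; cl <- sva_clothing[i, ]
    if (stats::sd(b) == 0 || stats::sd(cl) == 0) next
    r[i] <- stats::cor(b, cl)
  }
  excluded <- sum(is.na(r))
  if (excluded > 0)
    warning(sprintf("%d zero-variance cycle(s) excluded from correlation", excluded))
  r <- r[!is.na(r)]
  sh <- if (length(r) >= 3 && length(r) <= 5000 && stats::sd(r) > 0)
    tryCatch(stats::shapiro.test(r)$p.value, error = function(e) NA_real_)
  else NA_real_
  list(r_per_cycle = r, r_mean = mean(r), n_cycles = length(r),
       shapiro_p = sh, excluded = excluded)
}

#' Clothing-minus-body angle difference at a gait event
#'
#' The SVA difference (clothing minus body) evaluated per sample over a
#' standing window, or per cycle at initial contact, or per cycle at the
#' instant the body-mounted lower-shank sensor passes vertical during
#' stance.
#'
#' @param sva_body,sva_clothing full-length theta series (degrees) for one
#'   sensor pair, or `sva_series` objects.
#' @param event `"standing"`, `"ic"` or `"shank_vertical"`.
#' @param cycles a [gait_cycles] object with IC/TO filled (events `"ic"`
#'   and `"shank_vertical"`).
#' @param standing_idx integer sample indices of the standing window
#'   (event `"standing"`).
#' @param vertical_idx per-cycle absolute sample indices from
#'   [find_shank_vertical()] (event `"shank_vertical"`); `NA` entries are
#'   skipped.
#' @return List with `mean`, `sd` and the individual `values` in degrees.
#' @export
angle_difference_at <- function(sva_body, sva_clothing,
                                event = c("standing", "ic", "shank_vertical"),
                                cycles = NULL, standing_idx = NULL,
                                vertical_idx = NULL) {
  event <- match.arg(event)
  if (inherits(sva_body, "sva_series")) sva_body <- sva_body$theta
  if (inherits(sva_clothing, "sva_series")) sva_clothing <- sva_clothing$theta
  idx <- switch(event,
    standing = {
      if (!length(standing_idx))
        gait_stop("no standing window supplied", "gaitsva_empty_result")
      standing_idx
    },
    ic = {
      if (is.null(cycles))
        gait_stop("`cycles` required for event = 'ic'", "gaitsva_invalid_parameter")
      ic <- cycles$cycles$ic[!cycles$cycles$flagged]
      ic <- ic[!is.na(ic)]
      if (!length(ic)) gait_stop("no IC indices available", "gaitsva_empty_result")
      ic
    },
    shank_vertical = {
      vi <- vertical_idx[!is.na(vertical_idx)]
      if (!length(vi))
        gait_stop("no shank-vertical indices available", "gaitsva_empty_result")
      vi
    })
  vals <- sva_clothing[idx] - sva_body[idx]
  list(mean = mean(vals), sd = if (length(vals) > 1) stats::sd(vals) else 0,
       values = vals)
}

#' Find where the body-mounted shank passes vertical in stance
#'
#' Per cycle, the first sample in \[IC, TO\] where the body-mounted
#' lower-shank SVA crosses 0 degrees (sign change, nearest-sample
#' convention: of the two samples bracketing the crossing, the one with
#' the smaller absolute angle). Cycles whose stance window contains no
#' sign change get `NA` (flagged for downstream exclusion).
#'
#' @param theta_body_shank full-length body-shank theta series, degrees.
#' @param cycles a [gait_cycles] object with IC/TO filled.
#' @return Integer vector (one absolute sample index or `NA` per cycle
#'   row).
#' @export
find_shank_vertical <- function(theta_body_shank, cycles) {
  stopifnot(inherits(cycles, "gait_cycles"))
  out <- rep(NA_integer_, nrow(cycles$cycles))
  for (i in seq_len(nrow(cycles$cycles))) {
    ci <- cycles$cycles[i, ]
    if (ci$flagged || is.na(ci$ic) || is.na(ci$to)) next
    w <- theta_body_shank[ci$ic:ci$to]
    sgn <- sign(w)
    cross <- which(sgn[-1] * sgn[-length(sgn)] <= 0 &
                     (sgn[-1] != 0 | sgn[-length(sgn)] != 0))
    if (!length(cross)) next
    j <- cross[1]
    pick <- if (abs(w[j]) <= abs(w[j + 1])) j else j + 1L
    out[i] <- ci$ic + pick - 1L
  }
  out
}

#' Assemble a phase portrait for one gait cycle
#'
#' The angular velocity plotted against the sensor-to-vertical angle over
#' one cycle traces a closed loop whose shape summarises the gait
#' dynamics; MS, IC and TO are marked. The per-cycle theta and omega
#' ranges are returned so range comparisons between clothing and body
#' sensors (clothing loops are typically wider) can be made directly.
#'
#' @param sva an `sva_series` (or list with `theta` and `omega`).
#' @param cycle one row of `cycles$cycles` (with `start`, `ic`, `to`)
#'   plus the cycle length, or a list with those fields.
#' @param cycle_length window length in samples.
#' @return Object of class `phase_portrait`: `theta`, `omega`, `markers`
#'   (window-relative ms/ic/to indices), `theta_range`, `omega_range`.
#' @export
assemble_phase_portrait <- function(sva, cycle, cycle_length = NULL) {
  if (inherits(cycle, "gait_cycles")) {
    cycle_length <- cycle$cycle_length
    cycle <- cycle$cycles[1, ]
  }
  if (is.null(cycle_length))
    gait_stop("`cycle_length` required", "gaitsva_invalid_parameter")
  s <- cycle$start
  idx <- s:(s + cycle_length - 1L)
  theta <- sva$theta[idx]
  omega <- sva$omega[idx]
  structure(list(
    theta = theta, omega = omega,
    markers = c(ms = 1L,
                ic = if (is.na(cycle$ic)) NA_integer_ else as.integer(cycle$ic - s + 1L),
                to = if (is.na(cycle$to)) NA_integer_ else as.integer(cycle$to - s + 1L)),
    theta_range = diff(range(theta)),
    omega_range = diff(range(omega)),
    placement = sva$placement, attachment = sva$attachment),
    class = "phase_portrait")
}

#' @export
plot.phase_portrait <- function(x, ...) {
  graphics::plot(x$theta, x$omega, type = "l",
                 xlab = "sensor-to-vertical angle (deg)",
                 ylab = "angular velocity (deg/s)",
                 main = sprintf("%s / %s", x$placement, x$attachment), ...)
  mk <- x$markers[!is.na(x$markers)]
  graphics::points(x$theta[mk], x$omega[mk], pch = c(8, 18, 1)[seq_along(mk)],
                   col = c("red", "darkgreen", "blue")[seq_along(mk)], cex = 1.3)
  graphics::legend("topright", legend = names(mk), pch = c(8, 18, 1)[seq_along(mk)],
                   col = c("red", "darkgreen", "blue")[seq_along(mk)], bty = "n")
  invisible(x)
}
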