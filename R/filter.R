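# zero-phase Butterworth filtering -------------------------------------------

# forward-backward IIR pass with odd-reflection padding so that startup
# transients decay inside the pad, not the data
zero_phase <- function(x, b, a, pad) {
  n <- length(x)
  p <- min(pad, n - 1L)
  if (p > 0) {
    head_ext <- 2 * x[1] - x[(p + 1):2]
    tail_ext <- 2 * x[n] - x[(n - 1):(n - p)]
    xe <- c(head_ext, x, tail_ext)
  } else xe <- x
  y <- as.numeric(signal::filter(signal::Arma(b = b, a = a), xe))
  y <- rev(as.numeric(signal::filter(signal::Arma(b = b, a = a), rev(y))))
  y[(p + 1):(p + n)]
}

#' Zero-phase low-pass filter an IMU series
#'
#' Applies a Butterworth low-pass filter forwards and backwards (so the net
#' phase shift is zero) independently to every accelerometer and gyroscope
#' channel. The default 3 Hz cut-off at 50 Hz sampling retains the gait
#' band while suppressing sensor noise and impact ringing. The DC gain is
#' exactly 1, so constant signals pass unchanged. Edges are handled by
#' odd-reflection padding (1 s worth of samples) so startup transients decay
#' outside the data.
#'
#' @param series an [imu_series], or a plain numeric vector.
#' @param cutoff low-pass cut-off frequency in Hz; must be below the
#'   Nyquist frequency.
#' @param order Butterworth filter order (applied twice, forward and
#'   backward, so the effective attenuation is the squared magnitude
#'   response).
#' @param sample_rate sampling rate in Hz; taken from `series` when it is an
#'   [imu_series].
#' @return An object of the same type as `series`, filtered per channel.
#' @export
lowpass_filter <- function(series, cutoff = 3, order = 2, sample_rate = NULL) {
  if (inherits(series, "imu_series")) sample_rate <- series$sample_rate
  if (is.null(sample_rate))
    gait_stop("`sample_rate` is required for plain numeric input", "gaitsva_invalid_parameter")
  stopifnot_scalar_pos(cutoff, "cutoff")
  if (cutoff >= sample_rate / 2)
    gait_stop("`cutoff` must be below the Nyquist frequency", "gaitsva_invalid_parameter")
  bf <- signal::butter(order, cutoff / (sample_rate / 2), type = "low")
  pad <- as.integer(round(sample_rate))
  n <- if (inherits(series, "imu_series")) nrow(series$accel) else length(series)
  if (n <= 6L * order)
    gait_stop("series too short for stable zero-phase filtering", "gaitsva_insufficient_data")
  ff <- function(x) zero_phase(x, bf$b, bf$a, pad)
  if (inherits(series, "imu_series")) {
    series$accel <- apply(series$accel, 2, ff)
    series$gyro <- apply(series$gyro, 2, ff)
    series
  } else {
    ff(series)
  }
}

# exact forward-backward gain of the digital (bilinear-transform) Butterworth
# at frequency f: the analog magnitude evaluated at the prewarped frequency,
#   |H|^2 = 1 / (1 + (tan(pi f / fs) / tan(pi fc / fs))^(2*order))
butter2_filtfilt_gain <- function(f, cutoff = 3, sample_rate = 50, order = 2) {
  ratio <- tan(pi * f / sample_rate) / tan(pi * cutoff / sample_rate)
  1 / (1 + ratio^(2 * order))
}
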