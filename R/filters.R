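#' Resample a channel to a new rate
#'
#' IMU channels are resampled to 1 kHz so they can be analysed on the same
#' grid as the electro-goniometers. When downsampling, an 8th-order zero-phase
#' Butterworth anti-alias filter at 0.45 times the new rate is applied first;
#' the signal is then evaluated on the new time grid by cubic-spline
#' interpolation. Units, axis and start time are preserved, and duration is
#' preserved within one sample period.
#'
#' @param channel A [signal_channel()].
#' @param target_rate New rate in Hz (> 0).
#' @return A [signal_channel()] at `target_rate`.
#' @examples
#' ch <- signal_channel(sin(2 * pi * seq(0, 2, by = 5e-4)), rate = 2000)
#' resample_signal(ch, 1000)
#' @export
resample_signal <- function(channel, target_rate) {
  stopifnot(inherits(channel, "signal_channel"))
  if (!is.numeric(target_rate) || length(target_rate) != 1L || target_rate <= 0) {
    abort("`target_rate` must be a single positive number (Hz).",
          class = "pigait_error_parameter")
  }
  if (isTRUE(all.equal(target_rate, channel$rate))) {
    return(channel)
  }
  n <- length(channel$samples)
  t_old <- (seq_len(n) - 1L) / channel$rate
  n_out <- max(1L, floor((n - 1L) * target_rate / channel$rate) + 1L)
  t_new <- pmin((seq_len(n_out) - 1L) / target_rate, t_old[n])
  x <- channel$samples
  if (target_rate < channel$rate && n >= 4L) {
    # 0.45 * target_rate is always below the original Nyquist here
    x <- butterworth_lowpass(channel, order = 8,
                             cutoff_hz = 0.45 * target_rate)$samples
  }
  y <- if (n < 4L) {
    approx(t_old, x, xout = t_new, rule = 2)$y
  } else {
    spline(t_old, x, xout = t_new, method = "fmm")$y
  }
  channel_like(channel, y, rate = target_rate)
}

#' Savitzky-Golay smoothing of a channel
#'
#' Local least-squares polynomial smoothing of the raw angular acceleration,
#' with the window specified as a frame duration so the same smoothing scale
#' applies at any sampling rate. The window length in samples,
#' `round(frame_seconds * rate)`, is forced to the nearest odd integer (a
#' parity requirement of the algorithm); defaults are a 3rd-order polynomial
#' over a 0.051 s frame, i.e. 103 samples at 2 kHz and 51 at 1 kHz.
#'
#' @param channel A [signal_channel()].
#' @param poly_order Polynomial order (default 3).
#' @param frame_seconds Frame duration in seconds (default 0.051).
#' @return The smoothed [signal_channel()]; units and axis unchanged.
#' @export
savgol_filter <- function(channel, poly_order = 3, frame_seconds = 0.051) {
  stopifnot(inherits(channel, "signal_channel"))
  win <- round(frame_seconds * channel$rate)
  if (win %% 2 == 0) win <- win + 1L
  win <- as.integer(win)
  if (win <= poly_order) {
    abort(sprintf(
      "Savitzky-Golay window (%d samples) must exceed the polynomial order (%d).",
      win, poly_order), class = "pigait_error_parameter")
  }
  if (length(channel$samples) < win) {
    abort("Channel shorter than one Savitzky-Golay frame.",
          class = "pigait_error_parameter")
  }
  y <- signal::sgolayfilt(channel$samples, p = poly_order, n = win)
  channel_like(channel, y)
}

#' Zero-phase Butterworth low-pass filter
#'
#' Removes marker-vibration artefacts above the locomotor band. The filter is
#' applied forward and backward ([signal::filtfilt()]) so event timing (gait
#' extrema) is not biased by filter lag; `order` is the per-pass design order.
#' The input is extended by odd reflection at both ends before filtering so
#' that start-up transients fall in the discarded padding rather than in the
#' data. Defaults: 4th order, 10 Hz cut-off.
#'
#' @param channel A [signal_channel()].
#' @param order Per-pass filter order (default 4).
#' @param cutoff_hz Cut-off frequency in Hz; must be below Nyquist.
#' @return The filtered [signal_channel()]; units and axis unchanged.
#' @export
butterworth_lowpass <- function(channel, order = 4, cutoff_hz = 10) {
  stopifnot(inherits(channel, "signal_channel"))
  nyq <- channel$rate / 2
  if (!is.numeric(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= nyq) {
    abort(sprintf("`cutoff_hz` must lie in (0, %g) Hz for a %g Hz channel.",
                  nyq, channel$rate), class = "pigait_error_parameter")
  }
  bf <- signal::butter(order, cutoff_hz / nyq, type = "low")
  x <- channel$samples
  n <- length(x)
  # odd-reflection padding long enough for the impulse response to settle
  pad <- min(n - 1L, as.integer(12 * ceiling(channel$rate / cutoff_hz)))
  if (pad > 0L) {
    left <- 2 * x[1L] - x[seq(pad + 1L, 2L)]
    right <- 2 * x[n] - x[seq(n - 1L, n - pad)]
    y <- signal::filtfilt(bf, c(left, x, right))
    y <- y[seq(pad + 1L, pad + n)]
  } else {
    y <- signal::filtfilt(bf, x)
  }
  channel_like(channel, y)
}
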