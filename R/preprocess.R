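#' Condition a raw sEMG trace
#'
#' Standard sEMG conditioning: a 4th-order Butterworth band-pass (default
#' 10-400 Hz) followed by a second-order IIR notch (default 50 Hz, Q = 30),
#' both applied forward-backward so the net filter is zero-phase and window
#' times stay aligned with the raw recording. The input is extended by
#' odd-symmetric (anti-symmetric) padding of three filter lengths before
#' filtering to suppress edge transients.
#'
#' @param trace An [emg_trace].
#' @param band_low,band_high Band-pass corner frequencies in Hz.
#' @param notch Notch centre frequency in Hz (set `NA` to disable).
#' @param notch_q Notch quality factor (centre / -3 dB width).
#' @return The conditioned [emg_trace] (same length, fs and t0).
#' @examples
#' tr <- synth_emg(synth_spec(duration_s = 5, seed = 1))$trace
#' cd <- condition(tr)
#' @export
condition <- function(trace, band_low = 10, band_high = 400, notch = 50,
                      notch_q = 30) {
  stopifnot(inherits(trace, "emg_trace"))
  fs <- trace$fs
  nyq <- fs / 2
  if (!(band_low > 0 && band_low < band_high && band_high < nyq)) {
    stop(sprintf("band [%g, %g] Hz must satisfy 0 < low < high < fs/2 = %g",
                 band_low, band_high, nyq), call. = FALSE)
  }
  if (!is.na(notch) && !(notch > 0 && notch < nyq)) {
    stop(sprintf("notch %g Hz must lie in (0, fs/2 = %g)", notch, nyq),
         call. = FALSE)
  }

  bp <- signal::butter(4, c(band_low, band_high) / nyq, type = "pass")
  filts <- list(bp)
  if (!is.na(notch)) filts <- c(filts, list(design_notch(notch, fs, notch_q)))

  flen <- max(vapply(filts, function(f) max(length(f$b), length(f$a)),
                     numeric(1)))
  # padding must cover the impulse-response settling of the slowest pole:
  # the low band edge (~3 periods) and the notch ring-down (~3 * 2Q/w0)
  pad <- as.integer(max(3 * flen, ceiling(3 * fs / band_low),
                        if (!is.na(notch)) ceiling(3 * notch_q * fs /
                                                     (pi * notch)) else 0))
  x <- trace$samples
  if (length(x) <= pad) {
    stop(sprintf("input too short: %d samples but filter warm-up needs > %d",
                 length(x), pad), call. = FALSE)
  }

  # odd-symmetric extension about each end point
  left <- 2 * x[1] - x[seq(pad + 1, 2)]
  right <- 2 * x[length(x)] - x[seq(length(x) - 1, length(x) - pad)]
  xe <- c(left, x, right)
  for (f in filts) xe <- signal::filtfilt(f, xe)
  y <- xe[(pad + 1):(pad + length(x))]
  emg_trace(y, fs = fs, t0 = trace$t0)
}

# Second-order IIR notch (constrained biquad, standard audio-EQ cookbook
# form): unit gain away from f0, zero at f0, -3 dB width f0/Q.
design_notch <- function(f0, fs, Q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  signal::Arma(b = b / a[1], a = a / a[1])
}
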