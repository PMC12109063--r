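#' Uniformly sampled voltage trace
#'
#' `emg_trace()` wraps a numeric vector of voltage samples with its sampling
#' rate and start time. All pipeline stages consume and return this class.
#'
#' @param samples Numeric vector of voltages (V). Must be finite and of
#'   length at least 2.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param t0 Start time of the first sample in seconds.
#'
#' @return An object of class `emg_trace`: a list with elements `samples`,
#'   `fs`, `t0`.
#' @examples
#' tr <- emg_trace(sin(2 * pi * 50 * (0:999) / 1000), fs = 1000)
#' print(tr)
#' @export
emg_trace <- function(samples, fs, t0 = 0) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) {
    stop("'samples' must contain at least 2 values", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("'samples' contains non-finite values", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("'fs' must be a positive finite scalar (Hz)", call. = FALSE)
  }
  structure(list(samples = samples, fs = as.numeric(fs), t0 = as.numeric(t0)),
            class = "emg_trace")
}

#' @export
print.emg_trace <- function(x, ...) {
  dur <- length(x$samples) / x$fs
  cat(sprintf("<emg_trace> %d samples @ %g Hz (%.3f s), t0 = %g s\n",
              length(x$samples), x$fs, dur, x$t0))
  cat(sprintf("  range [%.4g, %.4g] V, RMS %.4g V\n",
              min(x$samples), max(x$samples), sqrt(mean(x$samples^2))))
  invisible(x)
}

#' @export
length.emg_trace <- function(x) length(x$samples)

#' Sample times of a trace
#'
#' @param trace An [emg_trace].
#' @return Numeric vector of sample times in seconds.
#' @export
trace_times <- function(trace) {
  stopifnot(inherits(trace, "emg_trace"))
  trace$t0 + (seq_along(trace$samples) - 1) / trace$fs
}

duration_s <- function(trace) length(trace$samples) / trace$fs
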