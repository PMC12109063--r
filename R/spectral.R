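#' Split a trace into sliding analysis windows
#'
#' Windows of `window_ms` milliseconds advance by `step_ms`; trailing samples
#' that do not fill a complete window are dropped (padding would bias the
#' terminal median frequency). The defaults - 10,240 ms windows with 2,560 ms
#' steps - trade frequency resolution (~0.1 Hz at 2 kHz) against temporal
#' granularity of the fatigue track.
#'
#' @param trace An [emg_trace].
#' @param window_ms,step_ms Window length and hop, in milliseconds.
#' @return List of segments, each a list with `samples` and `center_s` (the
#'   window-centre time). The count is
#'   `floor((len_ms - window_ms)/step_ms) + 1`.
#' @export
window_segments <- function(trace, window_ms = 10240, step_ms = 2560) {
  stopifnot(inherits(trace, "emg_trace"))
  if (window_ms <= 0 || step_ms <= 0) {
    stop("window_ms and step_ms must be positive", call. = FALSE)
  }
  fs <- trace$fs
  n <- length(trace$samples)
  win_n <- round(window_ms / 1000 * fs)
  step_n <- round(step_ms / 1000 * fs)
  if (n < win_n) {
    stop(sprintf("input too short: %.0f ms available but one window needs %.0f ms",
                 n / fs * 1000, window_ms), call. = FALSE)
  }
  count <- floor((n - win_n) / step_n) + 1
  lapply(seq_len(count) - 1L, function(k) {
    i0 <- k * step_n + 1L
    list(samples = trace$samples[i0:(i0 + win_n - 1L)],
         center_s = trace$t0 + (window_ms / 2 + k * step_ms) / 1000)
  })
}

#' One-sided power spectral density of a segment
#'
#' Single Hann-tapered, mean-detrended periodogram by default (one frame per
#' window, staying closest to a plain short-time Fourier transform of the
#' window); `segments > 1` averages the periodograms of that many
#' non-overlapping sub-frames (Welch), trading frequency resolution for
#' reduced bin-to-bin scatter. The normalisation is taper-corrected so that
#' `sum(power) * df` recovers the tapered segment's power exactly.
#'
#' @param x Numeric segment (>= 16 samples) or [emg_trace].
#' @param fs Sampling rate in Hz (ignored when `x` is a trace).
#' @param segments Number of non-overlapping Welch sub-frames (default 1,
#'   i.e. a single periodogram).
#' @return Object of class `emg_spectrum`: list with `freqs` (Hz, uniform
#'   grid from 0 to fs/2), `power` (PSD, V^2/Hz) and `degenerate` (TRUE for
#'   an all-zero segment).
#' @export
psd <- function(x, fs = NULL, segments = 1L) {
  if (inherits(x, "emg_trace")) {
    fs <- x$fs
    x <- x$samples
  }
  x <- as.numeric(x)
  if (is.null(fs)) stop("'fs' required when 'x' is not an emg_trace", call. = FALSE)
  n <- length(x)
  segments <- as.integer(segments)
  if (segments < 1L) stop("'segments' must be >= 1", call. = FALSE)
  if (n < 16L * segments) {
    stop(sprintf("segment too short for a PSD (< %d samples)", 16L * segments),
         call. = FALSE)
  }
  if (segments > 1L) {
    sub_n <- n %/% segments
    specs <- lapply(seq_len(segments) - 1L, function(k) {
      periodogram_hann(x[(k * sub_n + 1):((k + 1) * sub_n)], fs)
    })
    p <- Reduce(`+`, lapply(specs, `[[`, "power")) / segments
    return(structure(list(freqs = specs[[1]]$freqs, power = p,
                          degenerate = all(vapply(specs, `[[`, logical(1),
                                                  "degenerate"))),
                     class = "emg_spectrum"))
  }
  structure(periodogram_hann(x, fs), class = "emg_spectrum")
}

periodogram_hann <- function(x, fs) {
  n <- length(x)
  xd <- x - mean(x)
  degenerate <- all(xd == 0)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)
  X <- fft(xd * w)
  nhalf <- floor(n / 2)
  scale <- 1 / (fs * sum(w^2))
  p <- 2 * Mod(X[seq_len(nhalf + 1)])^2 * scale
  p[1] <- p[1] / 2
  if (n %% 2 == 0) p[nhalf + 1] <- p[nhalf + 1] / 2
  list(freqs = (0:nhalf) * fs / n, power = p, degenerate = degenerate)
}

#' Median frequency of a power spectrum
#'
#' The frequency splitting the spectrum into equal-energy halves. Each bin's
#' power is treated as spread uniformly over its width, and the half-energy
#' point is located by linear interpolation within the straddling bin, so MF
#' is not quantised to the bin grid.
#'
#' @param spectrum An `emg_spectrum` from [psd()], or any list with uniform
#'   increasing `freqs` (Hz) and non-negative `power`.
#' @return Median frequency in Hz.
#' @examples
#' median_frequency(list(freqs = 0:100, power = rep(1, 101)))  # 50 Hz
#' @export
median_frequency <- function(spectrum) {
  f <- spectrum$freqs
  p <- spectrum$power
  if (length(f) != length(p) || length(f) < 2L) {
    stop("spectrum must have matching freqs/power of length >= 2", call. = FALSE)
  }
  df <- diff(f)
  if (any(df <= 0) || diff(range(df)) > 1e-9 * df[1]) {
    stop("spectrum frequency grid must be uniform and increasing", call. = FALSE)
  }
  if (any(p < 0)) stop("spectral power must be non-negative", call. = FALSE)
  total <- sum(p)
  if (!is.finite(total) || total <= 0 || isTRUE(spectrum$degenerate)) {
    stop("degenerate spectrum: total power is zero", call. = FALSE)
  }
  df <- df[1]
  cum <- cumsum(p)
  half <- total / 2
  k <- which(cum >= half)[1]
  prev <- if (k > 1) cum[k - 1] else 0
  mf <- (f[k] - df / 2) + (half - prev) / p[k] * df
  max(mf, 0)
}

#' Windowed median-frequency series
#'
#' Applies [window_segments()], [psd()] and [median_frequency()] to a signal
#' component - in the fatigue pipeline, IMF1 of the EEMD - yielding the MF
#' track that the linear fatigue fit consumes.
#'
#' @param x An [emg_trace] or numeric vector.
#' @param fs Sampling rate in Hz (ignored when `x` is a trace).
#' @param window_ms,step_ms Passed to [window_segments()].
#' @return Object of class `mf_series`: a data.frame with columns `time_s`
#'   (window centres) and `mf_hz`, plus `window_ms`/`step_ms` attributes.
#' @export
mf_series <- function(x, fs = NULL, window_ms = 10240, step_ms = 2560) {
  if (!inherits(x, "emg_trace")) {
    if (is.null(fs)) stop("'fs' required when 'x' is not an emg_trace", call. = FALSE)
    x <- emg_trace(x, fs = fs)
  }
  segs <- window_segments(x, window_ms = window_ms, step_ms = step_ms)
  mf <- vapply(segs, function(s) median_frequency(psd(s$samples, fs = x$fs)),
               numeric(1))
  out <- data.frame(time_s = vapply(segs, `[[`, numeric(1), "center_s"),
                    mf_hz = mf)
  attr(out, "window_ms") <- window_ms
  attr(out, "step_ms") <- step_ms
  attr(out, "fs") <- x$fs
  class(out) <- c("mf_series", "data.frame")
  out
}

#' First-versus-last cycles spectral shift
#'
#' Compares unit-area spectra of the first and last `n_cycles` contraction
#' cycles of a session. Progressive fatigue moves power down-band, so the
#' fraction of power below `split_hz` grows from the first to the last
#' cycles.
#'
#' @param trace An [emg_trace].
#' @param cycle_s Contraction-cycle period in seconds.
#' @param n_cycles Number of cycles in each comparison block.
#' @param split_hz Boundary between the "low" and "high" bands, in Hz.
#' @return Object of class `spectral_shift`: list with `first` and `last`
#'   (unit-area `emg_spectrum` objects) and `low_band_fraction_delta` (the
#'   low-band power fraction of the last block minus the first block's).
#' @export
spectral_shift <- function(trace, cycle_s = 4, n_cycles = 2, split_hz = 60) {
  stopifnot(inherits(trace, "emg_trace"))
  fs <- trace$fs
  seg_n <- round(n_cycles * cycle_s * fs)
  n <- length(trace$samples)
  if (n < 2 * seg_n) {
    stop(sprintf("input too short: need >= %d samples (2 x %d cycles of %g s)",
                 2 * seg_n, n_cycles, cycle_s), call. = FALSE)
  }
  norm_psd <- function(seg) {
    sp <- psd(seg, fs = fs)
    area <- sum(sp$power) * (sp$freqs[2] - sp$freqs[1])
    if (area <= 0) stop("degenerate spectrum in spectral_shift", call. = FALSE)
    sp$power <- sp$power / area
    sp
  }
  first <- norm_psd(trace$samples[seq_len(seg_n)])
  last <- norm_psd(trace$samples[(n - seg_n + 1):n])
  low_frac <- function(sp) {
    df <- sp$freqs[2] - sp$freqs[1]
    sum(sp$power[sp$freqs < split_hz]) * df
  }
  structure(list(first = first, last = last,
                 low_band_fraction_delta = low_frac(last) - low_frac(first),
                 split_hz = split_hz),
            class = "spectral_shift")
}

#' @export
print.spectral_shift <- function(x, ...) {
  cat(sprintf("<spectral_shift> low-band (< %g Hz) fraction delta: %+.4f\n",
              x$split_hz, x$low_band_fraction_delta))
  invisible(x)
}

#' @export
print.mf_series <- function(x, ...) {
  cat(sprintf("<mf_series> %d windows (%g ms / %g ms), MF %.1f -> %.1f Hz\n",
              nrow(x), attr(x, "window_ms"), attr(x, "step_ms"),
              x$mf_hz[1], x$mf_hz[nrow(x)]))
  invisible(x)
}
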