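#' Empirical mode decomposition
#'
#' Decomposes a trace into intrinsic mode functions (IMFs) by sifting:
#' upper/lower envelopes are natural cubic splines through the local
#' maxima/minima (two extrema mirrored beyond each end to tame boundary
#' swings), the envelope mean is subtracted, and sifting stops on the Cauchy
#' standard-deviation criterion (`sift_sd_tol`) or at the `max_sifts` cap,
#' after which the component satisfies the IMF shape condition approximately
#' (extrema and zero-crossing counts nearly equal, alternating around a
#' near-zero local mean). Extraction stops when the residue has fewer than three
#' extrema or `max_imfs` is reached. IMF1 is the highest-frequency component;
#' the decomposition is exactly complete: `rowSums(imfs) + residue`
#' reconstructs the input to floating-point accuracy.
#'
#' @param trace An [emg_trace] (or numeric vector, taken at `fs = 1`).
#' @param max_imfs Maximum number of IMFs to extract.
#' @param sift_sd_tol Cauchy criterion tolerance for stopping a sift.
#' @param max_sifts Cap on sifting iterations per IMF.
#' @return An object of class `imf_set`: list with `imfs` (numeric matrix,
#'   one column per IMF), `residue`, `fs`, and `meta` (parameters used).
#'   A monotone input yields zero IMFs and `residue == input`.
#' @examples
#' tr <- emg_trace(sin(2 * pi * 5 * (0:999) / 500), fs = 500)
#' d <- emd(tr)
#' ncol(d$imfs)
#' @export
emd <- function(trace, max_imfs = 8, sift_sd_tol = 0.2, max_sifts = 50) {
  x <- as_samples(trace)
  fs <- if (inherits(trace, "emg_trace")) trace$fs else 1
  if (!all(is.finite(x))) stop("input contains non-finite samples", call. = FALSE)
  if (length(x) < 8L) stop("input too short for EMD (< 8 samples)", call. = FALSE)
  res <- .emd_cpp(x, as.integer(max_imfs), sift_sd_tol, as.integer(max_sifts))
  new_imf_set(res$imfs, res$residue, fs,
              meta = list(method = "emd", max_imfs = max_imfs,
                          sift_sd_tol = sift_sd_tol, max_sifts = max_sifts))
}

#' Ensemble empirical mode decomposition
#'
#' EMD averaged over an ensemble of white-noise-perturbed copies of the
#' input: realization m decomposes `x + noise_ratio * sd(x) * w_m`, and the
#' j-th EEMD component is the ensemble mean of the j-th IMFs (realizations
#' producing fewer IMFs contribute zeros for the missing components; residues
#' are averaged likewise). Uncorrelated noise cancels in the mean, which
#' suppresses mode mixing; the reconstruction defect `sum(IMFs) + residue -
#' x` equals the mean of the added noises and shrinks as the ensemble grows.
#' Noise for realization m is drawn from seed `seed + m - 1`, so enlarging
#' the ensemble never reshuffles earlier realizations.
#'
#' @inheritParams emd
#' @param ensemble_size Number of noise realizations (>= 1).
#' @param noise_ratio Noise amplitude as a fraction of the input's standard
#'   deviation. With `noise_ratio = 0` and `ensemble_size = 1` the result
#'   equals [emd()] exactly.
#' @param seed Integer master seed (kept below 2^31 together with the
#'   ensemble offset).
#' @return An `imf_set`, as for [emd()].
#' @export
eemd <- function(trace, ensemble_size = 100, noise_ratio = 0.2, seed = 1L,
                 max_imfs = 8, sift_sd_tol = 0.2, max_sifts = 50) {
  x <- as_samples(trace)
  fs <- if (inherits(trace, "emg_trace")) trace$fs else 1
  if (!all(is.finite(x))) stop("input contains non-finite samples", call. = FALSE)
  if (ensemble_size < 1) stop("'ensemble_size' must be >= 1", call. = FALSE)
  if (noise_ratio < 0) stop("'noise_ratio' must be >= 0", call. = FALSE)
  seed <- as.integer(seed)
  if (seed + ensemble_size >= 2^31) stop("seed too large", call. = FALSE)

  n <- length(x)
  amp <- noise_ratio * sd(x)
  acc <- matrix(0, n, as.integer(max_imfs))
  acc_res <- numeric(n)
  for (m in seq_len(ensemble_size)) {
    if (amp > 0) {
      set.seed(seed + m - 1L)
      xm <- x + amp * rnorm(n)
    } else {
      xm <- x
    }
    dm <- .emd_cpp(xm, as.integer(max_imfs), sift_sd_tol,
                   as.integer(max_sifts))
    k <- ncol(dm$imfs)
    if (k > 0) acc[, seq_len(k)] <- acc[, seq_len(k)] + dm$imfs
    acc_res <- acc_res + dm$residue
  }
  imfs <- acc / ensemble_size
  keep <- which(colSums(abs(imfs)) > 0)
  imfs <- imfs[, seq_len(if (length(keep)) max(keep) else 0), drop = FALSE]
  new_imf_set(imfs, acc_res / ensemble_size, fs,
              meta = list(method = "eemd", ensemble_size = ensemble_size,
                          noise_ratio = noise_ratio, seed = seed,
                          max_imfs = max_imfs, sift_sd_tol = sift_sd_tol,
                          max_sifts = max_sifts))
}

new_imf_set <- function(imfs, residue, fs, meta) {
  imfs <- as.matrix(imfs)
  if (ncol(imfs) > 0) colnames(imfs) <- paste0("IMF", seq_len(ncol(imfs)))
  structure(list(imfs = imfs, residue = as.numeric(residue), fs = fs,
                 meta = meta), class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %d IMFs + residue, %d samples @ %g Hz (%s)\n",
              ncol(x$imfs), length(x$residue), x$fs, x$meta$method))
  if (ncol(x$imfs) > 0) {
    zc <- zero_crossing_rates(x)
    cat("  zero-crossing rate (Hz):",
        paste(sprintf("%.1f", zc), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Extract one IMF from an `imf_set` as a trace
#'
#' @param decomp An `imf_set` from [emd()]/[eemd()].
#' @param index 1-based IMF index (1 = highest-frequency component).
#' @return An [emg_trace] holding that component.
#' @export
imf_trace <- function(decomp, index = 1L) {
  stopifnot(inherits(decomp, "imf_set"))
  if (index < 1 || index > ncol(decomp$imfs)) {
    stop(sprintf("IMF index %d out of range (decomposition has %d IMFs)",
                 index, ncol(decomp$imfs)), call. = FALSE)
  }
  emg_trace(decomp$imfs[, index], fs = decomp$fs)
}

#' Mean zero-crossing rate of each IMF
#'
#' The per-component zero-crossing rate (crossings per second) is a crude
#' mean-frequency ordering check: it decreases from IMF1 down the set.
#'
#' @param decomp An `imf_set`.
#' @return Numeric vector, one rate per IMF.
#' @export
zero_crossing_rates <- function(decomp) {
  stopifnot(inherits(decomp, "imf_set"))
  dur <- length(decomp$residue) / decomp$fs
  apply(decomp$imfs, 2, function(col) .zero_crossings_cpp(col) / dur)
}

#' Reconstruct the input from a decomposition
#'
#' @param decomp An `imf_set`.
#' @return Numeric vector `rowSums(imfs) + residue`.
#' @export
reconstruct <- function(decomp) {
  stopifnot(inherits(decomp, "imf_set"))
  if (ncol(decomp$imfs) == 0) return(decomp$residue)
  rowSums(decomp$imfs) + decomp$residue
}

as_samples <- function(x) {
  if (inherits(x, "emg_trace")) x$samples else as.numeric(x)
}
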