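#' Linear fit of a median-frequency series
#'
#' Ordinary least squares of MF on window time, `y = A x + b`. The intercept
#' `b` is the session's initial median frequency `mf0`; `mf_S` is the fitted
#' value at the last window centre (the terminal median frequency at maximal
#' fatigue); `R` is the absolute Pearson correlation between time and MF and
#' measures how well a straight line describes the drift.
#'
#' @param series An [mf_series], or any data.frame with `time_s` and `mf_hz`.
#' @return Object of class `mf_linfit`: list with `slope_A` (Hz/s),
#'   `intercept_b` (Hz), `mf_S` (Hz), `R`, `t_end` (s), `n_windows`, and
#'   `degenerate` (TRUE when the MF series has zero variance, in which case
#'   `R` is reported as 0 with a warning).
#' @examples
#' fit_mf_line(data.frame(time_s = 0:10, mf_hz = 135 - 0.1 * (0:10)))
#' @export
fit_mf_line <- function(series) {
  t <- series$time_s
  y <- series$mf_hz
  if (length(t) < 3L) {
    stop("insufficient data: need >= 3 windows for a linear MF fit", call. = FALSE)
  }
  if (!all(is.finite(t)) || !all(is.finite(y))) {
    stop("MF series contains non-finite values", call. = FALSE)
  }
  degenerate <- var(y) == 0
  if (degenerate) {
    warning("MF series has zero variance; degenerate fit with R = 0")
    slope <- 0
    intercept <- y[1]
    R <- 0
  } else {
    cf <- coef(lm(y ~ t))
    slope <- unname(cf[2])
    intercept <- unname(cf[1])
    R <- abs(cor(t, y))
  }
  t_end <- t[length(t)]
  structure(list(slope_A = slope, intercept_b = intercept,
                 mf_S = slope * t_end + intercept, R = R, t_end = t_end,
                 n_windows = length(t), degenerate = degenerate),
            class = "mf_linfit")
}

#' @export
print.mf_linfit <- function(x, ...) {
  cat(sprintf("<mf_linfit> A = %.3f Hz/s, mf0 = %.3f Hz, mfS = %.3f Hz, R = %.3f (%d windows)\n",
              x$slope_A, x$intercept_b, x$mf_S, x$R, x$n_windows))
  invisible(x)
}

#' Standardized median-frequency distribution range (SMFDR)
#'
#' Per-subject, per-load calibration of the fatigue scale: the standardized
#' initial MF is the mean of the training fits' intercepts and the
#' standardized terminal MF the mean of their fitted end values. The interval
#' `[mfs_bar, mf0_bar]` spans the subject's non-fatigued to fully fatigued
#' states and anchors the N-level quantizer. Calibration is never pooled
#' across subjects: individual physiology makes the range subject-specific.
#'
#' @param fits List of [mf_linfit] objects from the training sessions.
#' @param subject_id,load_label Free-text labels carried into the model.
#' @return Object of class `smfdr`: list with `mf0_bar`, `mfs_bar` (Hz),
#'   `n_train`, `subject_id`, `load_label`, and `usable` (FALSE when
#'   `mf0_bar <= mfs_bar`, i.e. no downward fatigue range exists; the
#'   estimator refuses such a model).
#' @export
build_smfdr <- function(fits, subject_id = "unknown", load_label = "unknown") {
  if (inherits(fits, "mf_linfit")) fits <- list(fits)
  if (length(fits) < 1L) stop("empty training set", call. = FALSE)
  if (!all(vapply(fits, inherits, logical(1), "mf_linfit"))) {
    stop("'fits' must be a list of mf_linfit objects", call. = FALSE)
  }
  mf0_bar <- mean(vapply(fits, `[[`, numeric(1), "intercept_b"))
  mfs_bar <- mean(vapply(fits, `[[`, numeric(1), "mf_S"))
  usable <- mf0_bar > mfs_bar
  if (!usable) {
    warning("no fatigue range: mf0_bar <= mfs_bar; model flagged unusable")
  }
  structure(list(mf0_bar = mf0_bar, mfs_bar = mfs_bar,
                 n_train = length(fits), subject_id = subject_id,
                 load_label = load_label, usable = usable),
            class = "smfdr")
}

#' @export
print.smfdr <- function(x, ...) {
  cat(sprintf("<smfdr> subject %s, load %s: MF0_bar = %.3f Hz, MFs_bar = %.3f Hz (n = %d)%s\n",
              x$subject_id, x$load_label, x$mf0_bar, x$mfs_bar, x$n_train,
              if (x$usable) "" else " [no fatigue range]"))
  invisible(x)
}

check_usable <- function(smfdr) {
  stopifnot(inherits(smfdr, "smfdr"))
  if (!isTRUE(smfdr$usable)) {
    stop("SMFDR has no fatigue range (mf0_bar <= mfs_bar); refusing to estimate",
         call. = FALSE)
  }
  invisible(smfdr)
}

#' Fatigue-level interval boundaries
#'
#' Splits the SMFDR into `N` contiguous frequency intervals of width
#' `delta = (mf0_bar - mfs_bar)/(N - 1)`. Interval `k` (k = 0..N-1) is
#' `(mf0_bar - (2k+1) delta/2, mf0_bar - (2k-1) delta/2]`, centred on
#' `mf0_bar - k delta`, so the interval centres run from `mf0_bar` (no
#' fatigue, LF = 0) down to `mfs_bar` (complete fatigue, LF = 1). Boundary
#' values belong to the lower-frequency (more fatigued) interval.
#'
#' @param smfdr A usable [build_smfdr()] model.
#' @param N Number of fatigue levels (>= 2).
#' @return data.frame with columns `k`, `lower_hz`, `upper_hz` (half-open
#'   `(lower, upper]`), `center_hz`, `LF`.
#' @export
level_boundaries <- function(smfdr, N) {
  check_usable(smfdr)
  if (!is.numeric(N) || length(N) != 1L || N < 2 || N != round(N)) {
    stop("'N' must be an integer >= 2", call. = FALSE)
  }
  N <- as.integer(N)
  delta <- (smfdr$mf0_bar - smfdr$mfs_bar) / (N - 1)
  k <- 0:(N - 1)
  data.frame(k = k,
             lower_hz = smfdr$mf0_bar - (2 * k + 1) * delta / 2,
             upper_hz = smfdr$mf0_bar - (2 * k - 1) * delta / 2,
             center_hz = smfdr$mf0_bar - k * delta,
             LF = k / (N - 1))
}

#' Quantize a fitted median frequency to a fatigue level
#'
#' Maps a fitted MF value onto the N-level scale defined by the SMFDR:
#' level index `k` is the interval of [level_boundaries()] containing `y_i`,
#' and `LF = k/(N-1)` in `[0, 1]` (0 = no fatigue, 1 = complete fatigue).
#' Values outside the calibrated range are clamped; by default with the
#' physiologically monotone orientation (MF above the range means less
#' fatigued than calibration, so `k = 0`; below it, `k = N-1`). The
#' `"inverted"` policy applies the opposite clamps and exists only for
#' auditing against conventions that state the out-of-range rule with the
#' inequalities reversed.
#'
#' @param y_i Fitted median frequency in Hz (finite scalar or vector).
#' @param smfdr A usable [build_smfdr()] model.
#' @param N Number of fatigue levels (>= 2).
#' @param out_of_range `"monotone"` (default) or `"inverted"` clamp policy.
#' @return For scalar `y_i` an object of class `fatigue_estimate` (list with
#'   `y_i`, `k`, `LF`, `N`, `delta`); for vector input a data.frame with one
#'   row per value.
#' @export
estimate_level <- function(y_i, smfdr, N,
                           out_of_range = c("monotone", "inverted")) {
  check_usable(smfdr)
  out_of_range <- match.arg(out_of_range)
  if (!is.numeric(N) || length(N) != 1L || N < 2 || N != round(N)) {
    stop("'N' must be an integer >= 2", call. = FALSE)
  }
  if (!all(is.finite(y_i))) stop("'y_i' must be finite", call. = FALSE)
  N <- as.integer(N)
  delta <- (smfdr$mf0_bar - smfdr$mfs_bar) / (N - 1)

  assign_one <- function(y) {
    k <- floor((smfdr$mf0_bar - y) / delta + 0.5)
    # float-safe adjustment onto the half-open (lower, upper] intervals,
    # using the same boundary expressions as level_boundaries()
    lower <- function(k) smfdr$mf0_bar - (2 * k + 1) * delta / 2
    upper <- function(k) smfdr$mf0_bar - (2 * k - 1) * delta / 2
    while (k > 0 && y > upper(k)) k <- k - 1
    while (k < N - 1 && y <= lower(k)) k <- k + 1
    if (out_of_range == "monotone") {
      if (y > upper(0)) k <- 0
      if (y <= lower(N - 1)) k <- N - 1
    } else {
      if (y > upper(0)) k <- N - 1
      if (y <= lower(N - 1)) k <- 0
    }
    max(0, min(N - 1, k))
  }
  k <- vapply(y_i, assign_one, numeric(1))
  if (length(y_i) == 1L) {
    structure(list(y_i = y_i, k = as.integer(k), LF = k / (N - 1), N = N,
                   delta = delta),
              class = "fatigue_estimate")
  } else {
    data.frame(y_i = y_i, k = as.integer(k), LF = k / (N - 1))
  }
}

#' @export
print.fatigue_estimate <- function(x, ...) {
  cat(sprintf("<fatigue_estimate> y = %.3f Hz -> level %d of %d, LF = %.3f\n",
              x$y_i, x$k, x$N, x$LF))
  invisible(x)
}

#' Fatigue-level trajectory of a session
#'
#' Evaluates the session's fitted MF line at the requested times and
#' quantizes each value with [estimate_level()]. For a negative MF slope the
#' LF sequence is non-decreasing in time.
#'
#' @param fit An [mf_linfit] for the session under evaluation.
#' @param smfdr A usable [build_smfdr()] model.
#' @param N Number of fatigue levels (>= 2).
#' @param times Evaluation times in seconds (defaults to a grid is not
#'   assumed; pass the window centres of the session's [mf_series]).
#' @param out_of_range Clamp policy, see [estimate_level()].
#' @return Object of classes `fatigue_trajectory`/`data.frame` with columns
#'   `time_s`, `y_i_hz`, `k`, `LF`; attributes carry `N`, `delta` and the
#'   `smfdr`.
#' @export
fatigue_trajectory <- function(fit, smfdr, N, times,
                               out_of_range = c("monotone", "inverted")) {
  stopifnot(inherits(fit, "mf_linfit"))
  check_usable(smfdr)
  out_of_range <- match.arg(out_of_range)
  if (!all(is.finite(times))) stop("'times' must be finite", call. = FALSE)
  y <- fit$slope_A * times + fit$intercept_b
  est <- estimate_level(y, smfdr, N, out_of_range = out_of_range)
  if (is.list(est) && !is.data.frame(est)) {
    est <- data.frame(y_i = est$y_i, k = est$k, LF = est$LF)
  }
  out <- data.frame(time_s = times, y_i_hz = est$y_i, k = est$k, LF = est$LF)
  attr(out, "N") <- as.integer(N)
  attr(out, "delta") <- (smfdr$mf0_bar - smfdr$mfs_bar) / (N - 1)
  attr(out, "smfdr") <- smfdr
  attr(out, "fit") <- fit
  class(out) <- c("fatigue_trajectory", "data.frame")
  out
}

#' Write / read an SMFDR model as JSON
#'
#' Serializes the calibrated range together with the pipeline parameters and
#' a provenance block so the estimate step can verify it runs with matching
#' settings.
#'
#' @param smfdr A [build_smfdr()] model.
#' @param path Output file path.
#' @param params Optional named list of pipeline parameters to embed.
#' @return `write_smfdr()` returns `path` invisibly; `read_smfdr()` returns
#'   the `smfdr` object with a `params` attribute.
#' @export
write_smfdr <- function(smfdr, path, params = list()) {
  stopifnot(inherits(smfdr, "smfdr"))
  obj <- list(subject_id = smfdr$subject_id, load_label = smfdr$load_label,
              mf0_bar = smfdr$mf0_bar, mfs_bar = smfdr$mfs_bar,
              n_train = smfdr$n_train, usable = smfdr$usable,
              params = params,
              provenance = list(package = "semgfatigue",
                                version = as.character(packageVersion("semgfatigue"))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_smfdr
#' @export
read_smfdr <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- structure(list(mf0_bar = obj$mf0_bar, mfs_bar = obj$mfs_bar,
                        n_train = obj$n_train, subject_id = obj$subject_id,
                        load_label = obj$load_label,
                        usable = isTRUE(obj$usable)),
                   class = "smfdr")
  attr(out, "params") <- obj$params
  out
}
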