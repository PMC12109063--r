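#' Pipeline configuration
#'
#' Bundles every tunable of the calibrate/estimate workflow with its default.
#' Values can come from a YAML config file and be overridden per call;
#' precedence is call arguments > config file > defaults.
#'
#' @param ... Named overrides of the defaults (see Details).
#' @param file Optional YAML file of `key: value` pairs.
#'
#' @details Keys and defaults: `sampling_rate` 2000 Hz (csv files without a
#'   time column); `band_low` 10, `band_high` 400, `notch_hz` 50, `notch_q`
#'   30 (conditioning); `window_ms` 10240, `step_ms` 2560 (MF windows);
#'   `ensemble_size` 100, `noise_ratio` 0.2, `seed` 1, `max_imfs` 8,
#'   `sift_sd_tol` 0.2, `max_sifts` 50 (EEMD); `imf_index` 1 (component
#'   analysed); `n_levels` 3 (fatigue grades; 3 balances resolution against
#'   calibration noise); `out_of_range` "monotone" (clamp policy).
#' @return Named list of class `run_config`.
#' @export
run_config <- function(..., file = NULL) {
  defaults <- list(
    sampling_rate = 2000, band_low = 10, band_high = 400, notch_hz = 50,
    notch_q = 30, window_ms = 10240, step_ms = 2560, ensemble_size = 100,
    noise_ratio = 0.2, seed = 1L, max_imfs = 8L, sift_sd_tol = 0.2,
    max_sifts = 50L, imf_index = 1L, n_levels = 3L, out_of_range = "monotone")
  cfg <- defaults
  if (!is.null(file)) {
    if (!file.exists(file)) stop(sprintf("config file not found: %s", file),
                                 call. = FALSE)
    fromfile <- yaml::read_yaml(file)
    unknown <- setdiff(names(fromfile), names(defaults))
    if (length(unknown)) {
      stop(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")),
           call. = FALSE)
    }
    cfg <- modifyList(cfg, fromfile)
  }
  overrides <- list(...)
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(defaults))
    if (length(unknown)) {
      stop(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")),
           call. = FALSE)
    }
    cfg <- modifyList(cfg, overrides)
  }
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  pos <- c("sampling_rate", "band_low", "band_high", "notch_hz", "notch_q",
           "window_ms", "step_ms", "ensemble_size", "sift_sd_tol", "max_sifts",
           "max_imfs")
  for (k in pos) {
    if (!is.numeric(cfg[[k]]) || cfg[[k]] <= 0) {
      stop(sprintf("config key '%s' must be positive", k), call. = FALSE)
    }
  }
  if (cfg$window_ms <= cfg$step_ms) {
    stop("config requires window_ms > step_ms", call. = FALSE)
  }
  if (cfg$imf_index < 1) stop("config requires imf_index >= 1", call. = FALSE)
  if (cfg$n_levels < 2) stop("config requires n_levels >= 2", call. = FALSE)
  if (cfg$noise_ratio < 0) stop("config requires noise_ratio >= 0", call. = FALSE)
  invisible(cfg)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (k in names(x)) cat(sprintf("  %-14s %s\n", k, format(x[[k]])))
  invisible(x)
}

config_provenance <- function(cfg) {
  c(unclass(cfg),
    list(package = "semgfatigue",
         version = as.character(packageVersion("semgfatigue"))))
}

log_info <- function(fmt, ...) message(sprintf(fmt, ...))

#' Run the MF extraction pipeline on one session
#'
#' condition -> EEMD -> selected IMF -> windowed MF series -> linear fit:
#' the per-session half of the fatigue workflow.
#'
#' @param trace An [emg_trace] (a raw session recording).
#' @param config A [run_config()].
#' @return List with `fit` (an [mf_linfit]), `mf` (the [mf_series]) and
#'   `imf1` (the analysed component as an [emg_trace]).
#' @export
session_pipeline <- function(trace, config = run_config()) {
  stopifnot(inherits(trace, "emg_trace"))
  cond <- condition(trace, band_low = config$band_low,
                    band_high = config$band_high, notch = config$notch_hz,
                    notch_q = config$notch_q)
  dec <- eemd(cond, ensemble_size = config$ensemble_size,
              noise_ratio = config$noise_ratio, seed = config$seed,
              max_imfs = config$max_imfs, sift_sd_tol = config$sift_sd_tol,
              max_sifts = config$max_sifts)
  comp <- imf_trace(dec, config$imf_index)
  mfs <- mf_series(comp, window_ms = config$window_ms, step_ms = config$step_ms)
  list(fit = fit_mf_line(mfs), mf = mfs, imf1 = comp)
}

resolve_trace <- function(x, config) {
  if (inherits(x, "emg_trace")) return(x)
  read_trace(x, sampling_rate = config$sampling_rate)
}

#' Calibrate an SMFDR model from training sessions
#'
#' Runs [session_pipeline()] on each training session, logs one row of fit
#' parameters (A, mf0, mfS, R) per file, and averages the per-session initial
#' and terminal median frequencies into the subject's standardized range.
#'
#' @param training Character vector of csv/edf paths, or list of
#'   [emg_trace]s.
#' @param config A [run_config()].
#' @param subject_id,load_label Labels stored in the model.
#' @param model_out Optional path; when given the model is written as JSON
#'   with [write_smfdr()].
#' @return The [build_smfdr()] model, with the per-session fits attached as
#'   attribute `fits`.
#' @export
emg_calibrate <- function(training, config = run_config(),
                          subject_id = "unknown", load_label = "unknown",
                          model_out = NULL) {
  if (length(training) < 1L) stop("empty training set", call. = FALSE)
  nm <- if (is.character(training)) basename(training) else
    sprintf("session%d", seq_along(training))
  log_info("calibrating on %d session(s) [subject %s, load %s]",
           length(training), subject_id, load_label)
  log_info("%-24s %10s %10s %10s %8s", "session", "A", "mf0", "mfS", "R")
  fits <- vector("list", length(training))
  for (i in seq_along(training)) {
    tr <- tryCatch(resolve_trace(training[[i]], config), error = function(e) {
      stop(sprintf("calibration failed on '%s': %s", nm[i], conditionMessage(e)),
           call. = FALSE)
    })
    res <- tryCatch(session_pipeline(tr, config), error = function(e) {
      stop(sprintf("calibration failed on '%s': %s", nm[i], conditionMessage(e)),
           call. = FALSE)
    })
    fits[[i]] <- res$fit
    log_info("%-24s %10.3f %10.3f %10.3f %8.3f", nm[i], res$fit$slope_A,
             res$fit$intercept_b, res$fit$mf_S, res$fit$R)
  }
  model <- build_smfdr(fits, subject_id = subject_id, load_label = load_label)
  log_info("SMFDR: MF0_bar = %.3f Hz, MFs_bar = %.3f Hz", model$mf0_bar,
           model$mfs_bar)
  if (!is.null(model_out)) {
    write_smfdr(model, model_out, params = config_provenance(config))
    log_info("model written to %s", model_out)
  }
  attr(model, "fits") <- fits
  model
}

#' Estimate the fatigue trajectory of a test session
#'
#' Runs [session_pipeline()] on the test session and quantizes its fitted MF
#' line against a calibrated SMFDR at the session's window centres.
#'
#' @param test A csv/edf path or [emg_trace].
#' @param model An [build_smfdr()] object or path to a model JSON.
#' @param config A [run_config()].
#' @param out Optional path for the trajectory as delimited text
#'   (`time_s, y_i_hz, k, LF` with a provenance header).
#' @param plot_file Optional png/svg path for the trajectory plot.
#' @return The [fatigue_trajectory()], with the session fit attached.
#' @export
emg_estimate <- function(test, model, config = run_config(), out = NULL,
                         plot_file = NULL) {
  if (is.character(model)) model <- read_smfdr(model)
  check_usable(model)
  tr <- resolve_trace(test, config)
  res <- session_pipeline(tr, config)
  traj <- fatigue_trajectory(res$fit, model, N = config$n_levels,
                             times = res$mf$time_s,
                             out_of_range = config$out_of_range)
  log_info("session fit: A = %.3f Hz/s, mf0 = %.3f Hz, mfS = %.3f Hz, R = %.3f",
           res$fit$slope_A, res$fit$intercept_b, res$fit$mf_S, res$fit$R)
  log_info("fatigue level: %.2f -> %.2f over %d windows (N = %d)",
           traj$LF[1], traj$LF[nrow(traj)], nrow(traj), config$n_levels)
  if (!is.null(out)) {
    prov <- c(config_provenance(config),
              list(mf0_bar = model$mf0_bar, mfs_bar = model$mfs_bar,
                   subject_id = model$subject_id, load_label = model$load_label))
    write_csv_with_provenance(as.data.frame(traj), out, prov)
    log_info("trajectory written to %s", out)
  }
  if (!is.null(plot_file)) {
    open_plot_device(plot_file)
    plot(traj, mf = res$mf)
    dev.off()
    log_info("plot written to %s", plot_file)
  }
  attr(traj, "mf") <- res$mf
  traj
}

#' Simulate a synthetic session to disk
#'
#' @param out Output csv path.
#' @param ... Arguments to [synth_spec()].
#' @return The [synth_emg()] result, invisibly; the trace is written with a
#'   provenance header recording the generating spec.
#' @export
emg_simulate <- function(out, ...) {
  spec <- synth_spec(...)
  res <- synth_emg(spec)
  write_trace(res$trace, out, provenance = c(unclass(spec),
    list(true_slope = res$true_slope, true_intercept = res$true_intercept,
         package = "semgfatigue",
         version = as.character(packageVersion("semgfatigue")))))
  log_info("synthetic session written to %s (%.0f s @ %g Hz, MF %g -> %g Hz)",
           out, spec$duration_s, spec$fs, spec$mf_start, spec$mf_end)
  invisible(res)
}

#' Dump the EEMD components of a session as delimited text
#'
#' @param input A csv/edf path or [emg_trace].
#' @param out Output csv path (one column per IMF plus the residue).
#' @param config A [run_config()].
#' @return The `imf_set`, invisibly.
#' @export
emg_decompose <- function(input, out, config = run_config()) {
  tr <- resolve_trace(input, config)
  cond <- condition(tr, band_low = config$band_low, band_high = config$band_high,
                    notch = config$notch_hz, notch_q = config$notch_q)
  dec <- eemd(cond, ensemble_size = config$ensemble_size,
              noise_ratio = config$noise_ratio, seed = config$seed,
              max_imfs = config$max_imfs, sift_sd_tol = config$sift_sd_tol,
              max_sifts = config$max_sifts)
  df <- as.data.frame(dec$imfs)
  df$residue <- dec$residue
  df <- cbind(time_s = trace_times(tr), df)
  write_csv_with_provenance(df, out, config_provenance(config))
  log_info("%d IMFs + residue written to %s", ncol(dec$imfs), out)
  invisible(dec)
}

#' Write the MF series of a session as delimited text
#'
#' @inheritParams emg_decompose
#' @return The [mf_series], invisibly.
#' @export
emg_mf <- function(input, out, config = run_config()) {
  tr <- resolve_trace(input, config)
  res <- session_pipeline(tr, config)
  write_csv_with_provenance(as.data.frame(res$mf), out,
                            config_provenance(config))
  log_info("%d MF windows written to %s", nrow(res$mf), out)
  invisible(res$mf)
}

open_plot_device <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  switch(ext,
         png = png(path, width = 1200, height = 700, res = 130),
         svg = svg(path, width = 9, height = 5.5),
         stop(sprintf("unsupported plot format '%s' (png or svg)", ext),
              call. = FALSE))
}
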