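#' Read a signal trace from disk
#'
#' Supports two-column delimited text (`time_s`, `value_V`; '.' decimal
#' separator; leading `#` provenance/comment lines are skipped) and
#' continuous EDF recordings. For text input the sampling rate is derived
#' from the time column unless supplied, and the time grid must be uniform
#' to within 1 ppm.
#'
#' @param path Input file.
#' @param format `"csv"` or `"edf"`; default inferred from the extension.
#' @param column For csv, name or index of the value column (default
#'   `"value_V"` or the second column); for EDF, the channel index.
#' @param sampling_rate Fallback sampling rate in Hz, used only for csv
#'   files without a time column (the time column, when present, is
#'   authoritative).
#' @return An [emg_trace].
#' @export
read_trace <- function(path, format = c("auto", "csv", "edf"), column = NULL,
                       sampling_rate = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  if (format == "edf") {
    return(read_edf_trace(path, channel = if (is.null(column)) 1L else column))
  }

  skip <- count_comment_lines(path)
  dt <- data.table::fread(path, skip = skip, header = TRUE, sep = ",")
  if (ncol(dt) < 1L) stop(sprintf("no data columns in %s", path), call. = FALSE)

  if (is.null(column)) {
    column <- if ("value_V" %in% names(dt)) "value_V" else min(2L, ncol(dt))
  }
  if (is.character(column) && !column %in% names(dt)) {
    stop(sprintf("missing column '%s' in %s (found: %s)", column, path,
                 paste(names(dt), collapse = ", ")), call. = FALSE)
  }
  v <- as.numeric(dt[[column]])
  bad <- which(!is.finite(v))
  if (length(bad)) {
    stop(sprintf("non-finite value at data row %d of %s", bad[1], path),
         call. = FALSE)
  }

  tcol <- if ("time_s" %in% names(dt)) "time_s" else NULL
  t0 <- 0
  if (!is.null(tcol)) {
    tt <- as.numeric(dt[[tcol]])
    badt <- which(!is.finite(tt))
    if (length(badt)) {
      stop(sprintf("non-finite time at data row %d of %s", badt[1], path),
           call. = FALSE)
    }
    dts <- diff(tt)
    mdt <- mean(dts)
    if (mdt <= 0 || max(abs(dts - mdt)) > 1e-6 * mdt) {
      stop(sprintf("non-uniform time steps in %s (> 1 ppm jitter)", path),
           call. = FALSE)
    }
    # the time column is authoritative; sampling_rate is only a fallback
    sampling_rate <- (length(tt) - 1) / (tt[length(tt)] - tt[1])
    t0 <- tt[1]
  } else if (is.null(sampling_rate)) {
    stop(sprintf("no 'time_s' column in %s: supply sampling_rate", path),
         call. = FALSE)
  }
  emg_trace(v, fs = sampling_rate, t0 = t0)
}

#' Write a signal trace as delimited text
#'
#' Two columns (`time_s`, `value_V`), '.' decimal separator, optionally
#' preceded by `#`-prefixed provenance lines that [read_trace()] skips.
#'
#' @param trace An [emg_trace].
#' @param path Output file.
#' @param provenance Optional named list written as `# key: value` lines.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, provenance = NULL) {
  stopifnot(inherits(trace, "emg_trace"))
  df <- data.frame(time_s = trace_times(trace), value_V = trace$samples)
  write_csv_with_provenance(df, path, provenance)
}

# fwrite wants a path, so provenance comments are written first and the
# table appended with its header.
write_csv_with_provenance <- function(df, path, provenance = NULL) {
  if (!is.null(provenance) && length(provenance)) {
    con <- file(path, open = "wt")
    write_provenance_lines(con, provenance)
    close(con)
    data.table::fwrite(df, path, sep = ",", append = TRUE, col.names = TRUE)
  } else {
    data.table::fwrite(df, path, sep = ",")
  }
  invisible(path)
}

count_comment_lines <- function(path) {
  con <- file(path, open = "rt")
  on.exit(close(con))
  k <- 0L
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L || !startsWith(line, "#")) break
    k <- k + 1L
  }
  k
}

write_provenance_lines <- function(con, provenance) {
  if (is.null(provenance) || !length(provenance)) return(invisible())
  for (nm in names(provenance)) {
    writeLines(sprintf("# %s: %s", nm,
                       paste(format(provenance[[nm]]), collapse = " ")), con)
  }
  invisible()
}

# Minimal reader for continuous EDF recordings (fixed-layout ASCII header,
# 16-bit little-endian samples). Only what the pipeline needs: one channel,
# uniform rate, physical calibration from the digital/physical extrema.
read_edf_trace <- function(path, channel = 1L) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  rd <- function(nbytes) {
    trimws(rawToChar(readBin(con, "raw", n = nbytes)))
  }
  rd(8)                       # version
  rd(80); rd(80)              # patient / recording ids
  rd(8); rd(8)                # start date / time
  rd(8)                       # header length
  rd(44)                      # reserved
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L) stop("malformed EDF header", call. = FALSE)
  if (channel < 1L || channel > ns) {
    stop(sprintf("EDF channel %d out of range (file has %d signals)",
                 channel, ns), call. = FALSE)
  }
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)                     # transducer
  for (i in seq_len(ns)) rd(8)                      # physical dimension
  phys_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  phys_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dig_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dig_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)                     # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)                     # reserved

  if (n_rec < 1L || rec_dur <= 0) stop("EDF file has no data records", call. = FALSE)
  out <- numeric(n_rec * spr[channel])
  pos <- 0L
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      vals <- readBin(con, "integer", n = spr[s], size = 2L, signed = TRUE,
                      endian = "little")
      if (s == channel) {
        out[(pos + 1L):(pos + spr[s])] <- vals
        pos <- pos + spr[s]
      }
    }
  }
  gain <- (phys_max[channel] - phys_min[channel]) /
    (dig_max[channel] - dig_min[channel])
  phys <- (out - dig_min[channel]) * gain + phys_min[channel]
  tr <- emg_trace(phys, fs = spr[channel] / rec_dur, t0 = 0)
  attr(tr, "label") <- labels[channel]
  tr
}
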