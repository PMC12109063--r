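# Independent oracles, deliberately written as plain loops so they share no
# code path with the package implementations they check.

# Median frequency by explicit cumulative mass: each bin's power spread
# uniformly over [f - df/2, f + df/2], walk until half the total is covered.
oracle_mf <- function(freqs, power) {
  df <- freqs[2] - freqs[1]
  total <- 0
  for (p in power) total <- total + p
  half <- total / 2
  cum <- 0
  for (k in seq_along(power)) {
    if (cum + power[k] >= half) {
      return((freqs[k] - df / 2) + (half - cum) / power[k] * df)
    }
    cum <- cum + power[k]
  }
  stop("oracle_mf: never reached half power")
}

# Closed-form ordinary least squares via the normal equations.
oracle_ols <- function(t, y) {
  n <- length(t)
  st <- sum(t); sy <- sum(y); stt <- sum(t * t); sty <- sum(t * y)
  slope <- (n * sty - st * sy) / (n * stt - st * st)
  intercept <- (sy - slope * st) / n
  list(slope = slope, intercept = intercept)
}

# Brute-force fatigue-level assignment: scan every interval
# (mf0 - (2k+1)d/2, mf0 - (2k-1)d/2], then apply the monotone clamps.
oracle_level <- function(y, mf0_bar, mfs_bar, N) {
  delta <- (mf0_bar - mfs_bar) / (N - 1)
  for (k in 0:(N - 1)) {
    lo <- mf0_bar - (2 * k + 1) * delta / 2
    hi <- mf0_bar - (2 * k - 1) * delta / 2
    if (y > lo && y <= hi) return(k)
  }
  if (y > mf0_bar + delta / 2) return(0)
  N - 1
}

# MF of a raw (untapered) periodogram — an independent route to the
# empirical median frequency of a segment.
oracle_mf_of_segment <- function(x, fs) {
  n <- length(x)
  X <- fft(x - mean(x))
  nh <- floor(n / 2)
  oracle_mf((0:nh) * fs / n, Mod(X[1:(nh + 1)])^2)
}

oracle_mf_of_trace <- function(tr) oracle_mf_of_segment(tr$samples, tr$fs)

sine_trace <- function(freq, duration_s, fs, amp = 1) {
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  emg_trace(amp * sin(2 * pi * freq * t), fs = fs)
}

rms <- function(x) sqrt(mean(x^2))

# Band-limited stationary noise trace via the package generator with the
# drift switched off.
stationary_trace <- function(duration_s, fs = 2000, center = 120,
                             bandwidth = 40, seed = 1) {
  synth_emg(synth_spec(duration_s = duration_s, fs = fs, mf_start = center,
                       mf_end = center, bandwidth = bandwidth, mod_depth = 0,
                       powerline_amp = 0, noise_floor = 0, seed = seed))$trace
}

# Tiny continuous-EDF writer (fixed-layout ASCII header + int16 records)
# used to exercise the EDF reader without storing binary fixtures.
write_mini_edf <- function(path, channels, fs, rec_dur = 1,
                           phys_min = -1000, phys_max = 1000) {
  ns <- length(channels)
  spr <- as.integer(fs * rec_dur)
  n_rec <- length(channels[[1]]) %/% spr
  stopifnot(n_rec >= 1, all(lengths(channels) == n_rec * spr))
  dig_min <- -32768; dig_max <- 32767
  con <- file(path, open = "wb")
  on.exit(close(con))
  pad <- function(s, width) {
    s <- substr(as.character(s), 1, width)
    writeChar(formatC(s, width = -width), con, eos = NULL)
  }
  pad("0", 8); pad("test patient", 80); pad("test recording", 80)
  pad("01.01.24", 8); pad("00.00.00", 8)
  pad(256 * (1 + ns), 8); pad("", 44); pad(n_rec, 8); pad(rec_dur, 8)
  pad(ns, 4)
  for (nm in names(channels)) pad(nm, 16)
  for (i in seq_len(ns)) pad("dry electrode", 80)
  for (i in seq_len(ns)) pad("uV", 8)
  for (i in seq_len(ns)) pad(phys_min, 8)
  for (i in seq_len(ns)) pad(phys_max, 8)
  for (i in seq_len(ns)) pad(dig_min, 8)
  for (i in seq_len(ns)) pad(dig_max, 8)
  for (i in seq_len(ns)) pad("none", 80)
  for (i in seq_len(ns)) pad(spr, 8)
  for (i in seq_len(ns)) pad("", 32)
  gain <- (dig_max - dig_min) / (phys_max - phys_min)
  for (r in seq_len(n_rec)) {
    for (ch in channels) {
      seg <- ch[((r - 1) * spr + 1):(r * spr)]
      dig <- as.integer(round((seg - phys_min) * gain + dig_min))
      writeBin(dig, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}
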