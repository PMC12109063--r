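fs <- 2000

test_that("window segmentation counts, centres and boundary cases are exact", {
  tr <- emg_trace(rnorm(160 * fs), fs = fs)
  segs <- window_segments(tr)
  expect_length(segs, 59)  # floor((160000 - 10240)/2560) + 1
  expect_equal(segs[[1]]$center_s, 10.24 / 2)
  expect_equal(segs[[2]]$center_s - segs[[1]]$center_s, 2.56)
  expect_length(segs[[59]]$samples, round(10.24 * fs))

  exact <- emg_trace(rnorm(round(10.24 * fs)), fs = fs)
  expect_length(window_segments(exact), 1)

  short <- emg_trace(rnorm(round(10.239 * fs)), fs = fs)
  expect_error(window_segments(short), "too short")
})

test_that("the periodogram peaks at a sine's frequency and satisfies Parseval", {
  tr <- sine_trace(100, 10.24, fs)
  sp <- psd(tr)
  df <- sp$freqs[2] - sp$freqs[1]
  expect_lt(abs(sp$freqs[which.max(sp$power)] - 100), df + 1e-12)

  set.seed(21)
  x <- rnorm(20480)
  sp <- psd(x, fs = fs)
  xd <- x - mean(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_along(x) - 1) / length(x))
  tapered_var <- sum((xd * w)^2) / sum(w^2)
  expect_equal(sum(sp$power) * df, tapered_var, tolerance = 1e-10)
  expect_equal(sum(sp$power) * df, var(x), tolerance = 0.05)
})

test_that("white noise gives a flat averaged spectrum", {
  set.seed(22)
  sp <- psd(rnorm(10 * fs), fs = fs, segments = 16)
  p <- sp$power[-1]
  expect_lt(max(p), 5 * median(p))
})

test_that("median frequency matches analytic cases and the cumulative-sum oracle", {
  expect_equal(median_frequency(list(freqs = 0:100, power = rep(1, 101))), 50,
               tolerance = 1e-12)

  p <- numeric(101)
  p[81] <- 3.7  # point mass at 80 Hz
  expect_equal(median_frequency(list(freqs = 0:100, power = p)), 80,
               tolerance = 1e-12)

  spec <- list(freqs = c(10, 20, 30, 40), power = c(1, 2, 3, 2))
  expect_equal(median_frequency(spec), oracle_mf(spec$freqs, spec$power),
               tolerance = 1e-12)

  set.seed(23)
  for (i in 1:20) {
    f0 <- runif(1, 0, 50)
    freqs <- f0 + 0:63 * 2
    power <- rexp(64)
    expect_equal(median_frequency(list(freqs = freqs, power = power)),
                 oracle_mf(freqs, power), tolerance = 1e-10)
  }
})

test_that("MF is scale invariant and tracks rigid spectral translation", {
  set.seed(24)
  freqs <- 0:255 * 0.5
  power <- rexp(256)
  mf <- median_frequency(list(freqs = freqs, power = power))
  expect_equal(median_frequency(list(freqs = freqs, power = 17.3 * power)), mf,
               tolerance = 1e-12)
  # rigid translation up by exactly 10 bins (5 Hz), keeping all mass
  mf2 <- median_frequency(list(freqs = 0:265 * 0.5,
                               power = c(numeric(10), power)))
  expect_equal(mf2 - mf, 5, tolerance = 1e-9)
})

test_that("degenerate spectra are refused", {
  expect_error(median_frequency(list(freqs = 0:10, power = numeric(11))),
               "degenerate")
  expect_error(mf_series(emg_trace(rep(1, 30000), fs = fs)), "degenerate")
})

test_that("the MF series is stable for stationary input and drifts with programmed drift", {
  tr <- stationary_trace(41, center = 120, seed = 25)
  m <- mf_series(tr)
  expect_true(all(m$mf_hz > 0 & m$mf_hz < fs / 2))
  expect_lt(sd(m$mf_hz), 5)
  expect_equal(diff(m$time_s), rep(2.56, nrow(m) - 1))

  drift <- synth_emg(synth_spec(duration_s = 80, mf_start = 136, mf_end = 110,
                                mod_depth = 0, noise_floor = 0, seed = 26))
  md <- mf_series(drift$trace)
  expect_lt(cor(md$time_s, md$mf_hz), 0)
})

test_that("spectral shift detects down-band power migration and normalizes to unit area", {
  stat <- stationary_trace(40, center = 120, seed = 27)
  ss <- spectral_shift(stat)
  expect_lt(abs(ss$low_band_fraction_delta), 0.05)
  for (sp in list(ss$first, ss$last)) {
    expect_equal(sum(sp$power) * (sp$freqs[2] - sp$freqs[1]), 1,
                 tolerance = 1e-9)
  }

  drift <- synth_emg(synth_spec(duration_s = 64, mf_start = 136, mf_end = 100,
                                mod_depth = 0, noise_floor = 0, seed = 28))
  sd2 <- spectral_shift(drift$trace)
  expect_gt(sd2$low_band_fraction_delta, 0)

  expect_error(spectral_shift(stationary_trace(10, seed = 1)), "too short")
})
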