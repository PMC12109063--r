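test_that("generated traces have exact length, finite samples, and seeded determinism", {
  spec <- synth_spec(duration_s = 7.3, fs = 1000, mf_start = 130, mf_end = 120,
                     seed = 42)
  res <- synth_emg(spec)
  expect_equal(length(res$trace$samples), round(7.3 * 1000))
  expect_true(all(is.finite(res$trace$samples)))
  expect_equal(res$trace$fs, 1000)

  res2 <- synth_emg(spec)
  expect_identical(res$trace$samples, res2$trace$samples)

  res3 <- synth_emg(synth_spec(duration_s = 7.3, fs = 1000, mf_start = 130,
                               mf_end = 120, seed = 43))
  expect_false(identical(res$trace$samples, res3$trace$samples))
})

test_that("programmed MF trajectory endpoints and linearity are exposed", {
  res <- synth_emg(synth_spec(duration_s = 20, mf_start = 136, mf_end = 122,
                              seed = 1))
  expect_equal(res$true_mf(0), 136)
  expect_equal(res$true_mf(20), 122)
  expect_equal(res$true_mf(10), 129)  # linear midpoint
  expect_equal(res$true_slope, (122 - 136) / 20)
  expect_equal(res$true_intercept, 136)
})

test_that("stationary spec yields empirical MF near the programmed centre", {
  tr <- stationary_trace(duration_s = 10, center = 120, bandwidth = 40,
                         seed = 5)
  mf <- oracle_mf_of_trace(tr)
  expect_lt(abs(mf - 120), 5)
})

test_that("downward drift moves the first-window MF above the last-window MF", {
  res <- synth_emg(synth_spec(duration_s = 160, mf_start = 136, mf_end = 122,
                              mod_depth = 0, powerline_amp = 0,
                              noise_floor = 0, seed = 9))
  n_win <- round(10.24 * res$trace$fs)
  x <- res$trace$samples
  first <- oracle_mf_of_segment(x[seq_len(n_win)], res$trace$fs)
  last <- oracle_mf_of_segment(x[(length(x) - n_win + 1):length(x)],
                               res$trace$fs)
  expect_gt(first, last)
})

test_that("invalid specs fail with errors naming the violated bound", {
  expect_error(synth_spec(duration_s = -1), "duration_s > 0")
  expect_error(synth_spec(mf_start = 100, mf_end = 110), "mf_end <= mf_start")
  expect_error(synth_spec(fs = 200, mf_start = 150, mf_end = 150),
               "mf_start < fs/2", fixed = TRUE)
  expect_error(synth_spec(mod_depth = 1.5), "mod_depth")
  expect_error(synth_spec(mf_end = 15, mf_start = 15, bandwidth = 40),
               "mf_end - bandwidth/2 > 0", fixed = TRUE)
})

test_that("cyclic modulation and powerline terms show up in the signal", {
  base <- synth_emg(synth_spec(duration_s = 8, mod_depth = 0,
                               powerline_amp = 0, noise_floor = 0, seed = 2))
  mod <- synth_emg(synth_spec(duration_s = 8, mod_depth = 1,
                              powerline_amp = 0, noise_floor = 0, seed = 2))
  # contraction envelope raises the RMS of the active phase over the rest phase
  t <- trace_times(mod$trace) %% 4
  active <- rms(mod$trace$samples[t > 0.5 & t < 2.5])
  rest <- rms(mod$trace$samples[t > 3.2])
  expect_gt(active / rest, 1.5)
  expect_equal(rms(base$trace$samples), 5e-4, tolerance = 1e-6)

  hum <- synth_emg(synth_spec(duration_s = 8, mod_depth = 0,
                              powerline_amp = 5e-4, noise_floor = 0, seed = 2))
  sp <- psd(hum$trace)
  i50 <- which.min(abs(sp$freqs - 50))
  sp0 <- psd(base$trace)
  expect_gt(sp$power[i50], 10 * sp0$power[i50])
})
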