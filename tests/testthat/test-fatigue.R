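mk_series <- function(time_s, mf_hz) data.frame(time_s = time_s, mf_hz = mf_hz)

# a calibrated range resembling a heavy-load subject: MF0_bar 135.8 Hz,
# MFs_bar 122.4 Hz
mk_smfdr <- function(mf0 = 135.8, mfs = 122.4) {
  fit <- function(b, e, t_end = 100) {
    f <- fit_mf_line(mk_series(c(0, t_end / 2, t_end),
                               c(b, (b + e) / 2, e)))
    f
  }
  build_smfdr(list(fit(mf0, mfs)), subject_id = "A", load_label = "4.5kg")
}

test_that("a perfect line is fitted exactly with R = 1", {
  s <- mk_series(seq(0, 150, by = 2.56), 135 - 0.1 * seq(0, 150, by = 2.56))
  f <- fit_mf_line(s)
  expect_equal(f$slope_A, -0.1, tolerance = 1e-10)
  expect_equal(f$intercept_b, 135, tolerance = 1e-10)
  expect_equal(f$R, 1, tolerance = 1e-10)
  expect_equal(f$mf_S, f$slope_A * f$t_end + f$intercept_b)
  expect_equal(f$t_end, s$time_s[nrow(s)])
})

test_that("noisy fits agree with the closed-form least-squares oracle", {
  set.seed(31)
  for (i in 1:50) {
    t <- sort(runif(sample(5:60, 1), 0, 160))
    y <- 130 + rnorm(1, -0.1, 0.05) * t + rnorm(length(t), sd = 2)
    f <- fit_mf_line(mk_series(t, y))
    o <- oracle_ols(t, y)
    expect_equal(f$slope_A, o$slope, tolerance = 1e-9)
    expect_equal(f$intercept_b, o$intercept, tolerance = 1e-9)
    expect_equal(f$R, abs(cor(t, y)), tolerance = 1e-12)
    expect_gte(f$R, 0); expect_lte(f$R, 1)
  }
})

test_that("constant MF series gives a degenerate zero-slope fit with R = 0", {
  expect_warning(f <- fit_mf_line(mk_series(0:10, rep(120, 11))),
                 "zero variance")
  expect_equal(f$slope_A, 0)
  expect_equal(f$R, 0)
  expect_true(f$degenerate)
  expect_error(fit_mf_line(mk_series(0:1, c(1, 2))), "insufficient")
})

test_that("SMFDR averages training intercepts and terminal values", {
  fits <- lapply(c(135.6, 135.8, 136.0), function(b) {
    fit_mf_line(mk_series(c(0, 50, 100), c(b, b - 5, b - 10)))
  })
  m <- build_smfdr(fits, subject_id = "A", load_label = "4.5kg")
  expect_equal(m$mf0_bar, 135.8, tolerance = 1e-9)
  expect_equal(m$mfs_bar, 125.8, tolerance = 1e-9)
  expect_equal(m$n_train, 3)
  expect_true(m$usable)

  single <- build_smfdr(fits[[1]])
  expect_equal(single$mf0_bar, fits[[1]]$intercept_b)
  expect_equal(single$mfs_bar, fits[[1]]$mf_S)

  set.seed(32)
  rnd <- lapply(1:10, function(i) {
    fit_mf_line(mk_series(0:20, 130 - runif(1, 0, 0.2) * 0:20 + rnorm(21)))
  })
  m2 <- build_smfdr(rnd)
  expect_equal(m2$mf0_bar,
               sum(vapply(rnd, `[[`, numeric(1), "intercept_b")) / 10,
               tolerance = 1e-12)
  expect_error(build_smfdr(list()), "empty")
})

test_that("an upward MF trend is flagged as having no fatigue range", {
  up <- fit_mf_line(mk_series(c(0, 50, 100), c(120, 125, 130)))
  expect_warning(m <- build_smfdr(list(up)), "no fatigue range")
  expect_false(m$usable)
  expect_error(estimate_level(125, m, 3), "no fatigue range")
})

test_that("level boundaries tile the range contiguously with the documented centres", {
  m <- mk_smfdr(135.8, 122.4)
  b <- level_boundaries(m, 5)
  delta <- (135.8 - 122.4) / 4
  expect_equal(b$center_hz, 135.8 - (0:4) * delta, tolerance = 1e-9)
  expect_equal(b$upper_hz - b$lower_hz, rep(delta, 5), tolerance = 1e-9)
  expect_equal(b$lower_hz[-5], b$upper_hz[-1], tolerance = 1e-12)  # no gaps
  expect_equal(b$LF, (0:4) / 4)

  b2 <- level_boundaries(m, 2)
  expect_equal(nrow(b2), 2)
  expect_equal(b2$upper_hz[1] - b2$lower_hz[1], 135.8 - 122.4, tolerance = 1e-9)

  expect_error(level_boundaries(m, 1), ">= 2")
})

test_that("range endpoints quantize to the extreme levels", {
  m <- mk_smfdr()
  for (N in 2:6) {
    at0 <- estimate_level(m$mf0_bar, m, N)
    expect_equal(at0$k, 0L)
    expect_equal(at0$LF, 0)
    at1 <- estimate_level(m$mfs_bar, m, N)
    expect_equal(at1$k, N - 1L)
    expect_equal(at1$LF, 1)
  }
  e <- estimate_level(130, m, 5)
  expect_equal(e$k, oracle_level(130, m$mf0_bar, m$mfs_bar, 5))
  expect_error(estimate_level(NaN, m, 3), "finite")
})

test_that("the quantizer matches the brute-force interval scan, including ties and clamps", {
  set.seed(33)
  for (i in 1:500) {
    m <- mk_smfdr(runif(1, 90, 140), runif(1, 60, 88))
    # use the calibrated values so boundary ties are exact in both routes
    mf0 <- m$mf0_bar
    mfs <- m$mfs_bar
    N <- sample(2:6, 1)
    y <- runif(1, mfs - 10, mf0 + 10)
    expect_equal(estimate_level(y, m, N)$k,
                 oracle_level(y, mf0, mfs, N))
    # exact boundary tie of a random interval edge
    k <- sample(0:(N - 1), 1)
    delta <- (mf0 - mfs) / (N - 1)
    y_tie <- mf0 - (2 * k + 1) * delta / 2
    expect_equal(estimate_level(y_tie, m, N)$k,
                 oracle_level(y_tie, mf0, mfs, N))
  }
})

test_that("the inverted out-of-range policy swaps only the clamps", {
  m <- mk_smfdr(135.8, 122.4)
  inside <- estimate_level(130, m, 5, out_of_range = "inverted")
  expect_equal(inside$k, estimate_level(130, m, 5)$k)
  expect_equal(estimate_level(140, m, 5, out_of_range = "inverted")$k, 4L)
  expect_equal(estimate_level(110, m, 5, out_of_range = "inverted")$k, 0L)
})

test_that("trajectories are monotone and visit every level in order", {
  m <- mk_smfdr(135.8, 122.4)
  # fit descending exactly from mf0_bar to mfs_bar over [0, 100]
  f <- fit_mf_line(mk_series(c(0, 50, 100), c(135.8, 129.1, 122.4)))
  traj <- fatigue_trajectory(f, m, N = 3, times = seq(0, 100, by = 0.5))
  expect_true(all(diff(traj$LF) >= 0))
  expect_equal(unique(traj$LF), c(0, 0.5, 1))
  expect_equal(traj$LF[1], 0)
  expect_equal(traj$LF[nrow(traj)], 1)
  # analytic boundary crossings: y = 135.8 - 0.134 t crosses the k=0/1
  # boundary (mf0 - delta/2) at t = delta/(2*0.134) and the next one delta later
  delta <- (135.8 - 122.4) / 2
  slope <- -0.134
  t1 <- delta / 2 / abs(slope)
  expect_equal(max(traj$time_s[traj$LF == 0]), t1, tolerance = 0.5)

  flat <- fit_mf_line(mk_series(c(0, 50, 100), c(135.8, 135.8 - 1e-9, 135.8)))
  tf <- fatigue_trajectory(flat, m, N = 4, times = seq(0, 100, by = 5))
  expect_true(all(tf$LF == 0))
})

test_that("coarsening N never reverses the fatigue ordering", {
  m <- mk_smfdr(135.8, 122.4)
  set.seed(34)
  y <- runif(200, 120, 138)
  k5 <- estimate_level(y, m, 5)$k
  k2 <- estimate_level(y, m, 2)$k
  for (i in 1:199) for (j in (i + 1):200) {
    if (k5[i] + 2 <= k5[j]) expect_lte(k2[i], k2[j])
  }
})

test_that("SMFDR models survive a JSON round-trip", {
  m <- mk_smfdr(135.8, 122.4)
  path <- tempfile(fileext = ".json")
  write_smfdr(m, path, params = list(window_ms = 10240))
  back <- read_smfdr(path)
  expect_equal(back$mf0_bar, m$mf0_bar, tolerance = 1e-12)
  expect_equal(back$mfs_bar, m$mfs_bar, tolerance = 1e-12)
  expect_equal(back$n_train, m$n_train)
  expect_equal(back$subject_id, "A")
  expect_true(back$usable)
  expect_equal(attr(back, "params")$window_ms, 10240)
})
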