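# Even resampling, Welch PSD, band integration.

test_that("resampling is the identity on an already-uniform series and linear in between", {
  tt <- seq(0.1, 10, by = 0.1)
  b <- beats_from(sbp = sin(tt) + 120, pint = rep(100, length(tt)), t = tt)
  es <- resample_evenly(b, rate = 10)
  keep <- match(round(es$window_start + seq_along(es$values) / 10 - 0.1, 6),
                round(tt, 6))
  expect_equal(es$values, (sin(tt) + 120)[keep[!is.na(keep)]], tolerance = 1e-9)
  # two-beat linear ramp interpolates on the straight line
  b2 <- beats_from(sbp = c(100, 110), pint = c(1000, 1000), t = c(0, 1),
                   map = c(90, 100))
  es2 <- resample_evenly(b2, rate = 10, min_beats = 2)
  expect_equal(es2$values, seq(100, 110, by = 1), tolerance = 1e-9)
})

test_that("sparse or gappy windows are invalid, not silently zero", {
  b <- beats_from(sbp = rep(120, 5), pint = rep(200, 5))
  expect_null(resample_evenly(b, rate = 10))                 # too few beats
  tt <- c(seq(0.2, 3, by = 0.2), seq(8, 12, by = 0.2))       # 5-s gap
  b2 <- beats_from(sbp = rep(120, length(tt)), pint = rep(200, length(tt)),
                   t = tt)
  expect_null(resample_evenly(b2, rate = 10, max_gap_s = 2))
})

test_that("the resampled dominant frequency matches the injected oscillation", {
  p <- 1000 / 6                       # HR 360
  tt <- cumsum(rep(p / 1000, 1200))
  sbp <- 120 + 2 * sin(2 * pi * 0.4 * tt)
  b <- beats_from(sbp = sbp, pint = rep(p, 1200), t = tt)
  ps <- estimate_psd(resample_evenly(b, 10), segment_s = 60)
  expect_equal(ps$freq[which.max(ps$density)], 0.4, tolerance = 0.02)
})

test_that("Welch PSD satisfies Parseval on noise and concentrates a sine's power", {
  set.seed(10)
  x <- rnorm(6000, 0, 2)
  ps <- estimate_psd(even_series(x, 10), segment_s = 60)
  expect_equal(sum(ps$density) * ps$resolution, var(x), tolerance = 0.05)
  tt <- seq(0, 600 - 0.1, by = 0.1)
  s <- 3 * sin(2 * pi * 0.5 * tt)
  pss <- estimate_psd(even_series(s, 10), segment_s = 60)
  expect_equal(sum(pss$density) * pss$resolution, 3^2 / 2, tolerance = 0.01)
  expect_equal(band_power(pss, 0.4, 0.6), 3^2 / 2, tolerance = 0.01)
  expect_lt(band_power(pss, 1, 2), 0.01 * 3^2 / 2)
  expect_error(estimate_psd(even_series(rnorm(100), 10), segment_s = 60),
               "segment longer")
})

test_that("band integration is a trapezoid with interpolated edges, exactly additive", {
  psd <- structure(list(freq = seq(0, 5, by = 0.1),
                        density = rep(1, 51), resolution = 0.1, nyquist = 5),
                   class = "bp_psd")
  expect_equal(band_power(psd, 0.27, 0.75), 0.48)
  expect_equal(band_power(psd, 0.75, 3.3), 2.55)
  set.seed(11)
  psd$density <- runif(51)
  expect_equal(band_power(psd, 0.27, 0.75) + band_power(psd, 0.75, 3.3),
               band_power(psd, 0.27, 3.3), tolerance = 1e-12)
  # all power in a single bin inside LF: lf gets it all, hf none
  d0 <- rep(0, 51); d0[6] <- 10     # 0.5 Hz
  psd$density <- d0
  expect_equal(band_power(psd, 0.27, 0.75), 10 * 0.1, tolerance = 1e-12)
  expect_equal(band_power(psd, 0.75, 3.3), 0)
  expect_error(band_power(psd, 4, 6), "outside")
})

test_that("hourly LF cadence yields one window per hour and flags invalid ones", {
  p <- make_strain_preset("WKY")
  b <- simulate_beats(p, sim_config(duration_hours = 3, seed = 21))
  lf <- lf_sbp_series(b)
  expect_equal(nrow(lf), 3)
  expect_equal(lf$window_start, c(0, 3600, 7200))
  expect_true(all(lf$valid))
  expect_true(all(lf$lf > 0 & lf$hf > 0))
  # drop the beats of hour 2's analysis window -> that hour goes invalid
  keep <- !(b$systolic_time >= 3600 & b$systolic_time < 3900)
  b2 <- beat_series(as.data.frame(b)[keep, ], start_clock = 20)
  lf2 <- lf_sbp_series(b2)
  expect_false(lf2$valid[2])
  expect_true(is.na(lf2$lf[2]))
})
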