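# Synthetic-cohort generator: presets, determinism, conservation, drug nulls.

test_that("built-in strain presets carry the published dark/light MAP means", {
  w <- make_strain_preset("WKY")
  expect_equal(c(w$map_dark, w$map_light), c(102.1, 94.4))
  s <- make_strain_preset("SHR")
  expect_equal(c(s$map_dark, s$map_light), c(142.0, 134.8))
  cp <- make_strain_preset("SHRcp")
  expect_equal(cp$map_dark - cp$map_light, 1.7, tolerance = 1e-9)
  # reported orderings: SHRcp gain below, LF amplitude above, WKY
  expect_lt(cp$brg_true, w$brg_true)
  expect_gt(cp$lf_amp, w$lf_amp)
  expect_error(make_strain_preset("nope"), "unknown strain preset")
})

test_that("preset validity rejects out-of-band frequencies and absurd rates", {
  expect_error(register_strain_preset("bad1", lf_freq = 0.2), "LF band")
  expect_error(register_strain_preset("bad2", hf_freq = 3.3), "HF band")
  expect_error(register_strain_preset("bad3", hr_dark = 150), "200")
  expect_error(register_strain_preset("bad4", noise_sd = -1), "non-negative")
})

test_that("quiet generator gives constant per-beat MAP and exact intervals", {
  b <- simulate_beats(quiet_preset(map = 100, hr = 360),
                      sim_config(duration_hours = 1, seed = 1))
  expect_true(all(abs(b$map - 100) < 1e-9))
  expect_true(all(abs(b$pulse_interval - 60000 / 360) < 1e-9))
  expect_true(all(b$dbp <= b$map & b$map <= b$sbp))
})

test_that("identical seeds reproduce waveforms and cohorts bit-for-bit", {
  cfg <- sim_config(duration_hours = 1, seed = 33)
  a <- simulate_waveform(make_strain_preset("WKY"), cfg)
  b <- simulate_waveform(make_strain_preset("WKY"), cfg)
  expect_identical(a$waveform$samples, b$waveform$samples)
  cfg2 <- sim_config(duration_hours = 1, seed = 33, n_animals = 3)
  c1 <- simulate_cohort(make_strain_preset("SHR"), cfg2, waveform = FALSE)
  c2 <- simulate_cohort(make_strain_preset("SHR"), cfg2, waveform = FALSE)
  expect_identical(c1$animals[[2]]$beats$sbp, c2$animals[[2]]$beats$sbp)
  # different animals get different realizations
  expect_false(identical(c1$animals[[1]]$beats$sbp, c1$animals[[2]]$beats$sbp))
})

test_that("period MAP conservation: trace time-average matches the profile", {
  # steady dark-period segment, realistic noise: time-average over the
  # period approaches the preset level within a few SEM
  p <- make_strain_preset("WKY")
  b <- simulate_beats(p, sim_config(duration_hours = 4, seed = 12))
  dark <- in_dark(b$systolic_time)
  expect_true(all(dark))
  # first 30 min are the transition ramp from the light level
  steady <- b$systolic_time > 1800
  expect_lt(abs(mean(b$map[steady]) - p$map_dark), 0.5)
})

test_that("zero-dose schedule leaves the stream identical to untreated", {
  zero <- drug_schedule(dose_by_week = c(0, 0))
  cfg <- sim_config(duration_hours = 2, seed = 9)
  p <- make_strain_preset("SHRcp")
  a <- simulate_beats(p, cfg)
  b <- simulate_beats(p, cfg, schedule = zero)
  expect_identical(a$sbp, b$sbp)
  expect_identical(a$pulse_interval, b$pulse_interval)
})

test_that("cohort jitter: zero jitter replicates the preset, centred draws keep the group mean", {
  p <- make_strain_preset("WKY")
  cfg <- sim_config(duration_hours = 1, seed = 5, n_animals = 5)
  co0 <- simulate_cohort(p, cfg, jitter = cohort_jitter(0, 0, 0, 0, 0),
                         waveform = FALSE)
  tr <- co0$truth
  expect_true(all(vapply(tr, function(x) x$target_map_dark, 1) == p$map_dark))
  co <- simulate_cohort(p, cfg, waveform = FALSE)
  dk <- vapply(co$truth, function(x) x$target_map_dark, 1)
  lt <- vapply(co$truth, function(x) x$target_map_light, 1)
  expect_equal(mean(dk), p$map_dark, tolerance = 1e-9)
  expect_equal(mean(lt), p$map_light, tolerance = 1e-9)
  expect_gt(stats::sd(dk), 0)
  expect_error(simulate_cohort(list(), cfg), "non-empty")
})

test_that("biomarker tables honour cell specs, seeds, and the lognormal option", {
  eff <- expand.grid(strain = c("W", "S"), period = c("dark", "light"))
  eff$mean <- c(10, 20, 10, 20); eff$sd <- 1
  t1 <- make_biomarker_tables(eff, n_per_cell = 5, seed = 3)
  t2 <- make_biomarker_tables(eff, n_per_cell = 5, seed = 3)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 20)
  expect_equal(length(unique(t1$animal)), 20)
  eff$dist <- "lognormal"
  eff$sd <- eff$mean                 # heavy-tailed cells
  t3 <- make_biomarker_tables(eff, n_per_cell = 500, seed = 4)
  m <- tapply(t3$value, interaction(t3$strain, t3$period), mean)
  expect_equal(as.numeric(m), eff$mean, tolerance = 0.2)
  x <- t3$value[t3$strain == "S" & t3$period == "dark"]
  expect_gt(mean((x - mean(x))^3), 0)   # right-skewed draws
  expect_error(make_biomarker_tables(eff, n_per_cell = 1), "n_per_cell")
})
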