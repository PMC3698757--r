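# Telemetry binning, period summaries, dipper calls, dose-response deltas.

test_that("telemetry binning follows the 30-s-every-5-min cadence", {
  b <- simulate_beats(quiet_preset(map = 100, hr = 360),
                      sim_config(duration_hours = 2, seed = 1))
  bins <- bin_telemetry(b)
  expect_equal(nrow(bins), 24)                      # 2 h / 5 min
  expect_true(all(bins$valid))
  expect_true(all(abs(bins$map - 100) < 1e-6))
  expect_true(all(abs(bins$hr - 360) < 0.5))
  # only beats in the first 30 s of each bin contribute (~180 at HR 360)
  expect_true(all(bins$n_beats >= 178 & bins$n_beats <= 182))
})

test_that("a 24-h recording yields 288 bins that partition into 144+144 dark/light", {
  b <- simulate_beats(quiet_preset(hr = 330), sim_config(duration_hours = 24, seed = 2))
  bins <- bin_telemetry(b)
  expect_equal(nrow(bins), 288)
  per <- in_dark(bins$bin_start)
  expect_equal(sum(per), 144)
  ps <- period_summary(bins, animal = 7L)
  expect_equal(sum(ps$n_bins), sum(bins$valid))
  expect_equal(sort(unique(ps$period)), c("dark", "light"))
  expect_true(all(ps$animal == 7L))
})

test_that("square-wave dark/light levels give exact period means", {
  # hand-built bins: dark 110, light 100 (recording starts at dark onset)
  t <- seq(0, 86100, by = 300)
  bins <- data.frame(bin_start = t,
                     map = ifelse(in_dark(t), 110, 100),
                     hr = 300, activity = NA_real_, n_beats = 10L,
                     valid = TRUE)
  ps <- period_summary(bins, schedule = light_schedule(), start_clock = 20)
  expect_equal(ps$mean_map[ps$period == "dark"], 110)
  expect_equal(ps$mean_map[ps$period == "light"], 100)
  expect_equal(ps$n_bins, c(144, 144))
})

test_that("identical dark and light values classify as nondipper with zero dip", {
  s <- data.frame(animal = rep(1:5, each = 2), day = 0,
                  period = rep(c("dark", "light"), 5),
                  mean_map = 120, mean_hr = 300, mean_activity = NA,
                  n_bins = 144)
  call <- classify_dipper(s)
  expect_equal(call$classification, "nondipper")
  expect_equal(call$dip_percent, 0)
  expect_equal(call$p_value, 1)
})

test_that("a clear 8-mmHg dip over 7 days classifies as dipper", {
  set.seed(31)
  s <- data.frame(animal = 1, day = rep(0:6, each = 2),
                  period = rep(c("dark", "light"), 7),
                  mean_map = rep(c(108, 100), 7) + rnorm(14, 0, 0.5),
                  mean_hr = 300, mean_activity = NA, n_bins = 144)
  call <- classify_dipper(s)
  expect_equal(call$classification, "dipper")
  expect_lt(call$p_value, 0.05)
  expect_equal(call$n_pairs, 7)
  expect_error(classify_dipper(s[s$day < 2, ]), "at least 3")
})

test_that("dipper calls control their false-positive rate on zero-dip cohorts", {
  # flat-profile cohorts with per-animal level jitter only: dipper calls
  # should occur at about the test's alpha
  set.seed(77)
  calls <- replicate(300, {
    lev <- rnorm(5, 120, 2)
    noise <- matrix(rnorm(10, 0, 1), 5)
    s <- data.frame(animal = rep(1:5, each = 2), day = 0,
                    period = rep(c("dark", "light"), 5),
                    mean_map = as.vector(rbind(lev + noise[, 1],
                                               lev + noise[, 2])),
                    mean_hr = 300, mean_activity = NA, n_bins = 144)
    classify_dipper(s)$classification == "dipper"
  })
  # one-sided binomial bound: alpha 0.05 -> <= 0.05 + 3 MC SE, halved for
  # the directional requirement (light < dark)
  expect_lt(mean(calls), 0.05 + 3 * sqrt(0.05 * 0.95 / 300))
})

test_that("dose-response deltas are zero on identical data and recover planted effects", {
  base <- data.frame(animal = rep(1:3, each = 2), day = 0,
                     period = rep(c("dark", "light"), 3),
                     mean_map = c(130, 125, 132, 126, 131, 124))
  tr <- base; tr$dose <- 1
  dr <- dose_response(base, tr)
  expect_true(all(dr$delta_map == 0))
  tr2 <- base; tr2$dose <- 1; tr2$mean_map <- tr2$mean_map - 15
  dr2 <- dose_response(base, tr2, strain = "SHRcp")
  expect_true(all(dr2$delta_map == -15))
  expect_true(all(dr2$strain == "SHRcp"))
  expect_error(dose_response(base[0, ], tr2), "baseline")
  expect_error(dose_response(base, base), "dose")
})

test_that("weekly dose lookup matches the escalation calendar", {
  sch <- drug_schedule(start_day = 7)
  expect_equal(dose_of_day(c(0, 6, 7, 13, 14, 21, 27, 28), sch),
               c(0, 0, 0.1, 0.1, 0.3, 1.0, 1.0, 0))
})

test_that("generator dose effects are recovered through binning and summaries", {
  # 2 baseline days + the first treatment week at 1.0 mg/kg (-15 mmHg)
  sch <- drug_schedule(dose_by_week = 1.0, start_day = 2)
  b <- simulate_beats(make_strain_preset("SHRcp"),
                      sim_config(duration_hours = 9 * 24, seed = 13),
                      schedule = sch)
  ps <- period_summary(bin_telemetry(b), animal = 1)
  ps$dose <- dose_of_day(ps$day, sch)
  dr <- dose_response(ps[ps$day < 2, ], ps[ps$day == 8, ])
  expect_equal(nrow(dr), 2)
  expect_equal(dr$delta_map, c(-15, -15), tolerance = 1 / 15)
})
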