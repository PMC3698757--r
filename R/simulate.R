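# Seeded synthetic telemetry generator with known ground truth.
#
# The generator works beat-by-beat: per-beat baseline MAP follows the
# dark/light profile (half-cosine 30-min transitions) plus drug effect and
# activity-linked slow wander; SBP adds LF (Mayer-wave) and HF (respiratory)
# sinusoids plus white noise on top of baseline + half the pulse pressure;
# the pulse interval couples to the SBP deviation with slope +brg_true
# (reflex bradycardia: higher SBP -> longer interval), delayed by a
# configurable number of beats. Beat times are the fixed point of
# t[i+1] = t[i] + PI(t, SBP(t))/1000, solved by a short vectorized
# fixed-point iteration (the feedback is weak, convergence is sub-ns).
#
# The continuous waveform is rendered from the beat series as two half-cosine
# arcs per beat, peak-aligned: between troughs the pressure is
# m_i + A_i * cos(pi * (t - T_i) / halfwidth), so the peak value is exactly
# the per-beat SBP, the peak-to-peak interval exactly the generated pulse
# interval, and the within-beat time average exactly the per-beat MAP.

#' Simulate a per-beat series for one animal
#'
#' The beat-domain core of the generator; [simulate_waveform()] renders its
#' output into a continuous pressure trace. Identical seeds give bit-identical
#' output.
#'
#' @param preset A [make_strain_preset()] result.
#' @param config A [sim_config()].
#' @param schedule Optional [drug_schedule()].
#' @param seed Seed; defaults to `config$seed`.
#' @param brg_delay Baroreflex coupling delay in beats (default 0): the pulse
#'   interval of beat `i + brg_delay` responds to the SBP of beat `i`.
#' @param activity_gain MAP wander SD in mmHg per activity count (the
#'   activity-linked noise component; AR(1) with ~2-min correlation time).
#' @return A [beat_series()] with a `truth` attribute (see
#'   [ground_truth()]).
#' @export
simulate_beats <- function(preset, config, schedule = NULL,
                           seed = config$seed, brg_delay = 0L,
                           activity_gain = 0.4) {
  stopifnot(inherits(preset, "strain_preset"), inherits(config, "sim_config"))
  dur <- config$duration_hours * 3600
  light <- config$schedule
  sc <- config$start_clock
  with_seed(seed, {
    n_max <- ceiling(dur / (60 / (max(preset$hr_dark, preset$hr_light) + 60))) + 16L
    eps <- stats::rnorm(n_max)       # SBP white noise
    eta <- stats::rnorm(n_max)       # pulse-interval white noise
    z <- stats::rnorm(n_max)         # wander innovations
    # activity-linked MAP wander: unit AR(1) over beats, tau ~ 120 s
    mean_pi_s <- 60 / mean(c(preset$hr_dark, preset$hr_light))
    rho <- exp(-mean_pi_s / 120)
    u <- as.numeric(stats::filter(z * sqrt(1 - rho^2), rho,
                                  method = "recursive"))
    # slowly varying profiles on a uniform lookup grid; the sequential
    # beat-stream kernel interpolates them at each realized beat time
    grid_dt <- 5
    tg <- seq(0, dur + grid_dt, by = grid_dt)
    drug <- drug_effect_profile(tg, schedule, light, sc)
    dark <- in_dark(tg, light, sc)
    map0 <- dark_light_profile(tg, preset$map_dark, preset$map_light,
                               light, sc) +
      ifelse(dark, drug$map_dark, drug$map_light)
    hr0 <- dark_light_profile(tg, preset$hr_dark, preset$hr_light, light, sc)
    lfamp <- dark_light_profile(tg, preset$lf_amp, preset$lf_amp_light,
                                light, sc) * drug$lf_factor
    wsd <- activity_gain * dark_light_profile(tg, preset$activity_dark,
                                              preset$activity_light, light, sc)
    brg0 <- preset$brg_true + drug$brg
    pp2 <- preset$pulse_pressure / 2
    st <- .gen_beat_stream(dur, 0.25, grid_dt, map0, hr0, lfamp, wsd, brg0,
                           preset$lf_freq, preset$hf_amp, preset$hf_freq,
                           preset$noise_sd, preset$pi_noise_sd, pp2,
                           eps, eta, u, as.integer(brg_delay))
    df <- data.frame(systolic_time = st$t, sbp = st$sbp,
                     dbp = 2 * st$map - st$sbp, map = st$map,
                     pulse_interval = st$pint)
    beats <- beat_series(df, schedule = light, start_clock = sc)
    attr(beats, "truth") <- ground_truth(preset, config, schedule, seed,
                                         brg_delay, activity_gain)
    beats
  })
}

#' Ground-truth record for a simulated animal
#'
#' Everything needed to score parameter recovery without re-reading the
#' configuration: the preset actually used (after any cohort jitter), the
#' drug schedule, seeds, and the target dark/light period MAP means.
#'
#' @inheritParams simulate_beats
#' @return A named list (class `ground_truth`).
#' @export
ground_truth <- function(preset, config, schedule = NULL, seed = config$seed,
                         brg_delay = 0L, activity_gain = 0.4) {
  structure(list(preset = unclass(preset),
                 target_map_dark = preset$map_dark,
                 target_map_light = preset$map_light,
                 brg_true = preset$brg_true,
                 lf_power_true = preset$lf_amp^2 / 2,
                 seed = seed, brg_delay = brg_delay,
                 activity_gain = activity_gain,
                 duration_hours = config$duration_hours,
                 sample_rate = config$sample_rate,
                 dosed = !is.null(schedule),
                 dose_by_week = if (!is.null(schedule)) schedule$dose_by_week),
            class = "ground_truth")
}

#' Render a beat series into a continuous pressure waveform
#'
#' @param beats A generator [beat_series()].
#' @param sample_rate Sampling rate in Hz.
#' @return A [bp_waveform()].
#' @export
render_waveform <- function(beats, sample_rate) {
  tk <- beats$systolic_time
  nb <- length(tk)
  stopifnot(nb >= 2)
  dur <- tk[nb] + beats$pulse_interval[nb] / 1000
  ts <- seq(0, dur - 1 / sample_rate, by = 1 / sample_rate)
  # nearest peak: troughs (midpoints between peaks) delimit each beat's arc
  mids <- (tk[-nb] + tk[-1]) / 2
  j <- findInterval(ts, mids) + 1L            # index of nearest peak
  d <- ts - tk[j]
  half_prev <- c(tk[2] - tk[1], diff(tk)) / 2  # left half-width per peak
  half_next <- c(diff(tk), tk[nb] - tk[nb - 1]) / 2
  half <- ifelse(d < 0, half_prev[j], half_next[j])
  amp <- beats$sbp[j] - beats$map[j]
  # clamp the arc phase so the trace holds at the trough outside the first
  # and last half-beats instead of extrapolating extra oscillations
  p <- beats$map[j] + amp * cos(pi * pmin(pmax(d / half, -1), 1))
  if (any(p < 0)) {
    warning(sum(p < 0), " negative pressure samples clipped to 0")
    p[p < 0] <- 0
  }
  bp_waveform(p, sample_rate, schedule = attr(beats, "schedule"),
              start_clock = attr(beats, "start_clock"))
}

#' Simulate a continuous arterial-pressure waveform
#'
#' @inheritParams simulate_beats
#' @return List with elements `waveform` (a [bp_waveform()]), `beats` (the
#'   generator's true [beat_series()]) and `truth` (a [ground_truth()]).
#' @export
simulate_waveform <- function(preset, config, schedule = NULL,
                              seed = config$seed, ...) {
  if (config$sample_rate < 4 * preset$hf_freq)
    stop("sample_rate violates the Nyquist margin (need >= 4 * hf_freq)")
  beats <- simulate_beats(preset, config, schedule, seed = seed, ...)
  wf <- render_waveform(beats, config$sample_rate)
  list(waveform = wf, beats = beats, truth = attr(beats, "truth"))
}

#' Between-animal jitter specification for cohorts
#'
#' Per-animal deviations around the strain-preset group means. The MAP
#' deviation has two components: a level shift common to both periods
#' (`level_sd`) and a circadian-dip component (`dip_sd`) split `+D/2` into the
#' dark and `-D/2` into the light period, so animals differ in how much their
#' pressure dips at lights-on. With the defaults (level 2, dip 3 mmHg) a
#' 5-animal group shows a period-mean SEM of roughly 1 mmHg, matching
#' published telemetry baselines at n = 5. Draws are centred within the
#' cohort (sum to zero) because the preset specifies the group mean itself.
#'
#' @param level_sd SD of the shared dark+light MAP shift, mmHg.
#' @param dip_sd SD of the dark-minus-light dip deviation, mmHg.
#' @param hr_sd SD of the heart-rate shift (both periods), beats/min.
#' @param brg_cv,lf_cv Coefficients of variation of the baroreflex gain and
#'   LF amplitude.
#' @param centered Centre each draw within the cohort (default `TRUE`).
#' @return A `cohort_jitter` list.
#' @export
cohort_jitter <- function(level_sd = 2, dip_sd = 3, hr_sd = 10,
                          brg_cv = 0.1, lf_cv = 0.1, centered = TRUE) {
  structure(list(level_sd = level_sd, dip_sd = dip_sd, hr_sd = hr_sd,
                 brg_cv = brg_cv, lf_cv = lf_cv, centered = centered),
            class = "cohort_jitter")
}

jitter_presets <- function(preset, n, jitter, seed) {
  with_seed(seed, {
    draw <- function(sd) {
      if (sd == 0 || n == 1) return(numeric(n))
      x <- stats::rnorm(n, 0, sd)
      if (isTRUE(jitter$centered)) x - mean(x) else x
    }
    L <- draw(jitter$level_sd)
    D <- draw(jitter$dip_sd)
    H <- draw(jitter$hr_sd)
    B <- draw(jitter$brg_cv * preset$brg_true)
    A <- draw(jitter$lf_cv * preset$lf_amp)
    lapply(seq_len(n), function(i) {
      p <- unclass(preset)
      p$map_dark <- p$map_dark + L[i] + D[i] / 2
      p$map_light <- p$map_light + L[i] - D[i] / 2
      p$hr_dark <- min(max(p$hr_dark + H[i], 200), 500)
      p$hr_light <- min(max(p$hr_light + H[i], 200), 500)
      p$brg_true <- max(p$brg_true + B[i], 0)
      sc <- if (p$lf_amp > 0) (p$lf_amp + A[i]) / p$lf_amp else 1
      p$lf_amp <- max(p$lf_amp + A[i], 0)
      p$lf_amp_light <- max(p$lf_amp_light * sc, 0)
      validate_strain_preset(structure(p, class = "strain_preset"))
    })
  })
}

#' Simulate a cohort of animals
#'
#' Per-animal seeds are derived deterministically from the master seed
#' (counter-based), so cohorts are reproducible and insensitive to
#' generation order.
#'
#' @param presets A single [make_strain_preset()] (replicated with
#'   [cohort_jitter()] deviations) or a list of `config$n_animals` presets
#'   (used as-is, no jitter).
#' @inheritParams simulate_beats
#' @param jitter A [cohort_jitter()]; use `cohort_jitter(0, 0, 0, 0, 0)` for
#'   identical animals.
#' @param waveform Render the continuous waveform for each animal (`TRUE`,
#'   default) or return only beat series (`FALSE`; much lighter for long
#'   multi-day designs).
#' @return List with `animals` (per-animal lists as in [simulate_waveform()])
#'   and `truth` (list of per-animal [ground_truth()] records).
#' @export
simulate_cohort <- function(presets, config, schedule = NULL,
                            jitter = cohort_jitter(), waveform = TRUE, ...) {
  n <- config$n_animals
  if (inherits(presets, "strain_preset")) {
    presets <- jitter_presets(presets, n, jitter,
                              seed = animal_seed(config$seed, 0L))
  }
  if (!is.list(presets) || !length(presets))
    stop("presets must be a strain_preset or a non-empty list of them")
  if (length(presets) != n)
    stop("need one preset per animal (", n, ")")
  animals <- lapply(seq_len(n), function(i) {
    s <- animal_seed(config$seed, i)
    if (waveform) {
      res <- simulate_waveform(presets[[i]], config, schedule, seed = s, ...)
    } else {
      b <- simulate_beats(presets[[i]], config, schedule, seed = s, ...)
      res <- list(waveform = NULL, beats = b, truth = attr(b, "truth"))
    }
    res$animal <- i
    res
  })
  list(animals = animals, truth = lapply(animals, `[[`, "truth"))
}
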