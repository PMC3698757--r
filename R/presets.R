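# Strain presets, drug schedules, and simulation configuration.

#' Spectral bands of rat blood-pressure variability
#'
#' Band edges in Hz: `LF_BAND` is the low-frequency (Mayer-wave) band of
#' systolic-pressure variability, whose integrated power indexes vasomotor
#' sympathetic tone in the rat; `HF_BAND` is the high-frequency band carrying
#' the respiratory oscillation.
#' @name bands
#' @export
LF_BAND <- c(0.27, 0.75)

#' @rdname bands
#' @export
HF_BAND <- c(0.75, 3.30)

.preset_registry <- new.env(parent = emptyenv())

new_strain_preset <- function(name, map_dark, map_light, pulse_pressure,
                              hr_dark, hr_light, lf_amp, lf_amp_light = lf_amp,
                              lf_freq, hf_amp, hf_freq, brg_true, noise_sd,
                              pi_noise_sd = 1, activity_dark, activity_light) {
  p <- list(name = name, map_dark = map_dark, map_light = map_light,
            pulse_pressure = pulse_pressure, hr_dark = hr_dark,
            hr_light = hr_light, lf_amp = lf_amp, lf_amp_light = lf_amp_light,
            lf_freq = lf_freq, hf_amp = hf_amp, hf_freq = hf_freq,
            brg_true = brg_true, noise_sd = noise_sd,
            pi_noise_sd = pi_noise_sd,
            activity_dark = activity_dark, activity_light = activity_light)
  validate_strain_preset(structure(p, class = "strain_preset"))
}

validate_strain_preset <- function(p) {
  stopifnot(inherits(p, "strain_preset"))
  num <- c("map_dark", "map_light", "pulse_pressure", "hr_dark", "hr_light",
           "lf_amp", "lf_amp_light", "lf_freq", "hf_amp", "hf_freq",
           "brg_true", "noise_sd", "pi_noise_sd",
           "activity_dark", "activity_light")
  for (f in num) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("strain_preset field '", f, "' must be a single non-negative number")
  }
  if (p$lf_freq <= LF_BAND[1] || p$lf_freq >= LF_BAND[2])
    stop("lf_freq must lie strictly inside the LF band (",
         LF_BAND[1], ", ", LF_BAND[2], ") Hz")
  if (p$hf_freq <= HF_BAND[1] || p$hf_freq >= HF_BAND[2])
    stop("hf_freq must lie strictly inside the HF band (",
         HF_BAND[1], ", ", HF_BAND[2], ") Hz")
  if (p$hr_dark < 200 || p$hr_dark > 500 || p$hr_light < 200 || p$hr_light > 500)
    stop("heart rates must lie in [200, 500] beats/min for a rat")
  p
}

#' Strain presets for synthetic telemetry cohorts
#'
#' Returns the generator parameter set for one of the built-in rat strains or
#' a preset previously added with [register_strain_preset()]. The dark/light
#' mean arterial pressure (MAP) levels of the three built-in strains are the
#' published 12-hour baseline means for these strains:
#' \describe{
#'   \item{WKY}{normotensive dipper control; MAP 102.1 (dark) / 94.4 (light) mmHg}
#'   \item{SHR}{dipper-type hypertensive; MAP 142.0 / 134.8 mmHg}
#'   \item{SHRcp}{nondipper-type hypertensive metabolic-syndrome model;
#'     MAP 133.4 / 131.7 mmHg (blunted 1.7-mmHg dip)}
#' }
#' All other fields (heart rates, pulse pressure, oscillation amplitudes,
#' baroreflex gain, noise levels, activity counts) are NOT published values:
#' they are physiologically plausible defaults, with only their ordering
#' constrained by the reported findings (SHRcp baroreflex gain below, and LF
#' amplitude above, WKY; heart rate slightly lower in SHR/SHRcp than WKY).
#'
#' @param name `"WKY"`, `"SHR"`, `"SHRcp"`, or the name of a registered preset.
#' @return A `strain_preset` object (named list).
#' @export
#' @examples
#' make_strain_preset("WKY")$map_dark  # 102.1
make_strain_preset <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.null(.preset_registry[[name]])) return(.preset_registry[[name]])
  switch(name,
    WKY = new_strain_preset("WKY",
      map_dark = 102.1, map_light = 94.4, pulse_pressure = 35,
      hr_dark = 330, hr_light = 300,
      lf_amp = 2.0, lf_amp_light = 1.2, lf_freq = 0.40,
      hf_amp = 1.0, hf_freq = 1.50,
      brg_true = 1.2, noise_sd = 1.0, pi_noise_sd = 1.0,
      activity_dark = 4, activity_light = 1),
    SHR = new_strain_preset("SHR",
      map_dark = 142.0, map_light = 134.8, pulse_pressure = 45,
      hr_dark = 320, hr_light = 290,
      lf_amp = 2.5, lf_amp_light = 1.5, lf_freq = 0.40,
      hf_amp = 1.0, hf_freq = 1.50,
      brg_true = 0.8, noise_sd = 1.0, pi_noise_sd = 1.0,
      activity_dark = 6, activity_light = 1.5),
    SHRcp = new_strain_preset("SHRcp",
      map_dark = 133.4, map_light = 131.7, pulse_pressure = 45,
      hr_dark = 310, hr_light = 285,
      lf_amp = 2.5, lf_amp_light = 2.3, lf_freq = 0.40,
      hf_amp = 1.0, hf_freq = 1.50,
      brg_true = 0.6, noise_sd = 1.0, pi_noise_sd = 1.0,
      activity_dark = 2, activity_light = 1),
    stop("unknown strain preset '", name, "'; known: WKY, SHR, SHRcp",
         if (length(ls(.preset_registry)))
           paste0(", ", paste(ls(.preset_registry), collapse = ", ")))
  )
}

#' Register a custom strain preset
#'
#' @param name Preset name.
#' @param ... Fields passed to the preset constructor; any field of a
#'   built-in preset may be given. Unspecified fields default from `base`.
#' @param base Name of the preset to use for unspecified fields.
#' @return The registered `strain_preset`, invisibly.
#' @export
register_strain_preset <- function(name, ..., base = "WKY") {
  p <- unclass(make_strain_preset(base))
  mods <- list(...)
  # lf_amp_light tracks lf_amp unless set explicitly
  if (!is.null(mods$lf_amp) && is.null(mods$lf_amp_light))
    mods$lf_amp_light <- mods$lf_amp
  bad <- setdiff(names(mods), names(p))
  if (length(bad)) stop("unknown preset fields: ", paste(bad, collapse = ", "))
  p[names(mods)] <- mods
  p$name <- name
  p <- validate_strain_preset(structure(p, class = "strain_preset"))
  assign(name, p, envir = .preset_registry)
  invisible(p)
}

#' @export
print.strain_preset <- function(x, ...) {
  cat(sprintf("<strain_preset> %s\n", x$name))
  cat(sprintf("  MAP dark/light: %.1f / %.1f mmHg, pulse pressure %.0f mmHg\n",
              x$map_dark, x$map_light, x$pulse_pressure))
  cat(sprintf("  HR dark/light: %.0f / %.0f bpm\n", x$hr_dark, x$hr_light))
  cat(sprintf("  LF %.2g mmHg (light %.2g) @ %.2f Hz; HF %.2g mmHg @ %.2f Hz\n",
              x$lf_amp, x$lf_amp_light, x$lf_freq, x$hf_amp, x$hf_freq))
  cat(sprintf("  baroreflex gain %.2g ms/mmHg; SBP noise %.2g mmHg, PI noise %.2g ms\n",
              x$brg_true, x$noise_sd, x$pi_noise_sd))
  invisible(x)
}

#' Dose-escalating drug schedule
#'
#' Once-daily oral dosing at dark onset (the start of the animal's active
#' period), with the dose escalated weekly. The default dose ladder is
#' 0.1, 0.3 and 1.0 mg/kg for weeks 1, 2 and 3. Effects are sustained: each
#' dose's effect holds constant from its dosing time until the next dose
#' (optionally with exponential decay). Effect magnitudes are generator free
#' parameters (not published values); the default MAP effect is monotone in
#' dose and equal in both periods.
#'
#' @param dose_by_week Numeric vector of doses (mg/kg), one per treatment week.
#' @param start_day Analysis-day index (0-based, days anchored at dark onset)
#'   of the first dose. Default 0.
#' @param effect_map Data frame with columns `dose`, `dark`, `light`: MAP
#'   change (mmHg, negative = reduction) per period at each dose.
#' @param effect_brg Data frame `dose`, `delta`: additive change of the
#'   baroreflex coupling gain (ms/mmHg).
#' @param effect_lf Data frame `dose`, `factor`: multiplicative factor on the
#'   LF oscillation amplitude.
#' @param decay_tau_h Optional exponential decay time constant (hours) of the
#'   effect after each dose; `Inf` (default) = sustained constant effect.
#' @param washout_weeks Weeks simulated after the last treatment week with
#'   zero effect. Default 0.
#' @return A `drug_schedule` object.
#' @export
drug_schedule <- function(dose_by_week = c(0.1, 0.3, 1.0),
                          start_day = 0,
                          effect_map = data.frame(
                            dose = c(0.1, 0.3, 1.0),
                            dark = c(-2, -6, -15),
                            light = c(-2, -6, -15)),
                          effect_brg = data.frame(
                            dose = c(0.1, 0.3, 1.0),
                            delta = c(0.05, 0.15, 0.4)),
                          effect_lf = data.frame(
                            dose = c(0.1, 0.3, 1.0),
                            factor = c(0.95, 0.9, 0.8)),
                          decay_tau_h = Inf,
                          washout_weeks = 0) {
  stopifnot(is.numeric(dose_by_week), all(dose_by_week >= 0),
            washout_weeks >= 0, decay_tau_h > 0)
  structure(list(dose_by_week = dose_by_week, start_day = start_day,
                 effect_map = effect_map, effect_brg = effect_brg,
                 effect_lf = effect_lf, decay_tau_h = decay_tau_h,
                 washout_weeks = washout_weeks),
            class = "drug_schedule")
}

#' @export
print.drug_schedule <- function(x, ...) {
  cat("<drug_schedule> weekly doses (mg/kg):",
      paste(x$dose_by_week, collapse = " -> "),
      sprintf("from day %d, dosed at dark onset\n", x$start_day))
  invisible(x)
}

# interpolate an effect column at a dose (0 dose => exactly 0 / identity)
.effect_at <- function(tab, col, dose, identity = 0) {
  if (dose <= 0) return(identity)
  if (nrow(tab) == 0) return(identity)
  stats::approx(c(0, tab$dose), c(identity, tab[[col]]), xout = dose,
                rule = 2)$y
}

#' Time course of drug effects along a recording
#'
#' Evaluates, at each time point, the active dose and its MAP / baroreflex /
#' LF-amplitude effects under a [drug_schedule()].
#'
#' @param t Seconds from recording start.
#' @param schedule A `drug_schedule`, or `NULL` for no treatment.
#' @param light A [light_schedule()].
#' @param start_clock Clock hour of recording start.
#' @return List with vectors `dose`, `map_dark`, `map_light`, `brg`, `lf_factor`.
#' @keywords internal
drug_effect_profile <- function(t, schedule, light = light_schedule(),
                                start_clock = light$dark_onset) {
  zero <- list(dose = numeric(length(t)) , map_dark = numeric(length(t)),
               map_light = numeric(length(t)), brg = numeric(length(t)),
               lf_factor = rep(1, length(t)))
  if (is.null(schedule)) return(zero)
  day <- day_index(t, light, start_clock)
  tweek <- (day - schedule$start_day) %/% 7L
  dose <- ifelse(day < schedule$start_day | tweek >= length(schedule$dose_by_week),
                 0, schedule$dose_by_week[pmax(tweek, 0) + 1L])
  dose[is.na(dose)] <- 0
  md <- ml <- db <- numeric(length(t)); lf <- rep(1, length(t))
  for (d in setdiff(unique(dose), 0)) {
    i <- dose == d
    md[i] <- .effect_at(schedule$effect_map, "dark", d)
    ml[i] <- .effect_at(schedule$effect_map, "light", d)
    db[i] <- .effect_at(schedule$effect_brg, "delta", d)
    lf[i] <- .effect_at(schedule$effect_lf, "factor", d, identity = 1)
  }
  if (is.finite(schedule$decay_tau_h)) {
    # seconds since the (daily, dark-onset) dose of the current day
    offset <- ((start_clock - light$dark_onset) %% 24) * 3600
    since <- (t + offset) %% 86400
    dec <- exp(-since / (schedule$decay_tau_h * 3600))
    md <- md * dec; ml <- ml * dec; db <- db * dec
    lf <- 1 + (lf - 1) * dec
  }
  list(dose = dose, map_dark = md, map_light = ml, brg = db, lf_factor = lf)
}

#' Simulation configuration
#'
#' @param sample_rate Waveform sampling rate, Hz. Default 250 Hz, of the
#'   order of implanted-telemetry acquisition rates and fine enough (4-ms
#'   spacing) for sub-millisecond systolic-peak timing after
#'   quadratic interpolation.
#' @param duration_hours Recording length in hours.
#' @param schedule A [light_schedule()].
#' @param start_clock Clock hour of recording start; defaults to dark onset.
#' @param seed Integer master seed.
#' @param n_animals Number of animals for cohort simulation.
#' @return A `sim_config` object.
#' @export
sim_config <- function(sample_rate = 250, duration_hours = 24,
                       schedule = light_schedule(),
                       start_clock = schedule$dark_onset,
                       seed = 1L, n_animals = 5L) {
  stopifnot(sample_rate > 0, duration_hours >= 1, n_animals >= 1)
  structure(list(sample_rate = sample_rate,
                 duration_hours = duration_hours,
                 schedule = schedule, start_clock = start_clock,
                 seed = as.integer(seed), n_animals = as.integer(n_animals)),
            class = "sim_config")
}

# run `code` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# deterministic per-animal seed stream from a master seed (counter-based)
animal_seed <- function(master, i) {
  as.integer((as.numeric(master) * 2654435761 + i * 40503) %% 2147483647)
}
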