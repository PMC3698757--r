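#' Light/dark schedule
#'
#' Describes the lighting cycle of the animal room. The default is the
#' conventional reversed-activity arrangement for nocturnal rats: a 12-hour
#' dark (active) period starting at 20:00 and a 12-hour light (inactive)
#' period starting at 08:00. Analysis "days" are anchored at dark onset, so
#' one day is a dark period followed by its light period.
#'
#' @param dark_onset Clock hour (0-24) at which lights go off. Default 20.
#' @param dark_hours Duration of the dark period in hours. Default 12.
#' @return An object of class `light_schedule`.
#' @export
light_schedule <- function(dark_onset = 20, dark_hours = 12) {
  stopifnot(is.numeric(dark_onset), dark_onset >= 0, dark_onset < 24,
            is.numeric(dark_hours), dark_hours > 0, dark_hours < 24)
  structure(list(dark_onset = dark_onset, dark_hours = dark_hours),
            class = "light_schedule")
}

#' @export
print.light_schedule <- function(x, ...) {
  light_on <- (x$dark_onset + x$dark_hours) %% 24
  cat(sprintf("<light_schedule> dark %02.0f:00-%02.0f:00 (%g h), light %g h\n",
              x$dark_onset, light_on, x$dark_hours, 24 - x$dark_hours))
  invisible(x)
}

#' Dark-period membership of recording times
#'
#' @param t Time in seconds from the start of the recording.
#' @param schedule A [light_schedule()].
#' @param start_clock Clock hour at which the recording starts (default:
#'   dark onset, i.e. the recording starts at lights-off).
#' @return Logical vector, `TRUE` where `t` falls in the dark period.
#' @export
in_dark <- function(t, schedule = light_schedule(),
                    start_clock = schedule$dark_onset) {
  clock <- (start_clock + t / 3600) %% 24
  ((clock - schedule$dark_onset) %% 24) < schedule$dark_hours
}

#' Analysis-day index of recording times
#'
#' Days are anchored at dark onset: day 0 spans the first dark onset at or
#' before the start of the recording plus 24 hours.
#'
#' @inheritParams in_dark
#' @return Integer vector of day indices (0-based).
#' @export
day_index <- function(t, schedule = light_schedule(),
                      start_clock = schedule$dark_onset) {
  # seconds since the most recent dark onset before (or at) recording start
  offset <- ((start_clock - schedule$dark_onset) %% 24) * 3600
  as.integer(floor((t + offset) / 86400))
}

#' Seconds into the current dark or light period
#'
#' Used internally to place the half-cosine transition ramp at the start of
#' each period.
#' @inheritParams in_dark
#' @return Numeric vector of seconds elapsed since the last light transition.
#' @keywords internal
period_elapsed <- function(t, schedule = light_schedule(),
                           start_clock = schedule$dark_onset) {
  clock <- (start_clock + t / 3600) %% 24
  since_dark <- ((clock - schedule$dark_onset) %% 24) * 3600
  dark_s <- schedule$dark_hours * 3600
  ifelse(since_dark < dark_s, since_dark, since_dark - dark_s)
}

#' Piecewise dark/light profile with half-cosine transitions
#'
#' Evaluates a quantity that takes one level in the dark period and another
#' in the light period, with a smooth half-cosine ramp of `ramp_s` seconds at
#' the start of each period (avoids a step discontinuity that would leak into
#' the spectra).
#'
#' @param t Seconds from recording start.
#' @param dark_value,light_value Levels in each period.
#' @param schedule A [light_schedule()].
#' @param start_clock Clock hour of recording start.
#' @param ramp_s Ramp length in seconds (default 1800 = 30 min).
#' @return Numeric vector of profile values.
#' @export
dark_light_profile <- function(t, dark_value, light_value,
                               schedule = light_schedule(),
                               start_clock = schedule$dark_onset,
                               ramp_s = 1800) {
  dark <- in_dark(t, schedule, start_clock)
  cur <- ifelse(dark, dark_value, light_value)
  prev <- ifelse(dark, light_value, dark_value)
  s <- period_elapsed(t, schedule, start_clock)
  w <- ifelse(s < ramp_s, (1 + cos(pi * s / ramp_s)) / 2, 0)
  cur + (prev - cur) * w
}
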