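# Telemetry-cadence binning, 12-h dark/light summaries, dipper/nondipper
# classification and treatment-effect (delta-MAP) summaries.

#' Bin a beat series at telemetry cadence
#'
#' Emulates the standard telemetry acquisition scheme: one bin every
#' `bin_s` seconds (default 5 min), each value the average over the first
#' `avg_s` seconds (default 30 s) of the bin. MAP is averaged over beats
#' whose systolic time falls in the sampling window; HR is
#' `60000 / mean(pulse interval)`. Bins with fewer than `min_beats` beats in
#' the sampling window are invalid and carry no values.
#'
#' @param beats A [beat_series()].
#' @param activity Optional data frame `time` (s), `counts`: a locomotor
#'   activity series averaged over the same windows.
#' @param bin_s Bin cadence, s.
#' @param avg_s Sampling window at the start of each bin, s.
#' @param min_beats Validity floor per bin.
#' @return Data frame: `bin_start` (s), `map`, `hr`, `activity`, `n_beats`,
#'   `valid`; `floor(duration / bin_s)` rows.
#' @export
bin_telemetry <- function(beats, activity = NULL, bin_s = 300, avg_s = 30,
                          min_beats = 3L) {
  stopifnot(inherits(beats, "beat_series"), avg_s <= bin_s)
  dur <- max(beats$systolic_time)
  n_bins <- ceiling(dur / bin_s)    # a started bin is emitted; validity is
  if (n_bins < 1) stop("beats must span at least one bin")  # per sampling window
  tt <- beats$systolic_time
  bin <- floor(tt / bin_s)
  insamp <- (tt - bin * bin_s) < avg_s & bin < n_bins
  dt <- data.table::data.table(bin = bin[insamp], map = beats$map[insamp],
                               pint = beats$pulse_interval[insamp])
  agg <- dt[, list(map = mean(map), hr = 60000 / mean(pint),
                   n_beats = .N), by = "bin"]
  out <- data.frame(bin_start = (seq_len(n_bins) - 1) * bin_s,
                    map = NA_real_, hr = NA_real_, activity = NA_real_,
                    n_beats = 0L, valid = FALSE)
  i <- agg$bin + 1L
  out$map[i] <- agg$map
  out$hr[i] <- agg$hr
  out$n_beats[i] <- agg$n_beats
  out$valid <- out$n_beats >= min_beats
  out$map[!out$valid] <- NA_real_
  out$hr[!out$valid] <- NA_real_
  if (!is.null(activity)) {
    ab <- floor(activity$time / bin_s)
    ains <- (activity$time - ab * bin_s) < avg_s & ab < n_bins
    am <- tapply(activity$counts[ains], ab[ains], mean)
    out$activity[as.integer(names(am)) + 1L] <- as.numeric(am)
  }
  attr(out, "schedule") <- attr(beats, "schedule")
  attr(out, "start_clock") <- attr(beats, "start_clock")
  out
}

#' 12-hour dark/light period summaries
#'
#' Unweighted means of valid telemetry bins per animal-day-period. Days are
#' anchored at dark onset, so a "day" is one dark period followed by its
#' light period; with the default schedule each complete period holds up to
#' 144 five-minute bins.
#'
#' @param bins Output of [bin_telemetry()].
#' @param schedule A [light_schedule()]; defaults to the one carried by
#'   `bins`.
#' @param start_clock Clock hour of recording start.
#' @param animal Animal identifier attached to each row.
#' @return Data frame: `animal`, `day`, `period` (`"dark"`/`"light"`),
#'   `mean_map`, `mean_hr`, `mean_activity`, `n_bins`. Periods with zero
#'   valid bins are absent.
#' @export
period_summary <- function(bins, schedule = attr(bins, "schedule"),
                           start_clock = attr(bins, "start_clock"),
                           animal = 1L) {
  if (is.null(schedule)) schedule <- light_schedule()
  if (is.null(start_clock)) start_clock <- schedule$dark_onset
  t <- bins$bin_start
  per <- ifelse(in_dark(t, schedule, start_clock), "dark", "light")
  day <- day_index(t, schedule, start_clock)
  v <- bins$valid
  if (!any(v)) stop("no valid bins")
  dt <- data.table::data.table(day = day[v], period = per[v],
                               map = bins$map[v], hr = bins$hr[v],
                               act = bins$activity[v])
  agg <- dt[, list(mean_map = mean(map), mean_hr = mean(hr),
                   mean_activity = mean(act), n_bins = .N),
            by = c("day", "period")]
  data.table::setorderv(agg, c("day", "period"))
  cbind(animal = animal, as.data.frame(agg))
}

#' Dipper / nondipper classification
#'
#' Paired comparison of dark vs light MAP means. Pairs are the rows sharing a
#' pairing key (animals of a cohort for a single-day recording, or days of a
#' multi-day recording for one animal). The difference distribution is tested
#' with Shapiro-Wilk: a paired t test when normality is not rejected,
#' otherwise a Wilcoxon signed-rank test. The record is a dipper if and only
#' if the light mean is significantly lower than the dark mean at `alpha`;
#' the descriptive dip percentage `100 * (dark - light) / dark` is reported
#' either way. This mirrors the statistical (not the clinical 10%-dip)
#' definition of dipping.
#'
#' @param summaries A [period_summary()] data frame (possibly several animals
#'   row-bound together).
#' @param alpha Significance level (default 0.05).
#' @param pair_by Pairing key: `"auto"` (animals if > 1 animal, else days),
#'   `"animal"`, or `"day"`.
#' @return List of class `dipper_call`: `classification`, `dark_mean`,
#'   `light_mean`, `dip_percent`, `p_value`, `test`, `n_pairs`.
#' @export
classify_dipper <- function(summaries, alpha = 0.05, pair_by = "auto") {
  if (pair_by == "auto")
    pair_by <- if (length(unique(summaries$animal)) > 1) "animal" else "day"
  key <- summaries[[if (pair_by == "animal") "animal" else "day"]]
  dk <- summaries$period == "dark"
  dark <- tapply(summaries$mean_map[dk], key[dk], mean)
  light <- tapply(summaries$mean_map[!dk], key[!dk], mean)
  ids <- intersect(names(dark), names(light))
  if (length(ids) < 3)
    stop("need at least 3 paired ", pair_by, " records; have ", length(ids))
  d <- as.numeric(dark[ids]); l <- as.numeric(light[ids])
  cmp <- paired_compare(d, l, alpha = alpha)
  dip <- 100 * (mean(d) - mean(l)) / mean(d)
  structure(list(classification = if (cmp$p_value < alpha && mean(d) > mean(l))
                   "dipper" else "nondipper",
                 dark_mean = mean(d), light_mean = mean(l),
                 dip_percent = dip, p_value = cmp$p_value,
                 test = cmp$method, n_pairs = length(ids)),
            class = "dipper_call")
}

#' @export
print.dipper_call <- function(x, ...) {
  cat(sprintf("<dipper_call> %s: dark %.1f / light %.1f mmHg (dip %.1f%%), %s p = %.3g, n = %d\n",
              x$classification, x$dark_mean, x$light_mean, x$dip_percent,
              x$test, x$p_value, x$n_pairs))
  invisible(x)
}

#' Dose-response summary of treatment effect on 12-h MAP
#'
#' Change in the 12-hour period MAP mean relative to the pre-treatment
#' baseline, per animal, period and dose -- the "after 7 days at each dose"
#' summary of a weekly dose-escalation design. `treated` rows must carry a
#' `dose` column (use [dose_of_day()] to derive it from a
#' [drug_schedule()]); multiple baseline days per animal are averaged.
#'
#' @param baseline [period_summary()] rows from the pre-treatment baseline.
#' @param treated [period_summary()] rows from treatment days, with a `dose`
#'   column.
#' @param strain Optional strain label attached to the output.
#' @return Data frame: `strain`, `period`, `dose`, `animal`, `delta_map`
#'   (treated minus baseline, mmHg).
#' @export
dose_response <- function(baseline, treated, strain = NA_character_) {
  if (!nrow(baseline)) stop("missing baseline summaries")
  if (!"dose" %in% names(treated)) stop("treated summaries need a dose column")
  base <- stats::aggregate(mean_map ~ animal + period, baseline, mean)
  names(base)[3] <- "base_map"
  tr <- stats::aggregate(mean_map ~ animal + period + dose, treated, mean)
  m <- merge(tr, base, by = c("animal", "period"))
  if (!nrow(m)) stop("no animal/period overlap between treated and baseline")
  data.frame(strain = strain, period = m$period, dose = m$dose,
             animal = m$animal, delta_map = m$mean_map - m$base_map)
}

#' Dose administered on each analysis day
#'
#' @param day Analysis-day index (0-based, anchored at dark onset).
#' @param schedule A [drug_schedule()].
#' @return Numeric vector of doses (mg/kg), 0 outside the treatment weeks.
#' @export
dose_of_day <- function(day, schedule) {
  wk <- (day - schedule$start_day) %/% 7L
  ifelse(day < schedule$start_day | wk >= length(schedule$dose_by_week),
         0, schedule$dose_by_week[pmax(wk, 0) + 1L])
}
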