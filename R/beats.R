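# Per-beat series: construction, beat detection on pressure waveforms,
# windowing, and CSV round-trip.

#' Per-beat series
#'
#' A data frame with one row per cardiac beat and columns
#' `systolic_time` (s from recording start, strictly increasing),
#' `sbp`, `dbp`, `map` (mmHg) and `pulse_interval` (ms, the time to the next
#' systolic peak). Carries the recording's light schedule and start clock as
#' attributes so downstream circadian summaries need no extra arguments.
#'
#' @param df Data frame with the five beat columns.
#' @param schedule A [light_schedule()].
#' @param start_clock Clock hour of recording start.
#' @param n_artifacts Number of beats excluded as artifacts upstream.
#' @return A `beat_series` (also a data.frame).
#' @export
beat_series <- function(df, schedule = light_schedule(),
                        start_clock = schedule$dark_onset, n_artifacts = 0L) {
  need <- c("systolic_time", "sbp", "dbp", "map", "pulse_interval")
  if (!all(need %in% names(df)))
    stop("beat_series needs columns: ", paste(need, collapse = ", "))
  df <- as.data.frame(df)[need]
  if (nrow(df) && any(diff(df$systolic_time) <= 0))
    stop("systolic_time must be strictly increasing")
  if (nrow(df) && any(df$dbp > df$map + 1e-9 | df$map > df$sbp + 1e-9))
    stop("per-beat ordering dbp <= map <= sbp violated")
  structure(df, class = c("beat_series", "data.frame"),
            schedule = schedule, start_clock = start_clock,
            n_artifacts = as.integer(n_artifacts))
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> %d beats over %.1f min (%d artifacts excluded)\n",
              nrow(x), diff(range(x$systolic_time)) / 60,
              attr(x, "n_artifacts") %||% 0L))
  if (nrow(x)) {
    cat(sprintf("  SBP %.1f mmHg, MAP %.1f mmHg, PI %.1f ms (means)\n",
                mean(x$sbp), mean(x$map), mean(x$pulse_interval)))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Detect beats on an arterial-pressure waveform
#'
#' Systolic peaks are found by local-maximum search with a prominence
#' threshold and a refractory window of `60000 / max_hr` ms; peak time and
#' value are refined by quadratic (three-point) interpolation, giving
#' sub-sample pulse-interval resolution. Per-beat MAP is the time average of
#' the samples between successive peaks and DBP their minimum. Beats whose
#' pulse interval falls outside `[60000/max_hr, 60000/min_hr]` ms are flagged
#' as artifacts and excluded (not interpolated); the count is recorded in the
#' `n_artifacts` attribute.
#'
#' The prominence threshold defaults to 0.25 times the median peak-to-trough
#' excursion of a calibration pass over all local maxima, making it unit-free.
#'
#' @param waveform A [bp_waveform()].
#' @param min_hr,max_hr Physiological heart-rate limits, beats/min.
#' @param prominence Absolute prominence threshold in mmHg, or `NULL` for the
#'   calibrated default.
#' @return A [beat_series()].
#' @export
detect_beats <- function(waveform, min_hr = 200, max_hr = 500,
                         prominence = NULL) {
  stopifnot(inherits(waveform, "bp_waveform"), min_hr < max_hr)
  x <- waveform$samples
  fs <- waveform$sample_rate
  n <- length(x)
  if (n < 3) stop("waveform too short")
  # candidate peaks: strict rise on the left, non-rise on the right
  left <- x[2:(n - 1)] > x[1:(n - 2)]
  right <- x[2:(n - 1)] >= x[3:n]
  cand <- which(left & right) + 1L
  if (!length(cand)) stop("no beats found: waveform has no local maxima")
  # prominence = peak minus the higher of the two neighbouring inter-peak minima
  bounds <- c(1L, cand, n)
  nmin <- length(cand) + 1L
  segmin <- vapply(seq_len(nmin), function(i)
    min(x[bounds[i]:bounds[i + 1L]]), numeric(1))
  prom <- x[cand] - pmax(segmin[-nmin], segmin[-1L])
  if (is.null(prominence)) prominence <- 0.25 * stats::median(prom)
  keep <- prom >= prominence & prom > 0
  cand <- cand[keep]
  if (!length(cand)) stop("no beats found above the prominence threshold")
  # refractory: greedily drop the lower of any pair closer than 60000/max_hr ms
  refr <- fs * 60 / max_hr
  repeat {
    d <- diff(cand)
    bad <- which(d < refr)
    if (!length(bad)) break
    bad <- bad[c(TRUE, diff(bad) > 1)]  # resolve non-adjacent conflicts first
    drop <- ifelse(x[cand[bad]] >= x[cand[bad + 1L]], bad + 1L, bad)
    cand <- cand[-unique(drop)]
  }
  if (length(cand) < 2) stop("fewer than two beats detected")
  # quadratic refinement of peak time and height
  i0 <- pmax(pmin(cand, n - 1L), 2L)
  ym <- x[i0 - 1L]; y0 <- x[i0]; yp <- x[i0 + 1L]
  den <- ym - 2 * y0 + yp
  delta <- ifelse(den < 0, 0.5 * (ym - yp) / den, 0)
  delta <- pmax(pmin(delta, 0.5), -0.5)
  pk_t <- (i0 - 1L + delta) / fs
  pk_v <- y0 - 0.25 * (ym - yp) * delta
  nb <- length(cand) - 1L
  # per-beat aggregates over [peak_i, peak_{i+1})
  idx <- rep.int(0L, n)
  idx[cand] <- 1L
  beat_of <- cumsum(idx)           # 0 before first peak, i in beat i
  sel <- beat_of >= 1L & beat_of <= nb
  dt <- data.table::data.table(b = beat_of[sel], p = x[sel])
  agg <- dt[, list(map = mean(p), dbp = min(p)), by = "b"]
  data.table::setorderv(agg, "b")
  pi_ms <- diff(pk_t) * 1000
  beats <- data.frame(systolic_time = pk_t[seq_len(nb)],
                      sbp = pk_v[seq_len(nb)],
                      dbp = agg$dbp, map = agg$map,
                      pulse_interval = pi_ms)
  # artifact exclusion by interval plausibility
  ok <- pi_ms >= 60000 / max_hr & pi_ms <= 60000 / min_hr
  n_art <- sum(!ok)
  beats <- beats[ok, , drop = FALSE]
  if (!nrow(beats)) stop("no beats with plausible pulse intervals")
  beats$sbp <- pmax(beats$sbp, beats$map)   # guard against interpolation undershoot
  beats$dbp <- pmin(beats$dbp, beats$map)
  beat_series(beats, schedule = waveform$schedule,
              start_clock = waveform$start_clock, n_artifacts = n_art)
}

#' Split a beat series into time windows
#'
#' Windows are half-open `[start, end)`: a beat whose systolic time equals a
#' window's end belongs to the next window.
#'
#' @param beats A [beat_series()].
#' @param windows Data frame with columns `start`, `end` (seconds), sorted and
#'   non-overlapping.
#' @return List of `beat_series`, one per window (possibly empty).
#' @export
split_by_window <- function(beats, windows) {
  stopifnot(inherits(beats, "beat_series"),
            all(c("start", "end") %in% names(windows)))
  if (nrow(windows) > 1) {
    if (any(diff(windows$start) <= 0) ||
        any(windows$start[-1] < windows$end[-nrow(windows)]))
      stop("windows must be sorted and non-overlapping")
  }
  lapply(seq_len(nrow(windows)), function(i) {
    sel <- beats$systolic_time >= windows$start[i] &
      beats$systolic_time < windows$end[i]
    beat_series(as.data.frame(beats)[sel, , drop = FALSE],
                schedule = attr(beats, "schedule"),
                start_clock = attr(beats, "start_clock"))
  })
}

#' Write / read a beat series as CSV
#'
#' Columns: `systolic_time_s,sbp,dbp,map,pulse_interval_ms`. The reader
#' validates strictly increasing systolic times.
#'
#' @param beats A [beat_series()].
#' @param path File path.
#' @export
write_beat_series <- function(beats, path) {
  out <- data.frame(systolic_time_s = beats$systolic_time, sbp = beats$sbp,
                    dbp = beats$dbp, map = beats$map,
                    pulse_interval_ms = beats$pulse_interval)
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname write_beat_series
#' @param schedule,start_clock Schedule metadata to attach (not stored in CSV).
#' @export
read_beat_series <- function(path, schedule = light_schedule(),
                             start_clock = schedule$dark_onset) {
  df <- data.table::fread(path, data.table = FALSE)
  names(df) <- sub("_s$", "", sub("_ms$", "", names(df)))
  beat_series(df, schedule = schedule, start_clock = start_clock)
}
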