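# Continuous arterial-pressure waveform container and CSV round-trip.

#' Arterial-pressure waveform
#'
#' Uniformly sampled arterial pressure with its sampling rate, start clock
#' time and light/dark schedule. Sample `i` is taken at
#' `(i - 1) / sample_rate` seconds from the start of the recording.
#'
#' @param samples Numeric vector of pressures, mmHg.
#' @param sample_rate Sampling rate, Hz.
#' @param schedule A [light_schedule()].
#' @param start_clock Clock hour of the first sample.
#' @return A `bp_waveform` object.
#' @export
bp_waveform <- function(samples, sample_rate, schedule = light_schedule(),
                        start_clock = schedule$dark_onset) {
  stopifnot(is.numeric(samples), sample_rate > 0)
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate,
                 schedule = schedule, start_clock = start_clock),
            class = "bp_waveform")
}

#' @export
print.bp_waveform <- function(x, ...) {
  cat(sprintf("<bp_waveform> %d samples @ %g Hz (%.2f h), start %02.0f:00\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate / 3600, x$start_clock))
  cat(sprintf("  pressure %.1f-%.1f mmHg\n",
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' Write / read a waveform as CSV with a YAML sidecar
#'
#' The CSV has columns `timestamp` (ISO 8601, to the millisecond) and
#' `pressure_mmHg`. Sampling rate, schedule, start clock and any provenance
#' fields are written to `<path>.yaml`.
#'
#' @param waveform A [bp_waveform()].
#' @param path CSV path; the sidecar is written next to it.
#' @param origin Calendar origin (date of the first sample) used to render
#'   timestamps; analysis only uses clock time, so the date is conventional.
#' @param meta Named list of extra fields for the sidecar.
#' @export
write_waveform <- function(waveform, path, origin = "2024-01-01",
                           meta = list()) {
  n <- length(waveform$samples)
  t0 <- as.POSIXct(paste0(origin, " 00:00:00"), tz = "UTC") +
    waveform$start_clock * 3600
  ts <- t0 + (seq_len(n) - 1) / waveform$sample_rate
  out <- data.frame(
    timestamp = format(ts, "%Y-%m-%dT%H:%M:%OS3Z"),
    pressure_mmHg = waveform$samples)
  data.table::fwrite(out, path)
  side <- c(list(sample_rate = waveform$sample_rate,
                 start_clock = waveform$start_clock,
                 dark_onset = waveform$schedule$dark_onset,
                 dark_hours = waveform$schedule$dark_hours,
                 n_samples = n), meta)
  yaml::write_yaml(side, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_waveform
#' @export
read_waveform <- function(path) {
  side_path <- paste0(path, ".yaml")
  if (!file.exists(side_path))
    stop("missing sidecar: ", side_path)
  side <- yaml::read_yaml(side_path)
  df <- data.table::fread(path, data.table = FALSE)
  if (!all(c("timestamp", "pressure_mmHg") %in% names(df)))
    stop("malformed waveform CSV (need timestamp, pressure_mmHg): ", path)
  bp_waveform(df$pressure_mmHg, side$sample_rate,
              schedule = light_schedule(side$dark_onset, side$dark_hours),
              start_clock = side$start_clock)
}
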