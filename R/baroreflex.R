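# Spontaneous baroreflex gain by the sequence (time-series) method:
# concordant spontaneous ramps of systolic pressure and pulse interval,
# positive-slope sequences only.

#' Sequence-method criteria
#'
#' Conventional sequence-method settings; all are configurable because the
#' source method's exact thresholds are implementation-defined.
#'
#' @param min_len Minimum run length in beats (>= 3).
#' @param min_dsbp Minimum per-beat SBP change, mmHg.
#' @param min_dpi Minimum per-beat pulse-interval change, ms.
#' @param delay Beat lag of the pulse-interval response (default 0).
#' @param min_r Minimum SBP-PI correlation within a sequence.
#' @return A `sequence_criteria` object.
#' @export
sequence_criteria <- function(min_len = 3L, min_dsbp = 0.5, min_dpi = 1,
                              delay = 0L, min_r = 0.8) {
  stopifnot(min_len >= 3, min_dsbp >= 0, min_dpi >= 0, delay >= 0,
            min_r >= 0, min_r <= 1)
  structure(list(min_len = as.integer(min_len), min_dsbp = min_dsbp,
                 min_dpi = min_dpi, delay = as.integer(delay), min_r = min_r),
            class = "sequence_criteria")
}

#' Find spontaneous SBP/PI sequences
#'
#' A sequence is a maximal run of at least `min_len` consecutive beats in
#' which SBP changes by at least `min_dsbp` in one direction at every beat
#' and the pulse interval, taken `delay` beats later, changes by at least
#' `min_dpi` in the same direction. The per-sequence slope is the ordinary
#' least-squares regression of PI on SBP; sequences with correlation below
#' `min_r` are discarded. Because only maximal runs are taken, the returned
#' sequences do not overlap.
#'
#' @param beats A [beat_series()].
#' @param criteria A [sequence_criteria()].
#' @return Data frame with one row per sequence: `start` (beat index),
#'   `length`, `direction` (`"up"`/`"down"`), `slope` (ms/mmHg), `r`.
#' @export
find_sequences <- function(beats, criteria = sequence_criteria()) {
  sbp <- beats$sbp
  pi_ <- beats$pulse_interval
  n <- length(sbp)
  d <- criteria$delay
  empty <- data.frame(start = integer(), length = integer(),
                      direction = character(), slope = numeric(),
                      r = numeric())
  if (n - d < criteria$min_len) return(empty)
  m <- n - d                      # usable beats (PI available at i + delay)
  s <- sbp[seq_len(m)]
  p <- pi_[seq_len(m) + d]
  ds <- diff(s); dp <- diff(p)
  step <- integer(m - 1L)
  step[ds >= criteria$min_dsbp & dp >= criteria$min_dpi] <- 1L
  step[ds <= -criteria$min_dsbp & dp <= -criteria$min_dpi] <- -1L
  r <- rle(step)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0L & r$lengths + 1L >= criteria$min_len
  if (!any(keep)) return(empty)
  out <- lapply(which(keep), function(k) {
    i0 <- starts[k]; i1 <- ends[k] + 1L       # beat indices of the run
    xs <- s[i0:i1]; ys <- p[i0:i1]
    slope <- stats::cov(xs, ys) / stats::var(xs)
    data.frame(start = i0, length = i1 - i0 + 1L,
               direction = if (r$values[k] > 0L) "up" else "down",
               slope = slope, r = stats::cor(xs, ys))
  })
  out <- do.call(rbind, out)
  out[out$r >= criteria$min_r, , drop = FALSE]
}

#' Spontaneous baroreflex gain of one window
#'
#' The gain is the arithmetic mean of the slopes of all sequences with a
#' positive slope -- both rising (SBP up, PI lengthening) and falling runs
#' qualify, since both yield positive slopes; negative-slope sequences are
#' counted but excluded, as they reflect non-baroreflex coupling. With no
#' qualifying sequence the estimate is invalid (`NA` gain), never zero.
#'
#' @param beats A [beat_series()].
#' @param criteria A [sequence_criteria()].
#' @param min_sequences Validity floor on the number of positive-slope
#'   sequences (default 1).
#' @return List of class `sbrg_estimate`: `gain` (ms/mmHg), `n_sequences`,
#'   `n_negative`, `valid`.
#' @export
sbrg <- function(beats, criteria = sequence_criteria(), min_sequences = 1L) {
  seqs <- find_sequences(beats, criteria)
  pos <- seqs$slope > 0
  n_pos <- sum(pos)
  structure(list(gain = if (n_pos >= min_sequences) mean(seqs$slope[pos])
                        else NA_real_,
                 n_sequences = n_pos, n_negative = sum(!pos),
                 valid = n_pos >= min_sequences),
            class = "sbrg_estimate")
}

#' @export
print.sbrg_estimate <- function(x, ...) {
  if (x$valid)
    cat(sprintf("<sbrg_estimate> %.3g ms/mmHg from %d sequences (%d negative-slope excluded)\n",
                x$gain, x$n_sequences, x$n_negative))
  else
    cat("<sbrg_estimate> invalid: no qualifying positive-slope sequences\n")
  invisible(x)
}

#' Hourly spontaneous baroreflex gain
#'
#' Same telemetry cadence as [lf_sbp_series()]: one `window_min`-minute
#' window per hour; windows with too few beats or sequences propagate as
#' invalid.
#'
#' @inheritParams lf_sbp_series
#' @param criteria A [sequence_criteria()].
#' @param min_sequences Validity floor per window.
#' @return Data frame: `window_start`, `gain`, `n_sequences`, `valid`.
#' @export
sbrg_series <- function(beats, window_min = 5, offset_s = 0,
                        criteria = sequence_criteria(), min_sequences = 1L) {
  win <- hourly_windows(beats, window_s = window_min * 60, offset_s = offset_s)
  pieces <- split_by_window(beats, win)
  rows <- lapply(seq_along(pieces), function(i) {
    b <- pieces[[i]]
    if (nrow(b) < criteria$min_len)
      return(data.frame(window_start = win$start[i], gain = NA_real_,
                        n_sequences = 0L, valid = FALSE))
    est <- sbrg(b, criteria, min_sequences)
    data.frame(window_start = win$start[i], gain = est$gain,
               n_sequences = est$n_sequences, valid = est$valid)
  })
  do.call(rbind, rows)
}
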