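# Spectral analysis of beat-to-beat systolic pressure: even resampling,
# Welch averaged periodogram, and LF/HF band-power integration. LF power of
# SBP (0.27-0.75 Hz in the rat) indexes vasomotor sympathetic tone; the HF
# band (0.75-3.3 Hz) carries the respiratory oscillation.

#' Evenly resampled series
#'
#' @param values Numeric values on a uniform grid.
#' @param rate Grid rate, Hz.
#' @param window_start Start time of the window, s.
#' @return An `even_series` object.
#' @export
even_series <- function(values, rate, window_start = 0) {
  stopifnot(is.numeric(values), rate > 2 * HF_BAND[2])
  structure(list(values = as.numeric(values), rate = rate,
                 window_start = window_start), class = "even_series")
}

#' Resample beat-to-beat SBP onto a uniform grid
#'
#' Linear interpolation of SBP against systolic time. No detrending is done
#' here; mean and trend removal belong to [estimate_psd()]. A window is
#' invalid (returns `NULL`) rather than silently zero when it has fewer than
#' `min_beats` beats or an inter-beat gap (e.g. from artifact exclusion)
#' longer than `max_gap_s`.
#'
#' @param beats A [beat_series()] (typically one analysis window).
#' @param rate Target rate in Hz; default 10 Hz, comfortably above twice the
#'   HF band's upper edge.
#' @param min_beats Minimum number of beats required.
#' @param max_gap_s Longest tolerated gap between consecutive beats, s.
#' @return An [even_series()], or `NULL` for an invalid window.
#' @export
resample_evenly <- function(beats, rate = 10, min_beats = 8, max_gap_s = 2) {
  if (nrow(beats) < min_beats) return(NULL)
  tt <- beats$systolic_time
  if (max(diff(tt)) > max_gap_s) return(NULL)
  grid <- seq(ceiling(tt[1] * rate) / rate, floor(tt[length(tt)] * rate) / rate,
              by = 1 / rate)
  if (length(grid) < 2) return(NULL)
  v <- stats::approx(tt, beats$sbp, xout = grid, method = "linear")$y
  even_series(v, rate, window_start = grid[1])
}

#' Welch power spectral density
#'
#' Averaged modified periodogram: the series is cut into segments of
#' `segment_s` seconds with fractional `overlap`, each segment is mean- and
#' linear-trend-removed, Hann-tapered, and its one-sided periodogram is
#' normalized so that the integral of the density over frequency equals the
#' variance of the detrended segment (within taper approximation); segment
#' periodograms are averaged.
#'
#' @param series An [even_series()].
#' @param segment_s Segment length, s (default 60, giving ~0.017-Hz resolution).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @return A `bp_psd` object with `freq` (Hz), `density` (mmHg^2/Hz) and
#'   `resolution` (Hz).
#' @export
estimate_psd <- function(series, segment_s = 60, overlap = 0.5) {
  stopifnot(inherits(series, "even_series"), overlap >= 0, overlap < 1)
  x <- series$values
  fs <- series$rate
  L <- round(segment_s * fs)
  if (L > length(x)) stop("segment longer than series")
  step <- max(1L, round(L * (1 - overlap)))
  starts <- seq(1L, length(x) - L + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * (0:(L - 1)) / L))   # periodic Hann
  U <- mean(w^2)
  nf <- L %/% 2L
  acc <- numeric(nf + 1L)
  k <- seq_len(L)
  kc <- k - mean(k)
  sxx <- sum(kc^2)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)]
    seg <- seg - mean(seg) - kc * (sum(kc * seg) / sxx)  # linear detrend
    X <- stats::fft(seg * w)
    P <- (Mod(X[1:(nf + 1L)])^2) / (fs * L * U)
    P[2:nf] <- 2 * P[2:nf]              # one-sided (DC and Nyquist once)
    acc <- acc + P
  }
  structure(list(freq = (0:nf) * fs / L, density = acc / length(starts),
                 resolution = fs / L, nyquist = fs / 2,
                 n_segments = length(starts)),
            class = "bp_psd")
}

#' @export
print.bp_psd <- function(x, ...) {
  cat(sprintf("<bp_psd> %d bins, 0-%.2f Hz, resolution %.4f Hz (%d segments)\n",
              length(x$freq), x$nyquist, x$resolution, x$n_segments))
  cat(sprintf("  total power %.3g mmHg^2\n",
              sum(x$density) * x$resolution))
  invisible(x)
}

#' Integrate spectral power over a band
#'
#' Trapezoidal integral of the density over `[lo, hi]`, with the density at
#' the band edges obtained by linear interpolation, so that
#' `band_power(a,b) + band_power(b,c) == band_power(a,c)` exactly.
#'
#' @param psd A [estimate_psd()] result.
#' @param lo,hi Band edges in Hz, `0 <= lo < hi <=` Nyquist.
#' @return Integrated power, mmHg^2.
#' @export
band_power <- function(psd, lo, hi) {
  stopifnot(inherits(psd, "bp_psd"), lo >= 0, lo < hi)
  if (hi > max(psd$freq) + 1e-12)
    stop("band [", lo, ", ", hi, "] outside PSD support (max ",
         max(psd$freq), " Hz)")
  f <- psd$freq; d <- psd$density
  inside <- f > lo & f < hi
  fe <- c(lo, f[inside], hi)
  de <- c(stats::approx(f, d, lo)$y, d[inside], stats::approx(f, d, hi)$y)
  pracma::trapz(fe, de)
}

#' Band powers of one window
#'
#' @param psd A [estimate_psd()] result.
#' @param lf_band,hf_band Band edges, Hz.
#' @return A one-row data frame: `lf`, `hf`, `lf_hf_ratio`.
#' @export
band_powers <- function(psd, lf_band = LF_BAND, hf_band = HF_BAND) {
  lf <- band_power(psd, lf_band[1], lf_band[2])
  hf <- band_power(psd, hf_band[1], hf_band[2])
  data.frame(lf = lf, hf = hf,
             lf_hf_ratio = if (hf > 0) lf / hf else NA_real_)
}

# shared hourly 5-min analysis cadence for LF and sBRG series
hourly_windows <- function(beats, window_s = 300, offset_s = 0) {
  dur <- max(beats$systolic_time)
  n_h <- floor((dur - offset_s - window_s) / 3600) + 1
  if (n_h < 1) stop("need at least one hour of beats")
  data.frame(start = (seq_len(n_h) - 1) * 3600 + offset_s,
             end = (seq_len(n_h) - 1) * 3600 + offset_s + window_s)
}

#' Hourly LF/HF power of systolic pressure
#'
#' Telemetry cadence: one `window_min`-minute analysis window per hour
#' (minutes 0-5 by default, configurable offset). Invalid windows (too few
#' beats, long gaps) propagate as `NA` with `valid = FALSE`, never as zero.
#'
#' @param beats A [beat_series()] spanning at least one hour.
#' @param window_min Analysis window length, minutes (default 5).
#' @param offset_s Window offset from the top of the hour, s.
#' @param rate Resampling rate, Hz.
#' @param segment_s,overlap Welch parameters; see [estimate_psd()].
#' @param lf_band,hf_band Band edges, Hz.
#' @return Data frame: `window_start` (s), `lf`, `hf` (mmHg^2),
#'   `lf_hf_ratio`, `valid`.
#' @export
lf_sbp_series <- function(beats, window_min = 5, offset_s = 0, rate = 10,
                          segment_s = 60, overlap = 0.5,
                          lf_band = LF_BAND, hf_band = HF_BAND) {
  win <- hourly_windows(beats, window_s = window_min * 60, offset_s = offset_s)
  pieces <- split_by_window(beats, win)
  rows <- lapply(seq_along(pieces), function(i) {
    es <- resample_evenly(pieces[[i]], rate = rate)
    if (is.null(es) || length(es$values) < segment_s * rate)
      return(data.frame(window_start = win$start[i], lf = NA_real_,
                        hf = NA_real_, lf_hf_ratio = NA_real_, valid = FALSE))
    bp <- band_powers(estimate_psd(es, segment_s, overlap), lf_band, hf_band)
    cbind(data.frame(window_start = win$start[i]), bp, valid = TRUE)
  })
  do.call(rbind, rows)
}
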