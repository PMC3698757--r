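# Shared fixtures: quiet presets, hand-built beat tables, and independent
# brute-force oracles used to cross-check the vectorized implementations.

# a preset with every stochastic and oscillatory component switched off
quiet_preset <- function(map = 100, hr = 360, pp = 30) {
  register_strain_preset("quiet_test",
                         map_dark = map, map_light = map,
                         pulse_pressure = pp, hr_dark = hr, hr_light = hr,
                         lf_amp = 0, lf_amp_light = 0, hf_amp = 0,
                         brg_true = 0, noise_sd = 0, pi_noise_sd = 0,
                         activity_dark = 0, activity_light = 0)
  make_strain_preset("quiet_test")
}

# validation fixture for gain-recovery runs: strong Mayer wave and
# respiratory coupling, modest non-reflex pulse-interval noise
ladder_preset <- function(brg) {
  register_strain_preset("ladder_test", brg_true = brg,
                         lf_amp = 3, lf_amp_light = 3, hf_amp = 2,
                         noise_sd = 1, pi_noise_sd = 0.5)
  make_strain_preset("ladder_test")
}

# beat series straight from vectors (for oracle tests that need exact data)
beats_from <- function(sbp, pint, t = NULL, map = NULL) {
  n <- length(sbp)
  if (is.null(t)) t <- cumsum(c(0.2, pint[-n] / 1000))
  if (is.null(map)) map <- sbp - 15
  beat_series(data.frame(systolic_time = t, sbp = sbp, dbp = map - 15,
                         map = map, pulse_interval = pint))
}

# independent brute-force sequence enumerator (greedy maximal runs)
bf_sequences <- function(sbp, pint, crit) {
  d <- crit$delay
  m <- length(sbp) - d
  res <- list()
  if (m < crit$min_len) {
    return(data.frame(start = integer(), length = integer(),
                      direction = character(), slope = numeric(),
                      r = numeric()))
  }
  s <- sbp[seq_len(m)]
  p <- pint[seq_len(m) + d]
  ok_step <- function(i, dir) {
    ds <- s[i + 1] - s[i]; dp <- p[i + 1] - p[i]
    if (dir > 0) ds >= crit$min_dsbp && dp >= crit$min_dpi
    else ds <= -crit$min_dsbp && dp <= -crit$min_dpi
  }
  for (dir in c(1, -1)) {
    i <- 1L
    while (i < m) {
      if (ok_step(i, dir) && (i == 1L || !ok_step(i - 1L, dir))) {
        j <- i
        while (j < m && ok_step(j, dir)) j <- j + 1L
        len <- j - i + 1L
        if (len >= crit$min_len) {
          xs <- s[i:j]; ys <- p[i:j]
          res[[length(res) + 1L]] <-
            data.frame(start = i, length = len,
                       direction = if (dir > 0) "up" else "down",
                       slope = stats::cov(xs, ys) / stats::var(xs),
                       r = stats::cor(xs, ys))
        }
        i <- j
      } else {
        i <- i + 1L
      }
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(start = integer(), length = integer(),
               direction = character(), slope = numeric(), r = numeric())
  out <- out[is.na(out$r) | out$r >= crit$min_r, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

# hand-computed two-way ANOVA F statistics for a balanced design (oracle)
anova2_oracle <- function(value, a, b) {
  a <- as.factor(a); b <- as.factor(b)
  n <- tapply(value, list(a, b), length)[1, 1]
  ai <- nlevels(a); bi <- nlevels(b)
  gm <- mean(value)
  ma <- tapply(value, a, mean); mb <- tapply(value, b, mean)
  mab <- tapply(value, list(a, b), mean)
  ssa <- n * bi * sum((ma - gm)^2)
  ssb <- n * ai * sum((mb - gm)^2)
  ssab <- n * (sum((sweep(sweep(mab, 1, ma), 2, mb) + gm)^2))
  sse <- sum((value - mab[cbind(a, b)])^2)
  dfe <- ai * bi * (n - 1)
  c(Fa = (ssa / (ai - 1)) / (sse / dfe),
    Fb = (ssb / (bi - 1)) / (sse / dfe),
    Fab = (ssab / ((ai - 1) * (bi - 1))) / (sse / dfe))
}
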