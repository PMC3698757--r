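# Grouped biomarker tables (strain x period x treatment) with known
# cell effects, for exercising the statistical decision tree.

#' Generate a grouped biomarker table
#'
#' Draws `n_per_cell` animals per design cell from the stated per-cell
#' distribution. The lognormal option (mean/SD given on the natural scale)
#' produces the right-skewed, variance-heterogeneous data that the decision
#' tree must route to the nonparametric branch.
#'
#' @param effects Data frame with one row per cell: any factor columns (e.g.
#'   `strain`, `period`, `treatment`), plus `mean`, `sd` and optionally
#'   `dist` (`"normal"`, default, or `"lognormal"`).
#' @param n_per_cell Animals per cell (>= 2).
#' @param seed Integer seed; identical seeds give identical tables.
#' @return Long-format data frame: the factor columns, `animal` (unique id)
#'   and `value`.
#' @export
make_biomarker_tables <- function(effects, n_per_cell, seed = 1L) {
  stopifnot(is.data.frame(effects), all(c("mean", "sd") %in% names(effects)),
            n_per_cell >= 2)
  if (!"dist" %in% names(effects)) effects$dist <- "normal"
  stopifnot(all(effects$dist %in% c("normal", "lognormal")),
            all(effects$sd >= 0))
  fac <- setdiff(names(effects), c("mean", "sd", "dist"))
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(effects)), function(i) {
      e <- effects[i, ]
      v <- if (e$dist == "lognormal") {
        # moment-match mean/sd on the natural scale
        s2 <- log(1 + (e$sd / e$mean)^2)
        stats::rlnorm(n_per_cell, log(e$mean) - s2 / 2, sqrt(s2))
      } else {
        stats::rnorm(n_per_cell, e$mean, e$sd)
      }
      cbind(e[rep(1, n_per_cell), fac, drop = FALSE],
            animal = paste0("c", i, "a", seq_len(n_per_cell)), value = v)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
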