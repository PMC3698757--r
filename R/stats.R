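# The statistical decision tree: Shapiro-Wilk normality and Bartlett
# variance-homogeneity gates route grouped data to factorial ANOVA (Tukey or
# Bonferroni-t post hoc) or to Kruskal-Wallis with Steel-Dwass post hoc.

new_test_result <- function(method, statistic, df, p_value, pairwise = NULL,
                            details = list()) {
  structure(list(method = method, statistic = statistic, df = df,
                 p_value = p_value, pairwise = pairwise, details = details),
            class = "bp_test")
}

#' @export
print.bp_test <- function(x, ...) {
  cat(sprintf("<bp_test> %s\n", x$method))
  if (length(x$statistic))
    for (i in seq_along(x$statistic))
      cat(sprintf("  %s = %.4g%s, p = %.4g\n",
                  names(x$statistic)[i] %||% "stat", x$statistic[i],
                  if (length(x$df)) paste0(" (df ",
                    paste(signif(unlist(x$df[i]), 4), collapse = ", "), ")")
                  else "", x$p_value[i]))
  if (!is.null(x$pairwise)) {
    cat("  pairwise comparisons:\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

#' Route grouped data through the normality/variance gate
#'
#' Per-group Shapiro-Wilk tests, then Bartlett's test across groups. The
#' parametric route is taken only when every group passes normality and the
#' variances are homogeneous at `alpha`; any rejection, any group too small
#' for the Shapiro-Wilk test (< 3 observations), or a degenerate
#' (zero-variance) group routes to the nonparametric branch, with the reason
#' recorded.
#'
#' @param values Numeric response.
#' @param groups Grouping factor (use `interaction()` for crossed factors).
#' @param alpha Gate significance level (default 0.05).
#' @return List of class `decision_trace`: `shapiro_p` (named per group),
#'   `bartlett_p`, `route` (`"parametric"`/`"nonparametric"`), `reason`.
#' @export
route_test <- function(values, groups, alpha = 0.05) {
  groups <- droplevels(as.factor(groups))
  sp <- vapply(levels(groups), function(g) {
    x <- values[groups == g]
    if (length(x) < 3) return(NA_real_)
    if (stats::var(x) == 0) return(0)
    stats::shapiro.test(x)$p.value
  }, numeric(1))
  reason <- character()
  if (anyNA(sp)) reason <- c(reason, "group(s) too small for Shapiro-Wilk")
  if (any(!is.na(sp) & sp == 0)) reason <- c(reason, "zero variance in a group")
  if (any(!is.na(sp) & sp > 0 & sp < alpha))
    reason <- c(reason, "normality rejected")
  bart <- NA_real_
  if (!length(reason)) {
    bart <- stats::bartlett.test(values, groups)$p.value
    if (bart < alpha) reason <- c(reason, "variance homogeneity rejected")
  }
  structure(list(shapiro_p = sp, bartlett_p = bart,
                 route = if (length(reason)) "nonparametric" else "parametric",
                 reason = if (length(reason)) paste(reason, collapse = "; ")
                          else "all groups normal, variances similar"),
            class = "decision_trace")
}

#' @export
print.decision_trace <- function(x, ...) {
  cat(sprintf("<decision_trace> route: %s (%s)\n", x$route, x$reason))
  cat("  Shapiro-Wilk p:",
      paste(sprintf("%s=%.3g", names(x$shapiro_p), x$shapiro_p),
            collapse = ", "), "\n")
  if (!is.na(x$bartlett_p))
    cat(sprintf("  Bartlett p: %.3g\n", x$bartlett_p))
  invisible(x)
}

# Greenhouse-Geisser epsilon from a subject x level matrix of one
# within-subject factor
gg_epsilon <- function(mat) {
  S <- stats::cov(mat)
  k <- ncol(S)
  # double-centre the covariance matrix
  rm <- rowMeans(S); gm <- mean(S)
  C <- S - outer(rm, rep(1, k)) - outer(rep(1, k), rm) + gm
  sum(diag(C))^2 / ((k - 1) * sum(C^2))
}

#' Factorial ANOVA with the study's post hoc conventions
#'
#' Fits a fully crossed factorial ANOVA by least squares, with repeated
#' measures handled as classical within-subject error strata
#' (`Error(subject/within)`), not as a mixed model. Post hoc pairwise
#' comparisons over the cells of the factor crossing follow the design
#' convention: Tukey's HSD for one- and two-factor designs,
#' Bonferroni-corrected unpaired t tests for three-factor designs. For a
#' design with a single within-subject factor, the Greenhouse-Geisser
#' sphericity correction is estimated and corrected p-values reported for
#' within-factor effects.
#'
#' @param data Long-format data frame.
#' @param value Name of the response column.
#' @param factors Character vector of factor column names (1-3).
#' @param within Names of `factors` that are repeated measures within
#'   subject, or `NULL`.
#' @param subject Name of the subject id column (required with `within`).
#' @param posthoc `"auto"` (Tukey for <= 2 factors, Bonferroni t for 3),
#'   `"tukey"`, `"bonferroni"`, or `"none"`.
#' @return A `bp_test` with the F table in `statistic`/`df`/`p_value` and a
#'   `pairwise` table of cell contrasts with adjusted p-values.
#' @export
factorial_anova <- function(data, value, factors, within = NULL,
                            subject = NULL, posthoc = "auto") {
  stopifnot(length(factors) >= 1, length(factors) <= 3,
            all(c(value, factors, within, subject) %in% names(data)))
  for (f in c(factors, subject)) data[[f]] <- as.factor(data[[f]])
  fixed <- paste(factors, collapse = " * ")
  if (!is.null(within)) {
    if (is.null(subject)) stop("repeated measures need a subject column")
    err <- paste0("Error(", subject, "/(",
                  paste(within, collapse = " * "), "))")
    fml <- stats::as.formula(paste(value, "~", fixed, "+", err))
  } else {
    fml <- stats::as.formula(paste(value, "~", fixed))
  }
  # inline the formula in the call so emmeans can recover the model frame
  fit <- do.call(stats::aov, list(formula = fml, data = data))
  # flatten the (possibly stratified) summary into one F table
  strata <- if (inherits(fit, "aovlist")) {
    lapply(summary(fit), function(s) as.data.frame(s[[1]]))
  } else {
    list(as.data.frame(summary(fit)[[1]]))
  }
  flat <- do.call(rbind, lapply(strata, function(s) {
    s$term <- trimws(rownames(s))
    s
  }))
  resid_df <- flat$Df[grepl("^Residuals", flat$term)]
  flat <- flat[!grepl("^Residuals", flat$term) & !is.na(flat[["F value"]]), ,
               drop = FALSE]
  stat <- flat[["F value"]]
  names(stat) <- flat$term
  pv <- flat[["Pr(>F)"]]
  details <- list(formula = deparse(fml))
  # Greenhouse-Geisser correction for a single within factor
  if (length(within) == 1 && length(unique(data[[within[1]]])) > 2) {
    wide <- tapply(data[[value]], list(data[[subject]], data[[within[1]]]),
                   mean)
    if (!anyNA(wide)) {
      eps <- gg_epsilon(wide)
      details$gg_epsilon <- eps
      iw <- grepl(within[1], names(stat), fixed = TRUE)
      if (any(iw) && length(resid_df)) {
        # corrected df scale numerator and denominator by epsilon
        dfn <- flat$Df[iw]
        dfd <- rep(resid_df[length(resid_df)], sum(iw))
        details$gg_p <- stats::pf(stat[iw], dfn * eps, dfd * eps,
                                  lower.tail = FALSE)
      }
    }
  }
  pw <- NULL
  if (posthoc != "none") {
    adj <- if (posthoc == "auto") {
      if (length(factors) >= 3) "bonferroni" else "tukey"
    } else posthoc
    spec <- stats::as.formula(paste("~", paste(factors, collapse = " * ")))
    em <- suppressMessages(emmeans::emmeans(fit, spec, data = data))
    pw <- as.data.frame(emmeans::contrast(em, method = "pairwise", adjust = adj))
    pw <- pw[, intersect(c("contrast", "estimate", "SE", "df", "t.ratio",
                           "p.value"), names(pw))]
    details$posthoc <- adj
  }
  new_test_result(
    method = sprintf("%d-factor ANOVA%s", length(factors),
                     if (!is.null(within)) " with repeated measures" else ""),
    statistic = stat, df = Map(c, flat$Df, NA), p_value = pv,
    pairwise = pw, details = details)
}

#' Kruskal-Wallis rank test
#'
#' Thin wrapper over [stats::kruskal.test()] (average ranks, tie-corrected H,
#' chi-square p-value) returning the package's common test-result container.
#' With all values tied the statistic is 0 and p = 1, with a warning.
#'
#' @param values Numeric response.
#' @param groups Grouping factor.
#' @return A `bp_test`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  if (length(unique(values)) == 1) {
    warning("all values tied; H = 0, p = 1")
    return(new_test_result("Kruskal-Wallis rank sum test",
                           c(H = 0), list(length(levels(groups)) - 1), 1))
  }
  kt <- stats::kruskal.test(values, groups)
  new_test_result("Kruskal-Wallis rank sum test",
                  c(H = unname(kt$statistic)), list(unname(kt$parameter)),
                  kt$p.value)
}

#' Steel-Dwass all-pairs nonparametric comparison
#'
#' The Steel-Dwass-Critchlow-Fligner procedure: for every pair of groups the
#' Wilcoxon rank sum (computed on the two groups' pooled ranks, average ranks
#' for ties) is standardized by its tie-corrected null mean and variance and
#' referred to the Studentized range distribution with `k` groups and
#' infinite error degrees of freedom.
#'
#' @param values Numeric response.
#' @param groups Grouping factor (>= 3 groups, each n >= 2).
#' @return A `bp_test` whose `pairwise` table has `comparison`, `estimate`
#'   (Hodges-Lehmann shift), `statistic` (standardized rank sum) and
#'   adjusted `p.value`.
#' @export
steel_dwass <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  lev <- levels(groups)
  k <- length(lev)
  if (k < 3) stop("Steel-Dwass needs at least 3 groups")
  ns <- table(groups)
  if (any(ns < 2)) stop("every group needs n >= 2")
  prs <- utils::combn(k, 2)
  rows <- apply(prs, 2, function(ij) {
    xi <- values[groups == lev[ij[1]]]
    xj <- values[groups == lev[ij[2]]]
    ni <- length(xi); nj <- length(xj); N <- ni + nj
    r <- rank(c(xi, xj))
    Ri <- sum(r[seq_len(ni)])
    E <- ni * (N + 1) / 2
    ties <- table(c(xi, xj))
    tiecor <- sum(ties^3 - ties) / (N * (N - 1))
    V <- ni * nj / 12 * ((N + 1) - tiecor)
    z <- if (V > 0) (Ri - E) / sqrt(V) else 0
    p <- stats::ptukey(abs(z) * sqrt(2), k, Inf, lower.tail = FALSE)
    hl <- stats::median(outer(xi, xj, "-"))
    data.frame(comparison = paste(lev[ij[1]], "-", lev[ij[2]]),
               estimate = hl, statistic = z, p.value = p)
  })
  pw <- do.call(rbind, rows)
  new_test_result("Steel-Dwass multiple comparison",
                  stats::setNames(pw$statistic, pw$comparison),
                  NULL, pw$p.value, pairwise = pw,
                  details = list(k = k))
}

#' Paired dark/light comparison
#'
#' Paired t test when the Shapiro-Wilk test on the paired differences does
#' not reject normality, Wilcoxon signed-rank otherwise. Zero-variance
#' differences short-circuit: p = 1 when all differences are 0, and a
#' minimal-variance t test is not attempted otherwise (the sign test via the
#' signed rank is used).
#'
#' @param x,y Paired numeric vectors (n >= 3).
#' @param alpha Normality-gate level.
#' @return A `bp_test` with the mean difference in `details$estimate`.
#' @export
paired_compare <- function(x, y, alpha = 0.05) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  d <- x - y
  if (all(d == 0))
    return(new_test_result("paired t test (degenerate: all differences 0)",
                           c(t = 0), list(length(d) - 1), 1,
                           details = list(estimate = 0)))
  sw <- if (stats::var(d) > 0 && length(d) >= 3 && length(unique(d)) > 1)
    stats::shapiro.test(d)$p.value else 0
  if (sw >= alpha) {
    tt <- stats::t.test(x, y, paired = TRUE)
    new_test_result("paired t test", c(t = unname(tt$statistic)),
                    list(unname(tt$parameter)), tt$p.value,
                    details = list(estimate = mean(d), shapiro_p = sw))
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE))
    new_test_result("Wilcoxon signed-rank test",
                    c(V = unname(wt$statistic)), NULL, wt$p.value,
                    details = list(estimate = stats::median(d),
                                   shapiro_p = sw))
  }
}

#' Run the full decision tree on a grouped table
#'
#' Routes via [route_test()] then applies the parametric chain
#' ([factorial_anova()] with its post hoc) or the nonparametric chain
#' ([kruskal_wallis()] followed by [steel_dwass()] when it is significant
#' and there are >= 3 groups).
#'
#' @param data Long-format data frame.
#' @param value Response column name.
#' @param factors Factor column names.
#' @param within,subject Repeated-measures specification, see
#'   [factorial_anova()].
#' @param alpha Gate and post hoc trigger level.
#' @return List with `trace` (a `decision_trace`), `test` (a `bp_test`) and
#'   `posthoc` (a `bp_test` or `NULL`).
#' @export
decision_tree <- function(data, value, factors, within = NULL, subject = NULL,
                          alpha = 0.05) {
  grp <- interaction(data[factors], drop = TRUE)
  trace <- route_test(data[[value]], grp, alpha = alpha)
  if (trace$route == "parametric") {
    test <- factorial_anova(data, value, factors, within, subject)
    list(trace = trace, test = test, posthoc = NULL)
  } else {
    test <- kruskal_wallis(data[[value]], grp)
    ph <- if (test$p_value < alpha && nlevels(grp) >= 3)
      steel_dwass(data[[value]], grp) else NULL
    list(trace = trace, test = test, posthoc = ph)
  }
}
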