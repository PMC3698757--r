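# The decision tree and its component tests.

test_that("routing passes clean normal data and catches lognormal or degenerate groups", {
  set.seed(51)
  ok <- route_test(rnorm(60), rep(1:3, each = 20))
  expect_equal(ok$route, "parametric")
  skewed <- route_test(c(rlnorm(20, 0, 1), rnorm(40)), rep(1:3, each = 20))
  expect_equal(skewed$route, "nonparametric")
  const <- route_test(rep(c(1, 2, 3), each = 5), rep(1:3, each = 5))
  expect_equal(const$route, "nonparametric")
  expect_match(const$reason, "zero variance")
  tiny <- route_test(rnorm(4), rep(1:2, each = 2))
  expect_equal(tiny$route, "nonparametric")
  expect_match(tiny$reason, "too small")
})

test_that("routing keeps its nominal operating characteristics on normal data", {
  set.seed(52)
  par_rate <- mean(replicate(300, {
    route_test(rnorm(60), rep(1:3, each = 20))$route == "parametric"
  }))
  # three Shapiro tests and one Bartlett at alpha 0.05 each: parametric in
  # roughly (1 - 0.05)^4 ~ 81% of draws; allow wide Monte-Carlo slack
  expect_gt(par_rate, 0.70)
  lognorm_rate <- mean(replicate(100, {
    route_test(c(rlnorm(20, 0, 1), rnorm(40)),
               rep(1:3, each = 20))$route == "nonparametric"
  }))
  expect_gt(lognorm_rate, 0.9)
})

test_that("one-factor two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(53)
  d <- data.frame(value = c(rnorm(12), rnorm(12, 0.8)),
                  g = factor(rep(1:2, each = 12)))
  ft <- factorial_anova(d, "value", "g", posthoc = "none")
  tt <- stats::t.test(value ~ g, d, var.equal = TRUE)
  expect_equal(unname(ft$statistic[1]), unname(tt$statistic^2),
               tolerance = 1e-9)
  expect_equal(ft$p_value[1], tt$p.value, tolerance = 1e-9)
})

test_that("two-factor F statistics match the closed-form balanced-design oracle", {
  set.seed(54)
  d <- expand.grid(a = factor(1:2), b = factor(1:3), rep = 1:6)
  d$value <- rnorm(36) + as.numeric(d$a) * 0.5 + as.numeric(d$b) * 0.3
  ft <- factorial_anova(d, "value", c("a", "b"))
  want <- anova2_oracle(d$value, d$a, d$b)
  expect_equal(unname(ft$statistic[c("a", "b", "a:b")]), unname(want),
               tolerance = 1e-9)
  expect_equal(ft$details$posthoc, "tukey")
  expect_equal(nrow(ft$pairwise), choose(6, 2))   # all 2x3 cell pairs
})

test_that("three-factor designs post hoc with Bonferroni t and repeated measures fit", {
  d <- expand.grid(a = factor(1:2), b = factor(1:2), w = factor(1:3),
                   subj = factor(1:4))
  set.seed(55)
  d$value <- rnorm(48) + rep(rnorm(4), each = 12) + as.numeric(d$w)
  ft <- factorial_anova(d, "value", c("a", "b", "w"), within = "w",
                        subject = "subj")
  expect_equal(ft$details$posthoc, "bonferroni")
  expect_true(all(ft$pairwise$p.value >= 0 & ft$pairwise$p.value <= 1))
  expect_true("w" %in% names(ft$statistic))
  expect_true(is.numeric(ft$details$gg_epsilon))
  expect_true(ft$details$gg_epsilon <= 1 + 1e-9 &&
                ft$details$gg_epsilon >= 1 / (3 - 1))
})

test_that("Kruskal-Wallis H matches the rank formula and degenerates sanely", {
  kw <- kruskal_wallis(1:9, rep(1:3, each = 3))
  expect_equal(unname(kw$statistic), 7.2)
  expect_warning(kw0 <- kruskal_wallis(rep(5, 9), rep(1:3, each = 3)), "tied")
  expect_equal(unname(kw0$statistic), 0)
  expect_equal(kw0$p_value, 1)
})

test_that("Steel-Dwass flags only pairs involving a strongly shifted group", {
  set.seed(56)
  v <- c(rnorm(10), rnorm(10), rnorm(10) + 5)
  g <- rep(c("A", "B", "C"), each = 10)
  sd_ <- steel_dwass(v, g)
  pw <- sd_$pairwise
  expect_equal(nrow(pw), 3)
  hit <- grepl("C", pw$comparison)
  expect_true(all(pw$p.value[hit] < 0.05))
  expect_true(all(pw$p.value[!hit] > 0.05))
  # permutation invariance to group labels
  perm <- sample(30)
  sd2 <- steel_dwass(v[perm], g[perm])
  expect_equal(sort(sd2$pairwise$p.value), sort(pw$p.value), tolerance = 1e-12)
  expect_error(steel_dwass(v[1:20], g[1:20]), "3 groups")
})

test_that("two-group Steel-Dwass-style z agrees with the normal-approximation Wilcoxon", {
  # k = 3 with one irrelevant far group: the A-B pair's standardized rank sum
  # must match an independent large-sample Wilcoxon z for A vs B
  set.seed(57)
  x <- rnorm(12); y <- rnorm(12, 1)
  v <- c(x, y, rnorm(12, 50)); g <- rep(c("A", "B", "C"), each = 12)
  z_pkg <- steel_dwass(v, g)$pairwise
  z_ab <- z_pkg$statistic[z_pkg$comparison == "A - B"]
  r <- rank(c(x, y)); R <- sum(r[1:12])
  z_ref <- (R - 12 * 25 / 2) / sqrt(12 * 12 * 25 / 12)
  expect_equal(z_ab, z_ref, tolerance = 1e-9)
})

test_that("paired comparison picks its test by normality and handles degeneracy", {
  x <- c(5, 6, 7, 8, 9)
  same <- paired_compare(x, x)
  expect_equal(same$p_value, 1)
  expect_equal(same$details$estimate, 0)
  set.seed(58)
  a <- rnorm(10); b <- a - 2 + rnorm(10, 0, 0.5)
  pc <- paired_compare(a, b)
  expect_match(pc$method, "paired t")
  expect_lt(pc$p_value, 0.01)
  # constant nonzero shift: zero-variance differences route to signed rank
  shift <- paired_compare(x + 3, x)
  expect_match(shift$method, "signed-rank")
  expect_lt(shift$p_value, 0.07)      # n = 5: smallest attainable ~ 0.0625
})

test_that("paired test power at shift/SD = 2 with n = 7 clears 80%", {
  set.seed(59)
  hits <- mean(replicate(400, {
    x <- rnorm(7); y <- x - 2 + rnorm(7)
    paired_compare(x, y)$p_value < 0.05
  }))
  expect_gt(hits, 0.8)
})

test_that("the assembled decision tree returns consistent route and tests", {
  set.seed(60)
  eff <- expand.grid(strain = c("W", "S", "cp"), period = c("d", "l"))
  eff$mean <- 10; eff$sd <- 1
  tab <- make_biomarker_tables(eff, n_per_cell = 8, seed = 61)
  res <- decision_tree(tab, "value", c("strain", "period"))
  if (res$trace$route == "parametric") {
    expect_match(res$test$method, "ANOVA")
  } else {
    expect_match(res$test$method, "Kruskal")
  }
  # planted lognormal heterogeneity routes nonparametric and flags the shift
  eff2 <- eff; eff2$dist <- "lognormal"; eff2$sd <- c(8, 1, 1, 1, 1, 1)
  eff2$mean[1] <- 30
  tab2 <- make_biomarker_tables(eff2, n_per_cell = 10, seed = 62)
  res2 <- decision_tree(tab2, "value", c("strain", "period"))
  expect_equal(res2$trace$route, "nonparametric")
})
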