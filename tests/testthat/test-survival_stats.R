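test_that("Kaplan-Meier matches the hand product-limit computation", {
  # events at t = 1 and 2, censoring at 2.5: S(1) = (1 - 1/3) = 2/3,
  # S(2) = 2/3 * (1 - 1/2) = 1/3 by the product limit
  km <- kaplan_meier(c(1, 2.5, 2), c(1, 0, 1))
  surv_at <- function(t) km$survival[km$time == t]
  expect_equal(surv_at(1), 2 / 3)
  expect_equal(surv_at(2), 1 / 3)
  # no events: survival constant 1
  km0 <- kaplan_meier(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km0$survival == 1))
  # curves are non-increasing within each group and stay in [0, 1]
  set.seed(1)
  km2 <- kaplan_meier(rexp(40) + 0.01, rbinom(40, 1, 0.7),
                      rep(c("a", "b"), 20))
  for (g in unique(km2$group)) {
    s <- km2$survival[km2$group == g][order(km2$time[km2$group == g])]
    expect_true(all(diff(s) <= 1e-12))
    expect_true(all(s >= 0 & s <= 1))
  }
  expect_error(kaplan_meier(c(0, 1), c(1, 1)), "times")
})

test_that("Kaplan-Meier without censoring equals the empirical survivor", {
  t <- c(1, 2, 3, 4, 5)
  km <- kaplan_meier(t, rep(1, 5))
  expect_equal(km$survival[match(t, km$time)], 1 - ecdf(t)(t))
})

test_that("logrank matches a hand observed-minus-expected computation", {
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(1, 1, 0, 1, 1, 0)
  groups <- rep(c("a", "b"), 3)
  res <- logrank_test(time, event, groups)
  expect_equal(res$statistic, unname(logrank_by_hand(time, event, groups)),
               tolerance = 1e-10)
  expect_equal(res$df, 1L)
  # identical groups: statistic ~ 0, p ~ 1
  res0 <- logrank_test(rep(c(1, 2, 3), 2), rep(c(1, 1, 0), 2),
                       rep(c("a", "b"), each = 3))
  expect_lt(res0$statistic, 1e-10)
  expect_equal(res0$p_value, 1, tolerance = 1e-6)
  # all censored: defined degenerate result
  resc <- logrank_test(c(1, 2, 3, 4), rep(0, 4), rep(c("a", "b"), 2))
  expect_equal(resc$statistic, 0)
  expect_equal(resc$p_value, 1)
  # symmetric under group-label swap
  swapped <- logrank_test(time, event, rev(groups))
  expect_equal(res$statistic,
               logrank_test(time, event, c("b", "a")[match(groups, c("a", "b"))])$statistic)
})

test_that("cluster-dependent hazards are detected with the planted power", {
  ps <- sapply(1:10, function(s) {
    coh <- generate_tnbc_cohort(cohort_spec(seed = s))
    cli <- coh$clinical
    logrank_test(cli$efs_time, cli$efs_event, cli$cluster)$p_value
  })
  expect_gte(sum(ps < 0.05), 8)
})

test_that("Cox fits recover planted effects and respect symmetries", {
  # null covariate: HR close to 1, CI covers 1 in most seeds
  cover <- sapply(1:10, function(s) with_seed(s, {
    n <- 120
    t <- rexp(n, 0.1); cc <- rexp(n, 0.05)
    fit <- cox_univariate(pmin(t, cc), as.integer(t <= cc), rnorm(n))
    fit$ci95[1] <= 1 && 1 <= fit$ci95[2]
  }))
  expect_gte(mean(cover), 0.8)
  # negating the covariate inverts the hazard ratio (per-unit scale)
  with_seed(3, {
    n <- 80
    x <- rnorm(n)
    t <- rexp(n, exp(0.4 * x) * 0.1)
    f1 <- cox_univariate(t, rep(1, n), x, scale = "per_unit")
    f2 <- cox_univariate(t, rep(1, n), -x, scale = "per_unit")
    expect_equal(f1$hazard_ratio, 1 / f2$hazard_ratio, tolerance = 1e-8)
    expect_true(f1$ci95[1] <= f1$hazard_ratio &&
                f1$hazard_ratio <= f1$ci95[2])
  })
  # planted per-SD log hazard recovered on average at n = 200
  logs <- sapply(1:20, function(s) with_seed(s, {
    n <- 200
    x <- rnorm(n)
    t <- rexp(n, exp(-0.5 * x) * 0.1)
    cc <- pmin(rexp(n, 0.04), 15)
    cox_univariate(pmin(t, cc), as.integer(t <= cc), x)$log_hr
  }))
  expect_lt(abs(mean(logs) - (-0.5)), 0.15)
  expect_error(cox_univariate(c(1, 2, 3), c(1, 1, 0), c(2, 2, 2)), "vary")
})

test_that("group comparison kinds match their base oracles", {
  # Fisher on (3,0;0,3): enumeration gives p = 2 / choose(6,3) = 0.1
  res <- group_compare("fisher_exact", table = matrix(c(3, 0, 0, 3), 2))
  p_enum <- (dhyper(3, 3, 3, 3) + dhyper(0, 3, 3, 3))
  expect_equal(res$p_value, p_enum)
  expect_equal(res$p_value, 0.1)
  expect_error(group_compare("fisher_exact", table = matrix(c(0, 0, 1, 2), 2)),
               "margin")
  # perfectly linear vectors: r = 1
  expect_equal(group_compare("pearson_cor", values = 1:10,
                             values2 = 2 * (1:10) + 3)$r, 1)
  expect_error(group_compare("pearson_cor", values = 1:5,
                             values2 = rep(1, 5)), "constant")
  # ANOVA + Tukey against stats::aov/TukeyHSD on the same data
  with_seed(2, {
    v <- c(rnorm(10, 0), rnorm(10, 1), rnorm(10, 3))
    g <- rep(c("x", "y", "z"), each = 10)
    res <- group_compare("anova_tukey", values = v, groups = g)
    ref <- summary(aov(v ~ factor(g)))[[1]]
    expect_equal(res$p_value, ref$`Pr(>F)`[1])
    expect_equal(nrow(res$tukey), 3)
    expect_true(all(res$tukey$p_adjusted >= 0 & res$tukey$p_adjusted <= 1))
  })
})

test_that("age-structured clusters separate by ANOVA with high power", {
  # three groups at the cohort's age means and sizes, sd 12
  hits <- sapply(1:10, function(s) with_seed(s, {
    v <- c(rnorm(24, 64.6, 12), rnorm(48, 56.8, 12), rnorm(35, 51.9, 12))
    g <- rep(1:3, c(24, 48, 35))
    group_compare("anova_tukey", values = v, groups = g)$p_value < 0.01
  }))
  expect_gte(sum(hits), 8)
})
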