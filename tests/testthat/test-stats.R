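test_that("summary-statistics ANOVA is identical to raw-data ANOVA", {
  # small printed-style dataset, 3 groups x 5 observations
  raw <- data.frame(
    y = c(4.1, 5.2, 3.9, 4.8, 5.0,
          5.6, 6.1, 5.9, 6.4, 5.2,
          4.0, 4.4, 3.6, 4.9, 4.2),
    g = rep(c("A", "B", "C"), each = 5))
  fit <- anova(aov(y ~ g, data = raw))
  res <- anova_oneway_summary(summarize_groups(raw$y, raw$g))
  expect_equal(res$statistic, fit$`F value`[1], tolerance = 1e-12)
  expect_equal(res$p_value, fit$`Pr(>F)`[1], tolerance = 1e-12)
  expect_equal(res$ss_between, fit$`Sum Sq`[1], tolerance = 1e-12)
  expect_equal(res$ss_within, fit$`Sum Sq`[2], tolerance = 1e-12)

  # identical groups: no between-group variation
  same <- group_summary(c("A", "B", "C"), c(10, 10, 10), c(2, 2, 2),
                        c(0.5, 0.5, 0.5))
  res0 <- anova_oneway_summary(same)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  expect_error(anova_oneway_summary(same[1, ]), "2 groups")
})

test_that("Bonferroni post hoc has the pooled-SE simultaneous-CI structure", {
  s <- group_summary(c("A", "B", "C"), c(12, 15, 10),
                     c(2.0, 2.0, 2.6), c(0.5, 0.6, 0.5))
  ph <- posthoc_bonferroni(s, c("A", "B"))
  expect_equal(ph$mean_diff, 0)
  expect_equal(ph$p_adjusted, 1)  # capped at 1

  set.seed(3)
  for (i in 1:20) {
    s <- group_summary(c("A", "B", "C"), sample(5:30, 3),
                       rnorm(3), runif(3, 0.3, 2))
    pair <- sample(c("A", "B", "C"), 2)
    ph <- posthoc_bonferroni(s, pair)
    expect_gte(ph$p_adjusted, ph$p_unadjusted)
    expect_lte(ph$p_adjusted, 1)
    expect_lte(ph$ci_lower, ph$mean_diff)
    expect_gte(ph$ci_upper, ph$mean_diff)
    # SE pools MSW over all groups, df = N - g
    msw <- sum((s$n - 1) * s$sd^2) / (sum(s$n) - 3)
    i1 <- match(pair[1], s$group); i2 <- match(pair[2], s$group)
    expect_equal(ph$se, sqrt(msw * (1 / s$n[i1] + 1 / s$n[i2])),
                 tolerance = 1e-12)
    expect_equal(ph$df, sum(s$n) - 3)
  }
  expect_error(posthoc_bonferroni(s, c("A", "Z")), "unknown group")
})

test_that("two-sample t-tests agree with the standard implementation", {
  a <- c(1, 2, 3); b <- c(2, 3, 4)
  res <- two_sample_ttest(a, b)
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(res$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
  # summary path reproduces the raw path exactly
  res2 <- ttest_from_summary(3, mean(a), sd(a), 3, mean(b), sd(b))
  expect_equal(res2$t, res$t, tolerance = 1e-12)
  expect_equal(res2$p_value, res$p_value, tolerance = 1e-12)
  # degenerate cases
  same <- ttest_from_summary(5, 2, 0, 5, 2, 0)
  expect_equal(same$t, 0); expect_equal(same$p_value, 1)
  expect_error(ttest_from_summary(5, 2, 0, 5, 3, 0), "zero pooled")
  # published HIT-6 row (rounded summaries drift slightly from print)
  hit6 <- ttest_from_summary(25, 64.2, 6.8, 23, 68.0, 5.5)
  expect_lt(abs(hit6$p_value - 0.043), 0.005)
})

test_that("paired t-test handles pairing and the all-zero degenerate case", {
  x <- c(5, 6, 7, 8)
  same <- paired_ttest(x, x)
  expect_equal(same$mean_diff, 0); expect_equal(same$p_value, 1)
  d <- c(1, 2, 3, 4)
  res <- paired_ttest(x + d, x)
  expect_equal(res$t, mean(d) / (sd(d) / sqrt(4)), tolerance = 1e-12)
  expect_equal(res$mean_diff, 2.5)
  expect_error(paired_ttest(1:3, 1:4), "equal length")

  # paired recovery of a within-subject right-left offset of 0.118
  # under realistic between-hemisphere correlation
  set.seed(11)
  left <- rnorm(24, 1.65, 0.16)
  right <- left + rnorm(24, 0.118, 0.08)
  rec <- paired_ttest(right, left)
  se <- sd(right - left) / sqrt(24)
  expect_lt(abs(rec$mean_diff - 0.118), 3 * se)
})

test_that("Mann-Whitney exact enumeration and approximation agree", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p_value, 0.1, tolerance = 1e-12)  # 2/20 orderings
  expect_equal(res$method, "exact")
  # agreement with the standard exact implementation (no ties)
  set.seed(4)
  a <- rnorm(5); b <- rnorm(5, 1)
  expect_equal(mann_whitney_u(a, b)$p_value,
               wilcox.test(a, b, exact = TRUE)$p.value, tolerance = 1e-12)
  # identical multisets are a null result
  expect_equal(mann_whitney_u(c(1, 2, 2, 3), c(1, 2, 2, 3))$p_value, 1)
  # exact and normal-approximation paths agree to within 0.05
  set.seed(9)
  for (i in 1:10) {
    a <- sample(1:20, 5, replace = TRUE); b <- sample(1:20, 5, replace = TRUE)
    exact <- mann_whitney_u(a, b)$p_value
    approx <- wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
    expect_lt(abs(exact - approx), 0.05)
  }
})

test_that("Pearson chi-square is uncorrected with closed-form df = 2 tail", {
  prop <- matrix(c(10, 10, 10, 10), 2)
  res <- chi_square_rxc(prop)
  expect_equal(res$statistic, 0); expect_equal(res$p_value, 1)
  # df = 2: upper tail is exp(-x/2)
  sex <- matrix(c(16, 25, 9, 23, 9, 15), 2)
  r2 <- chi_square_rxc(sex)
  expect_equal(r2$df, 2)
  expect_equal(r2$p_value, exp(-r2$statistic / 2), tolerance = 1e-10)
  expect_error(chi_square_rxc(matrix(c(1, 2, 0, 0), 2)), "margin")
  expect_error(chi_square_rxc(matrix(c(1.5, 2, 3, 4), 2)), "integers")
})

test_that("partial correlation equals the precision-matrix formula", {
  set.seed(21)
  n <- 60
  z1 <- rnorm(n); z2 <- rnorm(n)
  x <- 0.5 * z1 + rnorm(n)
  y <- 0.3 * z1 - 0.4 * z2 + 0.4 * x + rnorm(n)
  res <- partial_correlation(x, y, cbind(z1, z2))
  P <- solve(cor(cbind(x, y, z1, z2)))
  r_ref <- -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
  expect_equal(res$r, r_ref, tolerance = 1e-12)
  expect_equal(res$df, n - 4)
  # residual orthogonality: a pure covariate function is uncorrelated
  res0 <- partial_correlation(x, 2 * z1 - z2 + 1, cbind(z1, z2))
  expect_equal(res0$r, 0)
  expect_error(partial_correlation(x, y, cbind(z1, z1)), "collinear")
})

test_that("Bonferroni threshold is alpha over m", {
  expect_equal(bonferroni_threshold(0.05, 20), 0.0025)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.10, 4), 0.025)
  expect_error(bonferroni_threshold(0.05, 0), "m")
})

test_that("analytic ANOVA power has size alpha and matches simulation", {
  null <- group_summary(c("A", "B", "C"), c(20, 25, 30), c(1, 1, 1),
                        c(0.4, 0.4, 0.4))
  expect_equal(anova_power(null, alpha = 0.05), 0.05, tolerance = 1e-12)
  expect_equal(anova_power(null, alpha = 0.05, convention = "weighted"),
               0.05, tolerance = 1e-12)
  # equal n, equal sd: the two conventions coincide and match Monte Carlo
  s <- group_summary(c("A", "B", "C"), c(30, 30, 30),
                     c(1.6, 1.6, 1.75), c(0.2, 0.2, 0.2))
  pu <- anova_power(s); pw <- anova_power(s, convention = "weighted")
  expect_equal(pu, pw, tolerance = 1e-12)
  mc <- anova_power_sim(s, nrep = 4000, seed = 8)
  expect_lt(abs(pu - mc), 2 * sqrt(pu * (1 - pu) / 4000))
  # unequal n: weighted convention is exact for the homoscedastic model
  s2 <- paper_alps_summary()
  mc2 <- anova_power_sim(s2, nrep = 4000, seed = 9)
  pw2 <- anova_power(s2, convention = "weighted")
  expect_lt(abs(pw2 - mc2), 2 * sqrt(pw2 * (1 - pw2) / 4000))
})

test_that("normality screening routes to t or Mann-Whitney", {
  set.seed(14)
  a <- rnorm(30); b <- rnorm(30, 0.5)
  expect_equal(compare_two_groups(a, b)$test, "t")
  skew_a <- rexp(30)^3; skew_b <- rexp(30)^3 * 2
  expect_equal(compare_two_groups(skew_a, skew_b)$test, "mann-whitney")
})

test_that("cohort analysis reports the full battery on a simulated cohort", {
  cohort <- simulate_cohort(default_cohort_spec(seed = 31))
  res <- analyze_cohort(cohort$table)
  expect_true(all(c("anova_left", "anova_right", "posthoc_right_cm_hc",
                    "posthoc_right_cm_em", "paired_right_left_cm",
                    "anova_age", "chisq_sex", "em_cm_vas",
                    "cor_vas_left", "cor_vas_right") %in% names(res)))
  expect_true(res$anova_right$p_value > 0 && res$anova_right$p_value <= 1)
  expect_equal(res$cor_vas_left$k, 2)
  # group labels flow through the post hoc
  expect_match(res$posthoc_right_cm_hc$pair, "CM - HC")
})
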