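#' Group summaries
#'
#' Most published group comparisons are recomputable from the
#' `(n, mean, sd)` triple of each group. `group_summary()` builds the
#' summary table used throughout the statistics stage;
#' `summarize_groups()` derives it from raw values.
#'
#' @param group character group labels.
#' @param n integer counts (>= 2).
#' @param mean,sd group means and standard deviations (`sd > 0`).
#' @return data.frame with columns `group`, `n`, `mean`, `sd`.
#' @export
group_summary <- function(group, n, mean, sd) {
  out <- data.frame(group = as.character(group), n = as.integer(n),
                    mean = as.numeric(mean), sd = as.numeric(sd))
  if (any(out$n < 2)) stop("each group needs n >= 2", call. = FALSE)
  if (any(out$sd <= 0)) stop("group SDs must be > 0", call. = FALSE)
  out
}

#' @rdname group_summary
#' @param values numeric vector of observations.
#' @param groups group label per observation.
#' @export
summarize_groups <- function(values, groups) {
  sp <- split(values, groups)
  group_summary(names(sp), lengths(sp),
                vapply(sp, mean, 0), vapply(sp, sd, 0))
}

#' One-way ANOVA from group summaries
#'
#' Between- and within-group sums of squares are recovered exactly from
#' `(n, mean, sd)`: `SSB = sum n_i (m_i - m)^2` with `m` the weighted
#' grand mean, and `SSW = sum (n_i - 1) s_i^2`, so the result is
#' algebraically identical to a raw-data one-way ANOVA whenever the
#' summaries are exact.
#'
#' @param summ a [group_summary()] data.frame (>= 2 groups).
#' @return list of class `alps_anova`: `ss_between`, `ss_within`,
#'   `df_between`, `df_within`, `ms_between`, `ms_within`, `statistic`
#'   (F) and `p_value`.
#' @examples
#' s <- group_summary(c("HC", "EM", "CM"), c(41, 32, 24),
#'                    c(1.63, 1.64, 1.77), c(0.18, 0.17, 0.23))
#' anova_oneway_summary(s)$p_value
#' @export
anova_oneway_summary <- function(summ) {
  if (nrow(summ) < 2) stop("ANOVA needs at least 2 groups", call. = FALSE)
  N <- sum(summ$n); g <- nrow(summ)
  gm <- sum(summ$n * summ$mean) / N
  ssb <- sum(summ$n * (summ$mean - gm)^2)
  ssw <- sum((summ$n - 1) * summ$sd^2)
  msb <- ssb / (g - 1); msw <- ssw / (N - g)
  f <- msb / msw
  structure(list(ss_between = ssb, ss_within = ssw,
                 df_between = g - 1, df_within = N - g,
                 ms_between = msb, ms_within = msw,
                 statistic = f,
                 p_value = pf(f, g - 1, N - g, lower.tail = FALSE)),
            class = "alps_anova")
}

#' @export
print.alps_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4f, p = %.4g\n",
              x$df_between, x$df_within, x$statistic, x$p_value))
  invisible(x)
}

#' Bonferroni post hoc comparison (pooled-variance dialect)
#'
#' Pairwise comparison following a one-way ANOVA, in the dialect used by
#' mainstream clinical statistics software: the standard error pools the
#' within-group mean square over *all* groups
#' (`SE = sqrt(MSW (1/n_i + 1/n_j))`, `df = N - g`), the adjusted
#' p-value is `min(1, k p)` with `k = g(g-1)/2` pairs, and the
#' simultaneous confidence interval uses `t(df, 1 - alpha/(2k))`.
#'
#' @param summ a [group_summary()] data.frame of all groups.
#' @param pair length-2 character vector of group labels; the mean
#'   difference is first minus second.
#' @param alpha family significance level (default 0.05).
#' @param mean_diff optional published mean difference to use in place
#'   of the difference of the (possibly rounded) summary means, when a
#'   source reports it at higher precision.
#' @return data.frame row: `pair`, `mean_diff`, `se`, `t`, `df`,
#'   `p_unadjusted`, `p_adjusted`, `ci_lower`, `ci_upper`.
#' @export
posthoc_bonferroni <- function(summ, pair, alpha = 0.05, mean_diff = NULL) {
  if (!all(pair %in% summ$group))
    stop("unknown group in pair: ", paste(setdiff(pair, summ$group),
                                          collapse = ", "), call. = FALSE)
  g <- nrow(summ); N <- sum(summ$n)
  k <- g * (g - 1) / 2
  msw <- sum((summ$n - 1) * summ$sd^2) / (N - g)
  i <- match(pair[1], summ$group); j <- match(pair[2], summ$group)
  md <- mean_diff %||% (summ$mean[i] - summ$mean[j])
  se <- sqrt(msw * (1 / summ$n[i] + 1 / summ$n[j]))
  df <- N - g
  t <- md / se
  p <- 2 * pt(-abs(t), df)
  tcrit <- qt(1 - alpha / (2 * k), df)
  data.frame(pair = paste(pair, collapse = " - "),
             mean_diff = md, se = se, t = t, df = df,
             p_unadjusted = p, p_adjusted = min(1, k * p),
             ci_lower = md - tcrit * se, ci_upper = md + tcrit * se)
}

#' Independent-samples t-test from summaries
#'
#' Student's pooled-variance t-test (the "equal variances assumed" row)
#' by default; `pooled = FALSE` gives the Welch test. Operates on
#' `(n, mean, sd)` so published table rows can be re-tested.
#'
#' @param n1,m1,s1,n2,m2,s2 per-group count, mean and SD.
#' @param pooled use the pooled-variance Student test (default `TRUE`).
#' @return list: `t`, `df`, `p_value`, `mean_diff`.
#' @export
ttest_from_summary <- function(n1, m1, s1, n2, m2, s2, pooled = TRUE) {
  stopifnot(n1 >= 2, n2 >= 2)
  md <- m1 - m2
  if (pooled) {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    if (sp2 == 0) {
      if (md != 0)
        stop("zero pooled variance with unequal means", call. = FALSE)
      return(list(t = 0, df = n1 + n2 - 2, p_value = 1, mean_diff = 0))
    }
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- s1^2 / n1; v2 <- s2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- md / se
  list(t = t, df = df, p_value = 2 * pt(-abs(t), df), mean_diff = md)
}

#' @rdname ttest_from_summary
#' @param a,b raw samples.
#' @export
two_sample_ttest <- function(a, b, pooled = TRUE) {
  if (sd(a) == 0 && sd(b) == 0)
    return(ttest_from_summary(length(a), mean(a), 0, length(b), mean(b), 0,
                              pooled = TRUE))
  tt <- t.test(a, b, var.equal = pooled)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_diff = mean(a) - mean(b))
}

#' Paired t-test
#'
#' Standard paired t on the within-subject differences. The degenerate
#' case of all-zero differences is defined as a null result
#' (`mean_diff = 0`, `p = 1`) rather than an error, since it arises
#' naturally from noise-free simulations.
#'
#' @param a,b paired numeric vectors of equal length (>= 2).
#' @return list: `t`, `df`, `mean_diff`, `p_value`, `ci` (95 percent).
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b))
    stop("paired samples must have equal length", call. = FALSE)
  if (length(a) < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- a - b
  if (all(d == 0))
    return(list(t = 0, df = length(d) - 1, mean_diff = 0, p_value = 1,
                ci = c(0, 0)))
  if (sd(d) == 0)
    stop("constant non-zero differences: paired t undefined", call. = FALSE)
  tt <- t.test(d)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       mean_diff = mean(d), p_value = tt$p.value,
       ci = unname(tt$conf.int))
}

#' Mann-Whitney U test
#'
#' Exact two-sided p by full enumeration of the
#' `choose(n1 + n2, n1)` group assignments (conditional on the observed
#' pooled values, so ties are handled) when `n1 + n2 <= 12`; otherwise
#' the normal approximation with tie correction and continuity
#' correction. Two-sided exact p is `2 min(P(U <= u), P(U >= u))`
#' capped at 1.
#'
#' @param a,b numeric samples.
#' @return list: `U` (statistic of the first sample), `p_value`,
#'   `method`.
#' @export
mann_whitney_u <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty sample", call. = FALSE)
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  pooled <- c(a, b)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  U <- u_of(seq_len(n1))
  if (N <= 12) {
    combs <- combn(N, n1)
    us <- apply(combs, 2, u_of)
    p <- min(1, 2 * min(mean(us <= U), mean(us >= U)))
    return(list(U = U, p_value = p, method = "exact"))
  }
  mu <- n1 * n2 / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sig2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (sig2 <= 0) return(list(U = U, p_value = 1, method = "normal"))
  z <- max(abs(U - mu) - 0.5, 0) / sqrt(sig2)
  list(U = U, p_value = min(1, 2 * pnorm(-z)), method = "normal")
}

#' Pearson chi-square test for an r x c contingency table
#'
#' Pearson's statistic without continuity correction (the convention
#' that reproduces published SPSS "Pearson Chi-Square" rows), with
#' `df = (r - 1)(c - 1)`.
#'
#' @param tab matrix of non-negative integer counts, at least 2 x 2,
#'   with no zero row or column margin.
#' @return list: `statistic`, `df`, `p_value`, `expected`.
#' @export
chi_square_rxc <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("table must be at least 2 x 2", call. = FALSE)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero row or column margin", call. = FALSE)
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, expected = ct$expected)
}

#' Partial correlation adjusted for covariates
#'
#' Pearson correlation of the least-squares residuals of `x` and `y` on
#' an intercept plus the covariates, with
#' `df = n - 2 - k` and `t = r sqrt(df / (1 - r^2))`. This is the
#' "correlation adjusted for age and sex" of clinical ALPS studies.
#'
#' @param x,y numeric vectors.
#' @param covariates numeric matrix or data.frame of k covariate
#'   columns (factors must be coded numerically by the caller).
#' @return list of class `alps_partial_cor`: `r`, `n`, `k`, `df`, `t`,
#'   `p_value`.
#' @export
partial_correlation <- function(x, y, covariates) {
  C <- as.matrix(covariates)
  n <- length(x); k <- ncol(C)
  stopifnot(length(y) == n, nrow(C) == n)
  if (n <= k + 2) stop("need n > k + 2 observations", call. = FALSE)
  X <- cbind(1, C)
  if (qr(X)$rank < ncol(X))
    stop("collinear covariates", call. = FALSE)
  rx <- lm.fit(X, x)$residuals
  ry <- lm.fit(X, y)$residuals
  # a variable that is an exact covariate function has (numerically)
  # zero residuals: define the partial correlation as 0 rather than 0/0
  tol <- sqrt(.Machine$double.eps)
  degenerate <- sd(rx) <= tol * max(sd(x), 1) ||
    sd(ry) <= tol * max(sd(y), 1)
  r <- if (degenerate) 0 else cor(rx, ry)
  partial_correlation_test(r, n, k)
}

#' @rdname partial_correlation
#' @param r a (partial) correlation coefficient, e.g. a published one.
#' @param n number of observations; `k` number of covariates.
#' @export
partial_correlation_test <- function(r, n, k) {
  df <- n - 2 - k
  if (df < 1) stop("df = n - 2 - k must be >= 1", call. = FALSE)
  t <- r * sqrt(df / (1 - r^2))
  structure(list(r = r, n = n, k = k, df = df, t = t,
                 p_value = 2 * pt(-abs(t), df)),
            class = "alps_partial_cor")
}

#' @export
print.alps_partial_cor <- function(x, ...) {
  cat(sprintf("Partial correlation: r = %.3f (df = %d), p = %.4g\n",
              x$r, x$df, x$p_value))
  invisible(x)
}

#' Bonferroni significance threshold
#'
#' @param alpha familywise level.
#' @param m number of comparisons (>= 1).
#' @return `alpha / m`.
#' @examples bonferroni_threshold(0.05, 20)  # 0.0025
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  alpha / m
}

#' Analytic power of the one-way ANOVA
#'
#' Power of the omnibus F test for given group means, SDs and sizes,
#' from the noncentral F distribution:
#' `power = P(F'(g - 1, N - g, lambda) > F_crit)`. Two conventions for
#' the noncentrality are offered, differing in how the effect size f is
#' built from the group summaries:
#' \describe{
#'   \item{`"unweighted"`}{Cohen's f with unweighted means:
#'     `f^2 = (sum (m_i - mbar)^2 / g) / (mean s_i^2)`,
#'     `lambda = N f^2`.}
#'   \item{`"weighted"`}{sample-size-weighted means and the pooled
#'     within variance: `lambda = sum n_i (m_i - mw)^2 / MSW`.}
#' }
#' With all group means equal the power equals `alpha` (the size of the
#' test) under either convention.
#'
#' @param summ a [group_summary()] data.frame.
#' @param alpha two-sided significance level.
#' @param convention `"unweighted"` (default) or `"weighted"`.
#' @return power in `[alpha, 1)`.
#' @export
anova_power <- function(summ, alpha = 0.05,
                        convention = c("unweighted", "weighted")) {
  convention <- match.arg(convention)
  g <- nrow(summ); N <- sum(summ$n)
  if (g < 2) stop("need at least 2 groups", call. = FALSE)
  if (convention == "unweighted") {
    mbar <- mean(summ$mean)
    f2 <- (sum((summ$mean - mbar)^2) / g) / mean(summ$sd^2)
    lambda <- N * f2
  } else {
    mw <- sum(summ$n * summ$mean) / N
    msw <- sum((summ$n - 1) * summ$sd^2) / (N - g)
    lambda <- sum(summ$n * (summ$mean - mw)^2) / msw
  }
  fcrit <- stats::qf(1 - alpha, g - 1, N - g)
  pf(fcrit, g - 1, N - g, ncp = lambda, lower.tail = FALSE)
}

# draw nrep replicate (mean, sd) summaries per group under the normal model
simulate_summaries <- function(ns, means, sds, nrep) {
  g <- length(ns)
  m <- s <- matrix(0, g, nrep)
  for (i in seq_len(g)) {
    x <- matrix(rnorm(ns[i] * nrep, means[i], sds[i]), ns[i], nrep)
    m[i, ] <- colMeans(x)
    s[i, ] <- sqrt(colSums(sweep(x, 2, m[i, ])^2) / (ns[i] - 1))
  }
  list(mean = m, sd = s)
}

# vectorised omnibus F over replicate summaries
replicate_F <- function(ns, sim) {
  N <- sum(ns); g <- length(ns)
  gm <- colSums(sim$mean * ns) / N
  ssb <- colSums(ns * sweep(sim$mean, 2, gm)^2)
  ssw <- colSums((ns - 1) * sim$sd^2)
  (ssb / (g - 1)) / (ssw / (N - g))
}

#' @rdname anova_power
#' @param nrep number of Monte-Carlo replicates.
#' @param seed RNG seed for the simulation.
#' @param sd common within-group SD of the simulated model; defaults to
#'   the pooled within-group SD of `summ`.
#' @return `anova_power_sim()` returns the simulated rejection rate of
#'   the omnibus test under the homoscedastic normal model (the model
#'   in which the weighted noncentral-F power formula is exact), a
#'   Monte-Carlo check of the analytic power.
#' @export
anova_power_sim <- function(summ, alpha = 0.05, nrep = 10000, seed = 1,
                            sd = NULL) {
  g <- nrow(summ); N <- sum(summ$n)
  sd <- sd %||% sqrt(sum((summ$n - 1) * summ$sd^2) / (N - g))
  fcrit <- stats::qf(1 - alpha, g - 1, N - g)
  with_seed(seed, {
    sim <- simulate_summaries(summ$n, summ$mean, rep(sd, g), nrep)
    mean(replicate_F(summ$n, sim) > fcrit)
  })
}

#' Replicate-level operating characteristics of the ANOVA + post hoc
#'
#' `simulate_null_type1()` draws replicates of equal-mean homoscedastic
#' normal groups (common SD = the pooled within-group SD, the model
#' under which the F test has exactly its nominal size) and reports the
#' omnibus rejection rate, i.e. the empirical type-I error.
#' `simulate_group_detection()` draws replicates under the configured
#' group means and per-group SDs and reports how often the Bonferroni
#' post hoc flags the last group above each of the others (and both at
#' once), together with the omnibus rejection rate.
#'
#' @param summ a [group_summary()] data.frame; in
#'   `simulate_null_type1()` only the sizes and pooled SD matter (means
#'   are forced equal).
#' @param nrep number of replicates.
#' @param alpha significance level for omnibus and adjusted post hoc p.
#' @param seed RNG seed.
#' @return `simulate_null_type1()`: the rejection rate.
#'   `simulate_group_detection()`: list of rates `omnibus`,
#'   `last_vs_first`, `last_vs_second`, `joint`.
#' @export
simulate_null_type1 <- function(summ, nrep = 2000, alpha = 0.05, seed = 1) {
  g <- nrow(summ); N <- sum(summ$n)
  sd <- sqrt(sum((summ$n - 1) * summ$sd^2) / (N - g))
  fcrit <- stats::qf(1 - alpha, g - 1, N - g)
  with_seed(seed, {
    sim <- simulate_summaries(summ$n, rep(0, g), rep(sd, g), nrep)
    mean(replicate_F(summ$n, sim) > fcrit)
  })
}

#' @rdname simulate_null_type1
#' @export
simulate_group_detection <- function(summ, nrep = 100, alpha = 0.05,
                                     seed = 1) {
  g <- nrow(summ); N <- sum(summ$n)
  stopifnot(g >= 3)
  k <- g * (g - 1) / 2
  fcrit <- stats::qf(1 - alpha, g - 1, N - g)
  with_seed(seed, {
    sim <- simulate_summaries(summ$n, summ$mean, summ$sd, nrep)
    Fv <- replicate_F(summ$n, sim)
    msw <- colSums((summ$n - 1) * sim$sd^2) / (N - g)
    post <- function(i, j) {
      md <- sim$mean[i, ] - sim$mean[j, ]
      se <- sqrt(msw * (1 / summ$n[i] + 1 / summ$n[j]))
      padj <- pmin(1, k * 2 * pt(-abs(md / se), N - g))
      md > 0 & padj < alpha
    }
    d1 <- post(g, 1); d2 <- post(g, 2)
    list(omnibus = mean(Fv > fcrit),
         last_vs_first = mean(d1), last_vs_second = mean(d2),
         joint = mean(d1 & d2))
  })
}

#' Normality-routed two-group comparison
#'
#' Applies the conventional screening: Shapiro-Wilk on each sample, and
#' the pooled t-test when both look normal at `alpha_normality`,
#' otherwise the Mann-Whitney U test.
#'
#' @param a,b numeric samples.
#' @param alpha_normality screening level (default 0.05).
#' @return list: `test` ("t" or "mann-whitney"), `p_value`, plus the
#'   fields of the routed test.
#' @export
compare_two_groups <- function(a, b, alpha_normality = 0.05) {
  normal <- function(x) {
    if (length(unique(x)) < 3) return(FALSE)
    shapiro.test(x)$p.value >= alpha_normality
  }
  if (normal(a) && normal(b)) {
    res <- two_sample_ttest(a, b)
    c(list(test = "t"), res)
  } else {
    res <- mann_whitney_u(a, b)
    c(list(test = "mann-whitney"), res)
  }
}
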