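#' Full group-statistics stage on a cohort table
#'
#' Runs, on a per-subject ALPS table (simulated or measured), the same
#' battery a clinical ALPS study reports: per-hemisphere one-way ANOVA
#' across the three groups with all Bonferroni post hoc pairs; paired
#' right-versus-left t-tests within each group; age ANOVA and sex
#' chi-square across groups; normality-routed EM-versus-CM comparisons
#' of the clinical scores; depression prevalence (PHQ-9 >= 10)
#' chi-square; and age- and sex-adjusted partial correlations between
#' headache intensity (VAS) and the ALPS indices over the migraine
#' patients.
#'
#' @param table cohort data.frame in the [simulate_cohort()] schema (or
#'   with measured ALPS values in the columns named by `left_col` /
#'   `right_col`).
#' @param alpha significance level.
#' @param left_col,right_col names of the per-subject ALPS columns.
#' @return nested list keyed by analysis name.
#' @export
analyze_cohort <- function(table, alpha = 0.05,
                           left_col = "alps_left_true",
                           right_col = "alps_right_true") {
  res <- list()
  groups <- c("HC", "EM", "CM")
  pairs <- list(c("CM", "HC"), c("CM", "EM"), c("EM", "HC"))
  for (side in c("left", "right")) {
    col <- if (side == "left") left_col else right_col
    summ <- summarize_groups(table[[col]], table$group)
    key <- paste0("anova_", side)
    res[[key]] <- unclass(anova_oneway_summary(summ))
    for (p in pairs)
      res[[paste0("posthoc_", side, "_", tolower(p[1]), "_",
                  tolower(p[2]))]] <- posthoc_bonferroni(summ, p, alpha)
  }
  for (g in groups) {
    sub <- table[table$group == g, ]
    if (nrow(sub) >= 2)
      res[[paste0("paired_right_left_", tolower(g))]] <-
        paired_ttest(sub[[right_col]], sub[[left_col]])
  }
  res$anova_age <- unclass(anova_oneway_summary(
    summarize_groups(table$age, table$group)))
  sex_tab <- table(table$sex, table$group)
  res$chisq_sex <- tryCatch(chi_square_rxc(sex_tab), error = function(e) NULL)

  em <- table[table$group == "EM", ]; cm <- table[table$group == "CM", ]
  for (v in c("vas", "attack_frequency", "midas", "hit6", "phq9",
              "gad7", "psqi")) {
    a <- em[[v]]; b <- cm[[v]]
    if (sum(!is.na(a)) >= 3 && sum(!is.na(b)) >= 3)
      res[[paste0("em_cm_", v)]] <-
        compare_two_groups(a[!is.na(a)], b[!is.na(b)])
  }
  dep <- rbind(EM = table(factor(em$phq9 >= 10, c(FALSE, TRUE))),
               CM = table(factor(cm$phq9 >= 10, c(FALSE, TRUE))))
  res$chisq_depression <- tryCatch(chi_square_rxc(dep),
                                   error = function(e) NULL)

  mig <- table[table$group %in% c("EM", "CM") & !is.na(table$vas), ]
  if (nrow(mig) > 5) {
    covars <- cbind(age = mig$age, sex = as.integer(mig$sex == "M"))
    res$cor_vas_left <- unclass(
      partial_correlation(mig$vas, mig[[left_col]], covars))
    res$cor_vas_right <- unclass(
      partial_correlation(mig$vas, mig[[right_col]], covars))
  }
  res$alpha <- alpha
  res
}

#' End-to-end imaging run on one phantom
#'
#' Simulate (or take) a DWI volume, fit the tensor field, place the
#' default ROI set and measure both ALPS indices.
#'
#' @param config an [phantom_config()].
#' @param scheme an [acquisition_scheme()].
#' @param rois optional [roi_set()]; defaults to ROIs centred in the
#'   phantom's fibre blocks.
#' @param strict escalate QC failures to errors.
#' @return list: `measurement` (the [measure_alps()] table), `truth`
#'   (named ground-truth indices), `field` (the fitted
#'   `alps_tensor_field`).
#' @export
run_phantom_pipeline <- function(config, scheme = default_scheme(),
                                 rois = NULL, strict = FALSE) {
  dwi <- simulate_phantom(config, scheme)
  field <- fit_tensor(dwi$signal, scheme)
  rois <- rois %||% default_roi_set(config)
  list(measurement = measure_alps(field, rois, strict = strict),
       truth = phantom_true_alps(config),
       field = field)
}
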