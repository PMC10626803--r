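#' Cohort specification for multi-subject ALPS simulation
#'
#' Describes a three-group study population (healthy controls, episodic
#' migraine, chronic migraine) with per-group sample sizes, target ALPS
#' means and between-subject SDs for each hemisphere, and per-group
#' clinical covariate distributions. The defaults reproduce the group
#' structure of a published migraine-chronification ALPS study:
#' right-hemisphere ALPS 1.63 +/- 0.18 (HC, n = 41), 1.64 +/- 0.17
#' (EM, n = 32) and 1.77 +/- 0.23 (CM, n = 24), with the printed
#' left-hemisphere summaries for the migraine groups.
#'
#' @param groups data.frame with columns `group`, `n`,
#'   `alps_left_mean`, `alps_left_sd`, `alps_right_mean`,
#'   `alps_right_sd`. Counts must be >= 2 and SDs > 0.
#' @param template an [phantom_config()] shared by all subjects; each
#'   subject's perivascular (x) eigenvalues are rescaled to realise the
#'   subject's drawn ALPS indices.
#' @param clinical named list (per group) of covariate generator
#'   definitions; see [default_cohort_spec()] for the format.
#' @param seed master RNG seed; every draw in the cohort flows from it.
#' @return An object of class `alps_cohort_spec`.
#' @export
cohort_spec <- function(groups, template = phantom_config(),
                        clinical = default_clinical_generators(),
                        seed = 1) {
  stopifnot(is.data.frame(groups),
            all(c("group", "n", "alps_left_mean", "alps_left_sd",
                  "alps_right_mean", "alps_right_sd") %in% names(groups)))
  if (any(groups$n < 2))
    stop("each group needs at least 2 subjects", call. = FALSE)
  if (any(groups$alps_left_sd <= 0) || any(groups$alps_right_sd <= 0))
    stop("between-subject ALPS SDs must be > 0", call. = FALSE)
  if (any(groups$alps_left_mean <= 0) || any(groups$alps_right_mean <= 0))
    stop("ALPS target means must be > 0", call. = FALSE)
  structure(list(groups = groups, template = template,
                 clinical = clinical, seed = as.integer(seed)),
            class = "alps_cohort_spec")
}

#' @rdname cohort_spec
#' @param n_hc,n_em,n_cm group sizes (defaults 41/32/24).
#' @param seed master seed.
#' @export
default_cohort_spec <- function(n_hc = 41, n_em = 32, n_cm = 24, seed = 1,
                                template = phantom_config()) {
  groups <- data.frame(
    group = c("HC", "EM", "CM"),
    n = c(n_hc, n_em, n_cm),
    # HC left summaries are not published; the HC right targets are reused
    alps_left_mean = c(1.63, 1.59, 1.65),
    alps_left_sd = c(0.18, 0.15, 0.16),
    alps_right_mean = c(1.63, 1.64, 1.77),
    alps_right_sd = c(0.18, 0.17, 0.23))
  cohort_spec(groups, template = template, seed = seed)
}

# Covariate generators per group. Normal entries come from published
# mean +/- SD; median/IQR entries are drawn as Normal(median, IQR/1.349)
# and clamped to the variable's plausible range (distribution shapes
# beyond the published medians/IQRs are a modelling choice).
default_clinical_generators <- function() {
  n_ <- function(mean, sd, min, max, digits = 1)
    list(kind = "normal", mean = mean, sd = sd, min = min, max = max,
         digits = digits)
  iqr_ <- function(median, q1, q3, min, max, digits = 0)
    list(kind = "normal", mean = median, sd = (q3 - q1) / 1.349,
         min = min, max = max, digits = digits)
  list(
    HC = list(age = n_(36.0, 10.9, 18, 70, 0), male_ratio = 16 / 41,
              vas = NULL, attack_frequency = NULL, midas = NULL,
              hit6 = NULL, phq9 = NULL, gad7 = NULL, psqi = NULL),
    EM = list(age = n_(34.8, 15.4, 18, 70, 0), male_ratio = 9 / 32,
              vas = iqr_(7, 5, 8, 0, 10),
              attack_frequency = iqr_(6.5, 4, 10, 1, 14),
              midas = iqr_(48, 18, 60, 0, 270),
              hit6 = n_(64.2, 6.8, 36, 78, 0),
              phq9 = iqr_(5, 1, 7, 0, 27),
              gad7 = iqr_(3, 1, 8.5, 0, 21),
              psqi = n_(8.5, 4.8, 0, 21, 0)),
    CM = list(age = n_(34.8, 16.8, 18, 70, 0), male_ratio = 9 / 24,
              vas = iqr_(7, 6, 8, 0, 10),
              attack_frequency = iqr_(19, 15, 30, 15, 31),
              midas = iqr_(95, 58, 179, 0, 270),
              hit6 = n_(68.0, 5.5, 36, 78, 0),
              phq9 = iqr_(12, 6, 16, 0, 27),
              gad7 = iqr_(9, 5, 13, 0, 21),
              psqi = n_(9.1, 4.7, 0, 21, 0)))
}

draw_clinical_var <- function(gen, n) {
  if (is.null(gen)) return(rep(NA_real_, n))
  x <- rnorm(n, gen$mean, gen$sd)
  x <- pmin(pmax(x, gen$min), gen$max)
  round(x, gen$digits)
}

# normal draw truncated below at `lower` (rejection sampling)
rtruncnorm_lower <- function(n, mean, sd, lower = 1) {
  out <- rnorm(n, mean, sd)
  for (iter in 1:1000) {
    bad <- out < lower
    if (!any(bad)) return(out)
    out[bad] <- rnorm(sum(bad), mean, sd)
  }
  stop("truncated-normal sampler failed to converge; target mean ",
       mean, " is too far below the truncation bound", call. = FALSE)
}

#' Simulate a multi-subject ALPS cohort
#'
#' Draws per-subject ground-truth left and right ALPS indices from the
#' group target distributions (normal, truncated below at 1.0, the
#' physiological floor of the index) together with per-group clinical
#' covariates, and records full provenance (master seed and a
#' per-subject sub-seed). Per-subject DWI phantoms realising the drawn
#' indices are constructed on demand by [subject_phantom_config()] /
#' [simulate_subject_dwi()], so statistics-only cohorts carry no imaging
#' cost.
#'
#' @param spec an [cohort_spec()].
#' @return An object of class `alps_cohort`: list with `table` (one row
#'   per subject: `subject_id`, `group`, `age`, `sex`, `vas`,
#'   `attack_frequency`, `midas`, `hit6`, `phq9`, `gad7`, `psqi`,
#'   `alps_left_true`, `alps_right_true`, `seed`) and `spec`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "alps_cohort_spec"))
  g <- spec$groups
  if (any(g$alps_left_mean <= 1) || any(g$alps_right_mean <= 1))
    stop("unreachable ALPS target: group means must exceed 1 ",
         "(the index is truncated below at 1 by construction)",
         call. = FALSE)
  with_seed(spec$seed, {
    rows <- list()
    for (gi in seq_len(nrow(g))) {
      grp <- g$group[gi]; n <- g$n[gi]
      gen <- spec$clinical[[grp]]
      if (is.null(gen)) stop("no clinical generators for group ", grp,
                             call. = FALSE)
      al <- rtruncnorm_lower(n, g$alps_left_mean[gi], g$alps_left_sd[gi])
      ar <- rtruncnorm_lower(n, g$alps_right_mean[gi], g$alps_right_sd[gi])
      sex <- ifelse(runif(n) < gen$male_ratio, "M", "F")
      tab <- data.frame(
        subject_id = sprintf("%s%02d", grp, seq_len(n)),
        group = grp,
        age = draw_clinical_var(gen$age, n),
        sex = sex,
        vas = draw_clinical_var(gen$vas, n),
        attack_frequency = draw_clinical_var(gen$attack_frequency, n),
        midas = draw_clinical_var(gen$midas, n),
        hit6 = draw_clinical_var(gen$hit6, n),
        phq9 = draw_clinical_var(gen$phq9, n),
        gad7 = draw_clinical_var(gen$gad7, n),
        psqi = draw_clinical_var(gen$psqi, n),
        alps_left_true = al,
        alps_right_true = ar,
        seed = sample.int(.Machine$integer.max, n))
      rows[[gi]] <- tab
    }
    structure(list(table = do.call(rbind, rows), spec = spec),
              class = "alps_cohort")
  })
}

#' @rdname simulate_cohort
#' @param cohort an `alps_cohort`.
#' @param subject subject id or row index.
#' @return `subject_phantom_config()` returns the subject's
#'   [phantom_config()]: the spec template with its perivascular (x)
#'   eigenvalues rescaled to the subject's drawn indices and the
#'   subject's sub-seed installed.
#' @export
subject_phantom_config <- function(cohort, subject) {
  i <- if (is.character(subject))
    match(subject, cohort$table$subject_id) else subject
  if (is.na(i) || i < 1 || i > nrow(cohort$table))
    stop("unknown subject: ", subject, call. = FALSE)
  cfg <- set_phantom_alps(cohort$spec$template,
                          alps_left = cohort$table$alps_left_true[i],
                          alps_right = cohort$table$alps_right_true[i])
  cfg$seed <- cohort$table$seed[i]
  cfg
}

#' @export
print.alps_cohort <- function(x, ...) {
  cat("<alps_cohort> ", nrow(x$table), " subjects (",
      paste(sprintf("%s: %d", x$spec$groups$group, x$spec$groups$n),
            collapse = ", "), "), master seed ", x$spec$seed, "\n", sep = "")
  invisible(x)
}

#' @rdname simulate_cohort
#' @param scheme acquisition scheme for the subject's DWI volume.
#' @return `simulate_subject_dwi()` returns the subject's `alps_dwi`.
#' @export
simulate_subject_dwi <- function(cohort, subject, scheme = default_scheme()) {
  simulate_phantom(subject_phantom_config(cohort, subject), scheme)
}

#' Run the imaging pipeline over simulated subjects
#'
#' For each requested subject: simulate the DWI volume, fit the tensor
#' field, and measure left/right ALPS with the ROI set centred on the
#' template's fibre blocks.
#'
#' @inheritParams simulate_subject_dwi
#' @param subjects subject ids or indices (default: all).
#' @return data.frame with one row per subject and hemisphere
#'   (`subject_id`, `group`, plus the [measure_alps()] columns).
#' @export
recover_cohort_alps <- function(cohort, subjects = NULL,
                                scheme = default_scheme()) {
  ids <- cohort$table$subject_id
  if (!is.null(subjects))
    ids <- if (is.character(subjects)) subjects else ids[subjects]
  rois <- default_roi_set(cohort$spec$template)
  out <- lapply(ids, function(id) {
    dwi <- simulate_subject_dwi(cohort, id, scheme)
    meas <- measure_alps(fit_tensor(dwi$signal, dwi$scheme), rois)
    cbind(subject_id = id,
          group = cohort$table$group[match(id, cohort$table$subject_id)],
          meas)
  })
  do.call(rbind, out)
}
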