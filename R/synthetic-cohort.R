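# Default study conditions for the longitudinal cohort generator. Group
# sizes, visit-1 means/SDs, one-year declines, demographics and clinical
# scales are set to published magnitudes for multisite PD / PSP / MSA / HC
# pegboard cohorts; any quantity without a published value (site mix, change
# SD of the motor scale, MOCA change spread) uses a documented assumption.
default_ppt_table <- function() {
  g <- DIAGNOSIS_LABELS
  tasks <- TASK_LABELS
  m <- function(...) matrix(c(...), nrow = 4, byrow = TRUE,
                            dimnames = list(tasks, g))
  list(
    visit1_means = m(10.26, 6.590, 6.478, 12.77,
                     10.10, 6.179, 6.174, 12.83,
                     15.84, 8.718, 9.870, 20.70,
                     18.54, 10.69, 11.48, 26.77),
    visit1_sds = m(2.504, 2.953, 2.761, 2.072,
                   2.507, 2.964, 3.128, 1.816,
                   4.847, 4.599, 4.770, 3.555,
                   5.377, 5.172, 5.526, 6.381),
    decline_means = m(-0.579, -1.974, -1.174, 0.358,
                      -0.494, -1.769, -1.130, -0.057,
                      -1.268, -2.795, -2.913, 0.887,
                      -0.305, -3.051, -2.783, -0.623),
    decline_sds = m(1.922, 2.611, 2.229, 2.497,
                    1.901, 2.757, 1.984, 1.748,
                    3.527, 4.231, 3.088, 3.625,
                    4.057, 4.883, 4.991, 4.919))
}

default_clinical_table <- function() {
  g <- DIAGNOSIS_LABELS
  v <- function(...) setNames(c(...), g)
  updrs1_m <- v(29.92, 42.92, 49.04, 3.151)
  updrs1_s <- v(12.50, 15.77, 18.60, 2.663)
  updrs2_m <- v(33.03, 54.13, 57.39, 4.094)
  updrs2_s <- v(12.29, 14.05, 20.61, 3.353)
  retest <- 0.7  # assumed visit-to-visit correlation of the motor scale
  list(
    age_means = v(64.69, 69.62, 65.61, 65.17),
    age_sds = v(8.129, 5.861, 8.631, 8.706),
    male_prop = v(107 / 164, 17 / 39, 17 / 23, 20 / 53),
    duration_means = v(2.692, 2.932, 3.101, NA),
    duration_sds = v(2.349, 2.730, 2.667, NA),
    moca_means = v(26.35, 22.64, 22.52, 27.11),
    moca_sds = v(2.449, 4.196, 5.080, 1.888),
    moca_change_means = v(26.55, 21.39, 20.96, 27.55) - v(26.35, 22.64, 22.52, 27.11),
    moca_change_sds = v(2, 2, 2, 2),
    updrs_means = updrs1_m,
    updrs_sds = updrs1_s,
    updrs_change_means = updrs2_m - updrs1_m,
    updrs_change_sds = sqrt(updrs1_s^2 + updrs2_s^2 -
                              2 * retest * updrs1_s * updrs2_s))
}

#' Design of a synthetic longitudinal pegboard cohort
#'
#' Describes group sizes, per-task visit-1 score distributions, planted
#' one-year declines, clinical covariates, and the target rank correlation
#' between one-year motor-scale worsening and pegboard decline. Defaults are
#' the package's reference multisite study conditions (PD n=164, PSP n=39,
#' MSA n=23, HC n=53, with parkinsonian declines on the dominant-hand and
#' both-hands tasks and a flat healthy-control trajectory).
#'
#' @param group_sizes named counts per diagnosis (PD, PSP, MSA, HC), each
#'   >= 2.
#' @param visit1_means,visit1_sds 4x4 matrices (task x group) of visit-1
#'   pegboard scores (pegs; assemblies for the assembly task).
#' @param decline_means,decline_sds 4x4 matrices (task x group) of one-year
#'   change, pegs/year.
#' @param clinical list of covariate / clinical-scale parameters (see
#'   `pegkin:::default_clinical_table()` for the expected fields).
#' @param change_correlation target Spearman correlation between the
#'   one-year motor-scale change and the pegboard change on
#'   `correlation_task`; `|rho| <= 1`.
#' @param correlation_task task whose change score carries the planted
#'   correlation.
#' @param site_levels testing sites, sampled uniformly.
#' @param round_scores round pegboard scores to integers (real pegboard
#'   scores are counts); planting of correlations is then approximate.
#' @return an object of class `cohort_design`.
#' @export
cohort_design <- function(group_sizes = c(PD = 164, PSP = 39, MSA = 23, HC = 53),
                          visit1_means = NULL, visit1_sds = NULL,
                          decline_means = NULL, decline_sds = NULL,
                          clinical = default_clinical_table(),
                          change_correlation = -0.3,
                          correlation_task = "dominant",
                          site_levels = c("UF", "NU"),
                          round_scores = FALSE) {
  ppt <- default_ppt_table()
  visit1_means <- visit1_means %||% ppt$visit1_means
  visit1_sds <- visit1_sds %||% ppt$visit1_sds
  decline_means <- decline_means %||% ppt$decline_means
  decline_sds <- decline_sds %||% ppt$decline_sds
  if (is.null(names(group_sizes)) ||
      !all(names(group_sizes) %in% DIAGNOSIS_LABELS)) {
    stopf("`group_sizes` must be named with diagnoses among %s",
          paste(DIAGNOSIS_LABELS, collapse = ", "))
  }
  if (any(group_sizes < 2)) stopf("all group sizes must be >= 2")
  for (m in list(visit1_sds, decline_sds)) {
    if (any(m[, names(group_sizes)] <= 0)) stopf("all SDs must be > 0")
  }
  if (abs(change_correlation) > 1) stopf("|change_correlation| must be <= 1")
  correlation_task <- match.arg(correlation_task, TASK_LABELS)
  structure(
    list(group_sizes = group_sizes, visit1_means = visit1_means,
         visit1_sds = visit1_sds, decline_means = decline_means,
         decline_sds = decline_sds, clinical = clinical,
         change_correlation = change_correlation,
         correlation_task = correlation_task, site_levels = site_levels,
         round_scores = isTRUE(round_scores)),
    class = "cohort_design")
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws one subject-level cohort from a [cohort_design()]. Visit-1 scores
#' are Gaussian per group; visit-2 = visit-1 + a Gaussian decline draw. The
#' one-year motor-scale change is coupled to the pegboard change on the
#' design's `correlation_task` through a Gaussian copula, so the target
#' Spearman correlation holds regardless of the marginal scales
#' (`rho_pearson = 2 sin(pi rho_s / 6)`). Covariates (age, sex, site,
#' disease duration, cognition) are drawn independently. Pegboard scores are
#' clamped at 0.
#'
#' @param design a [cohort_design()].
#' @param seed integer seed or `NULL`.
#' @return a data.frame with one row per subject: `subject_id`, `diagnosis`,
#'   `site`, `age`, `sex`, `disease_duration` (NA for HC), `moca_v1/2`,
#'   `updrs_v1/2`, and `ppt_<task>_v1/2` for the four tasks.
#' @export
generate_cohort <- function(design = cohort_design(), seed = NULL) {
  stopifnot(inherits(design, "cohort_design"))
  with_seed(seed, {
    cl <- design$clinical
    rho_p <- 2 * sin(pi * design$change_correlation / 6)
    rows <- list()
    sid <- 0L
    for (g in names(design$group_sizes)) {
      n <- design$group_sizes[[g]]
      age <- rnorm(n, cl$age_means[[g]], cl$age_sds[[g]])
      sex <- ifelse(rbinom(n, 1, cl$male_prop[[g]]) == 1L, "M", "F")
      site <- sample(design$site_levels, n, replace = TRUE)
      dur <- if (g == "HC") rep(NA_real_, n) else
        pmax(rnorm(n, cl$duration_means[[g]], cl$duration_sds[[g]]), 0)
      moca1 <- clamp(rnorm(n, cl$moca_means[[g]], cl$moca_sds[[g]]), 0, 30)
      moca2 <- clamp(moca1 + rnorm(n, cl$moca_change_means[[g]],
                                   cl$moca_change_sds[[g]]), 0, 30)
      updrs1 <- pmax(rnorm(n, cl$updrs_means[[g]], cl$updrs_sds[[g]]), 0)
      z <- matrix(rnorm(n * 4L), n, 4L, dimnames = list(NULL, TASK_LABELS))
      df <- data.frame(
        subject_id = sprintf("S%04d", sid + seq_len(n)),
        diagnosis = g, site = site, age = age, sex = sex,
        disease_duration = dur, moca_v1 = moca1, moca_v2 = moca2,
        stringsAsFactors = FALSE)
      sid <- sid + n
      for (task in TASK_LABELS) {
        v1 <- rnorm(n, design$visit1_means[task, g], design$visit1_sds[task, g])
        chg <- design$decline_means[task, g] +
          design$decline_sds[task, g] * z[, task]
        v1 <- pmax(v1, 0)
        v2 <- pmax(v1 + chg, 0)
        if (design$round_scores) { v1 <- round(v1); v2 <- round(v2) }
        df[[paste0("ppt_", task, "_v1")]] <- v1
        df[[paste0("ppt_", task, "_v2")]] <- v2
      }
      u <- rho_p * z[, design$correlation_task] +
        sqrt(1 - rho_p^2) * rnorm(n)
      updrs_chg <- cl$updrs_change_means[[g]] + cl$updrs_change_sds[[g]] * u
      df$updrs_v1 <- updrs1
      df$updrs_v2 <- pmax(updrs1 + updrs_chg, 0)
      rows[[g]] <- df
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out$diagnosis <- factor(out$diagnosis, levels = DIAGNOSIS_LABELS)
    out$diagnosis <- droplevels(out$diagnosis)
    if (design$round_scores) {
      warning("scores rounded to integers: planted change correlation is approximate",
              call. = FALSE)
    }
    attr(out, "seed") <- seed
    out
  })
}
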