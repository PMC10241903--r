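imaging_regions <- function() {
  c("M1", "SMA", "preSMA", "SFG", "MFG", "IPL", "SMG", "caudate", "putamen",
    "STN", "pSN", "PPN", "dentate", "SMATT_M1", "SMATT_SMA", "SMATT_preSMA",
    "SCP", "nigrostriatal")
}

#' Names of the default baseline candidate predictors
#'
#' The 40 candidates entered into the backward-elimination model: age, sex,
#' disease duration, cognition (MOCA), and free-water (FW) plus free-water
#' corrected fractional anisotropy (FAt) for 13 gray-matter regions and 5
#' white-matter tracts of the motor network.
#'
#' @return a character vector of 40 names.
#' @export
predictor_names <- function() {
  reg <- imaging_regions()
  c("age", "sex", "disease_duration", "moca",
    paste0("FW_", reg), paste0("FAt_", reg))
}

#' Design of a synthetic baseline predictor matrix
#'
#' Describes a planted sparse linear model relating standardized baseline
#' candidates to a follow-up pegboard outcome. The default support mirrors
#' the basal-ganglia-dominated pattern seen in PD: FW in putamen, posterior
#' substantia nigra (pSN) and pedunculopontine nucleus (PPN), FAt in pSN and
#' subthalamic nucleus (STN), plus sex and MOCA, with n = 151 subjects so a
#' seven-term final model has 143 residual degrees of freedom.
#'
#' @param n_subjects number of subjects.
#' @param n_predictors number of candidate columns (default 40).
#' @param true_support named standardized effects of the planted predictors
#'   (subset of the candidate names); remaining candidates have zero effect.
#' @param noise_sd residual SD on the outcome scale (> 0). The default 1.6,
#'   with the default support, gives a planted R^2 near 0.24.
#' @param predictor_correlation common pairwise correlation of the candidate
#'   columns; must keep the equicorrelation matrix positive definite
#'   (`-1/(p-1) < rho < 1`).
#' @param names candidate column names (length `n_predictors`).
#' @return an object of class `predictor_design`.
#' @export
predictor_design <- function(n_subjects = 151, n_predictors = 40,
                             true_support = c(
                               FW_putamen = -0.258, FW_pSN = -0.325,
                               FW_PPN = 0.531, FAt_pSN = -0.358,
                               FAt_STN = 0.406, sex = -0.199, moca = 0.172),
                             noise_sd = 1.6, predictor_correlation = 0.1,
                             names = NULL) {
  if (is.null(names)) {
    names <- if (n_predictors == 40L) predictor_names() else
      sprintf("X%02d", seq_len(n_predictors))
  }
  stopifnot(length(names) == n_predictors, !anyDuplicated(names))
  if (length(true_support) > n_predictors ||
      !all(names(true_support) %in% names)) {
    stopf("`true_support` must name a subset of the candidate columns")
  }
  if (noise_sd <= 0) stopf("`noise_sd` must be > 0")
  rho <- predictor_correlation
  if (rho >= 1 || rho <= -1 / (n_predictors - 1)) {
    stopf("requested correlation structure is singular (rho = %g)", rho)
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         n_predictors = as.integer(n_predictors),
         true_support = true_support, noise_sd = noise_sd,
         predictor_correlation = rho, names = names),
    class = "predictor_design")
}

#' Generate a synthetic predictor matrix and outcome
#'
#' Draws an equicorrelated Gaussian design, standardizes each column to unit
#' sample variance, and forms `outcome = X beta + eps` with the planted
#' sparse support. Reproducible under `seed`.
#'
#' @param design a [predictor_design()].
#' @param seed integer seed or `NULL`.
#' @return a list with `x` (n x p standardized matrix with named columns),
#'   `y` (outcome vector), `beta` (full-length planted coefficient vector),
#'   and `design`.
#' @export
generate_predictors <- function(design = predictor_design(), seed = NULL) {
  stopifnot(inherits(design, "predictor_design"))
  with_seed(seed, {
    n <- design$n_subjects
    p <- design$n_predictors
    rho <- design$predictor_correlation
    z <- matrix(rnorm(n * p), n, p)
    if (rho != 0) {
      sigma <- matrix(rho, p, p)
      diag(sigma) <- 1
      z <- z %*% chol(sigma)
    }
    x <- scale(z)
    attr(x, "scaled:center") <- NULL
    attr(x, "scaled:scale") <- NULL
    colnames(x) <- design$names
    beta <- setNames(numeric(p), design$names)
    beta[names(design$true_support)] <- design$true_support
    y <- as.numeric(x %*% beta) + rnorm(n, 0, design$noise_sd)
    list(x = x, y = y, beta = beta, design = design)
  })
}
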