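# Validation utilities on synthetic cohorts: recovery of the generative
# distant-coupling and interaction coefficients, and null family-wise
# error-rate calibration of the map-level correction.

#' Recover the distant Abeta-to-glucose coupling coefficient
#'
#' For each default-mode region r, regresses the region's FDG mean on the
#' coupling-weighted distant Abeta signal (W a)_r, the local Abeta mean, and
#' covariates, across subjects; the negated average coefficient on the
#' distant term estimates the generative coupling strength gamma. Region
#' means are GTM partial-volume corrected and renormalised to the reference
#' regions, so that the broadcast-and-smooth observation process does not
#' attenuate the estimate.
#'
#' @param cohort A preprocessed synthetic [cohort_dataset()].
#' @param W Region-coupling matrix (default: the cohort's provenance
#'   record).
#' @param groups Optional group filter.
#' @param covariates Scalar adjustment set.
#' @return List with `gamma_hat`, per-region estimates, and their mean
#'   standard error.
#' @export
estimate_distant_effect <- function(cohort, W = NULL, groups = NULL,
                                    covariates = c("age", "sex", "education",
                                                   "apoe4", "ptau")) {
  prov <- attr(cohort, "provenance")
  if (is.null(W)) W <- prov$config$W
  if (is.null(W)) stop("no coupling matrix available")
  subjects <- filter_subjects(cohort, groups)
  fw <- prov$config$smoothing_fwhm_mm %||% 8
  A <- roi_mean_matrix(cohort, "abeta", pvc = TRUE, fwhm_mm = fw,
                       reference = "cerebellum")[subjects$id, , drop = FALSE]
  Fm <- roi_mean_matrix(cohort, "fdg", pvc = TRUE, fwhm_mm = fw,
                        reference = "pons")[subjects$id, , drop = FALSE]
  Z <- connectivity_covariates(cohort, subjects, covariates)
  p <- cohort$parcellation
  dm <- names(p$network_of)[p$network_of == "default_mode"]
  est <- setNames(numeric(length(dm)), dm)
  se <- setNames(numeric(length(dm)), dm)
  for (r in dm) {
    distant <- as.vector(A %*% W[r, colnames(A)])
    X <- cbind(1, distant, A[, r], Z)
    fit <- lm(Fm[, r] ~ X - 1)
    est[r] <- coef(fit)[2]
    se[r] <- sqrt(diag(vcov(fit)))[2]
  }
  list(gamma_hat = -mean(est), per_roi = -est, mean_se = mean(se))
}

#' Recover the local interaction effect on the cognitive slope
#'
#' Reconstructs the generative interaction driver -- the default-mode mean
#' of local Abeta times local hypometabolism (FDG centred across subjects,
#' negated) -- from GTM-corrected region means, and regresses the estimated
#' cognitive slope on it plus the main-effect summaries and covariates. The
#' coefficient on the driver estimates the generative beta3.
#'
#' @param cohort A preprocessed synthetic [cohort_dataset()].
#' @param groups Group filter (the interaction is group-specific).
#' @param covariates Scalar adjustment set.
#' @return List with `beta3_hat` and its standard error.
#' @export
estimate_interaction_effect <- function(cohort, groups = "MCI_pos",
                                        covariates = c("age", "sex",
                                                       "education", "apoe4",
                                                       "ptau",
                                                       "followup_years")) {
  prov <- attr(cohort, "provenance")
  fw <- prov$config$smoothing_fwhm_mm %||% 8
  subjects <- filter_subjects(cohort, groups)
  if (anyNA(subjects$slope)) stop("cognitive slopes missing")
  A <- roi_mean_matrix(cohort, "abeta", pvc = TRUE, fwhm_mm = fw,
                       reference = "cerebellum")[subjects$id, , drop = FALSE]
  Fm <- roi_mean_matrix(cohort, "fdg", pvc = TRUE, fwhm_mm = fw,
                        reference = "pons")[subjects$id, , drop = FALSE]
  p <- cohort$parcellation
  dm <- prov$config$interaction_rois %||%
    names(p$network_of)[p$network_of == "default_mode"]
  Gc <- scale(Fm[, dm], center = TRUE, scale = FALSE)  # centre across subjects
  Ac <- scale(A[, dm], center = TRUE, scale = FALSE)
  driver <- rowMeans(Ac * (-Gc))
  Z <- connectivity_covariates(cohort, subjects, covariates)
  fit <- lm(subjects$slope ~ driver + Z)
  list(beta3_hat = unname(coef(fit)["driver"]),
       se = sqrt(diag(vcov(fit)))[["driver"]])
}

#' Null calibration of the family-wise error rate
#'
#' Generates independent null cohorts (all generative effects zero), runs
#' the standard Abeta-metabolism voxel model with the requested map-level
#' correction on the focal term, and reports the fraction of cohorts in
#' which any voxel is declared significant -- the empirical family-wise
#' error rate, which a valid correction holds at or below `alpha`.
#'
#' @param config A [synth_config()]; its seed is re-derived per cohort.
#' @param n_cohorts Number of independent null cohorts (>= 1).
#' @param term Focal term of the correction.
#' @param method,alpha,n_perm,perm_scheme Correction settings (see
#'   [fwer_correct()]).
#' @param seed Master seed for the cohort and permutation streams.
#' @return List with `rate`, `n_rejections`, `n_cohorts`, and the
#'   per-cohort rejection indicator.
#' @export
calibrate_fwer <- function(config, n_cohorts = 200, term = "global_abeta",
                           method = "permutation_maxT", alpha = 0.05,
                           n_perm = 500, seed = 1L,
                           perm_scheme = "outcome") {
  set.seed(seed)
  cohort_seeds <- sample.int(.Machine$integer.max - 1L, n_cohorts)
  perm_seeds <- sample.int(.Machine$integer.max - 1L, n_cohorts)
  reject <- logical(n_cohorts)
  for (i in seq_len(n_cohorts)) {
    config$seed <- cohort_seeds[i]
    cohort <- preprocess_cohort(null_cohort(config))
    map <- fit_voxelwise(cohort, abeta_metabolism_spec())
    map <- fwer_correct(map, term, method = method, alpha = alpha,
                        n_perm = n_perm, seed = perm_seeds[i],
                        perm_scheme = perm_scheme)
    reject[i] <- any(map$suprathreshold, na.rm = TRUE)
  }
  list(rate = mean(reject), n_rejections = sum(reject),
       n_cohorts = n_cohorts, reject = reject)
}
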