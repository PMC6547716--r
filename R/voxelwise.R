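# Per-voxel GLM engine: a regression with voxel-level image predictors,
# scalar global predictors and covariates fitted independently at every
# in-mask voxel, with family-wise error control by Freedman-Lane max-|t|
# permutation, interaction models on cognitive slopes, nested-model
# comparison, and bootstrap stability analysis.

HUMAN_COVARIATES <- c("age", "sex", "education", "apoe4", "ptau", "gm_density")

#' Declarative per-voxel regression specification
#'
#' @param outcome `"voxel_fdg"` (the FDG value at the current voxel) or
#'   `"cognitive_slope"` (the per-subject slope, constant across voxels).
#' @param voxel_terms Modality tags whose value at the current voxel enters
#'   as a predictor.
#' @param global_terms Scalar per-subject predictors: columns of the subject
#'   table, `"global_abeta"`, or `roi:<region>` for a region's Abeta mean.
#' @param interaction_pairs List of length-2 character vectors naming
#'   declared voxel terms whose product enters the model.
#' @param covariates Adjustment variables; subject-table columns plus
#'   optionally `"gm_density"` (the voxel's gray-matter density) and
#'   `"global_abeta"` / `"followup_years"`.
#' @param group_filter Optional group tags to restrict the fitted subjects.
#' @return Object of class `voxel_model_spec`.
#' @export
voxel_model_spec <- function(outcome = c("voxel_fdg", "cognitive_slope"),
                             voxel_terms = character(),
                             global_terms = character(),
                             interaction_pairs = list(),
                             covariates = character(),
                             group_filter = NULL) {
  outcome <- match.arg(outcome)
  all_terms <- c(voxel_terms, global_terms, covariates)
  if (anyDuplicated(all_terms)) stop("duplicate model terms")
  for (pr in interaction_pairs) {
    if (length(pr) != 2L || !all(pr %in% voxel_terms))
      stop("interaction pairs must reference declared voxel terms")
  }
  structure(list(outcome = outcome, voxel_terms = voxel_terms,
                 global_terms = global_terms,
                 interaction_pairs = interaction_pairs,
                 covariates = covariates, group_filter = group_filter),
            class = "voxel_model_spec")
}

# Resolve a scalar term name to a per-subject numeric vector.
scalar_column <- function(cohort, subjects, name) {
  if (name == "global_abeta") {
    if (is.null(cohort$global_abeta))
      stop("global_abeta not computed; run preprocess_cohort() first")
    return(unname(cohort$global_abeta[subjects$id]))
  }
  if (startsWith(name, "roi:")) {
    region <- sub("^roi:", "", name)
    m <- roi_mean_matrix(cohort, "abeta")[subjects$id, region]
    return(unname(m))
  }
  if (!name %in% names(subjects)) stop("unknown scalar term: ", name)
  as.numeric(subjects[[name]])
}

# Build the per-voxel design pieces for a spec: shared scalar matrix C,
# named list of voxel matrices, interaction index pairs, outcome.
build_design <- function(cohort, spec) {
  subjects <- cohort$subjects
  if (!is.null(spec$group_filter))
    subjects <- subjects[subjects$group %in% spec$group_filter, , drop = FALSE]
  n <- nrow(subjects)
  if (n < 3L) stop("too few subjects after group filtering")
  mask_idx <- which(cohort$mask$data != 0)

  is_voxel_cov <- spec$covariates %in% MODALITIES
  scalar_names <- c(spec$global_terms, spec$covariates[!is_voxel_cov])
  C <- cbind(`(Intercept)` = rep(1, n))
  if (length(scalar_names)) {
    cols <- vapply(scalar_names, function(nm)
      scalar_column(cohort, subjects, nm), numeric(n))
    C <- cbind(C, cols)
    colnames(C) <- c("(Intercept)", scalar_names)
  }
  qrC <- qr(C)
  if (qrC$rank < ncol(C)) {
    drop <- colnames(C)[qrC$pivot[(qrC$rank + 1):ncol(C)]]
    stop("rank-deficient cohort-level design; offending column(s): ",
         paste(drop, collapse = ", "))
  }

  sub_cohort <- cohort
  sub_cohort$subjects <- subjects
  vox_names <- c(spec$voxel_terms, spec$covariates[is_voxel_cov])
  vox <- lapply(vox_names, function(m)
    voxel_matrix(sub_cohort, m, mask_idx))
  names(vox) <- vox_names

  ni <- length(spec$interaction_pairs)
  inter <- matrix(0L, 2, ni)
  inter_names <- character(ni)
  for (k in seq_len(ni)) {
    pr <- spec$interaction_pairs[[k]]
    inter[, k] <- match(pr, vox_names)
    inter_names[k] <- paste(pr, collapse = ":")
  }

  if (spec$outcome == "voxel_fdg") {
    Y <- voxel_matrix(sub_cohort, "fdg", mask_idx)
  } else {
    if (is.null(subjects$slope) || anyNA(subjects$slope))
      stop("cognitive slopes missing; run preprocess_cohort() first")
    Y <- matrix(subjects$slope, ncol = 1)
  }
  term_names <- c(colnames(C), spec$voxel_terms,
                  spec$covariates[is_voxel_cov], inter_names)
  list(C = C, vox = vox, inter = inter, Y = Y, term_names = term_names,
       mask_idx = mask_idx, n = n, ids = subjects$id, spec = spec,
       grid = dim(cohort$mask$data))
}

# Assemble the n x p design matrix at one voxel.
design_at_voxel <- function(d, v) {
  X <- d$C
  for (m in names(d$vox)) X <- cbind(X, d$vox[[m]][, v])
  ni <- ncol(d$inter)
  for (k in seq_len(ni)) {
    X <- cbind(X, d$vox[[d$inter[1, k]]][, v] * d$vox[[d$inter[2, k]]][, v])
  }
  colnames(X) <- d$term_names
  X
}

#' Fit a regression at every in-mask voxel
#'
#' Ordinary least squares of the outcome on intercept, voxel terms, global
#' terms, interactions and covariates, independently at each in-mask voxel.
#' Voxels with a rank-deficient design or zero outcome variance are marked
#' not-evaluated (NA in all maps) and counted.
#'
#' @param cohort A preprocessed [cohort_dataset()].
#' @param spec A [voxel_model_spec()].
#' @return A `stat_map` object: per-term `beta`, `t`, `p` 3-D arrays (NA
#'   outside evaluated voxels), residual `df`, the `evaluated` mask, and the
#'   design context used by [fwer_correct()].
#' @export
fit_voxelwise <- function(cohort, spec) {
  d <- build_design(cohort, spec)
  n <- d$n
  V <- length(d$mask_idx)
  p <- length(d$term_names)
  if (n <= p + 2L) stop("need n_subjects > n_terms + 2 (n = ", n,
                        ", terms = ", p, ")")
  df <- n - p
  beta <- matrix(NA_real_, p, V)
  tval <- matrix(NA_real_, p, V)
  evaluated <- logical(V)
  single_y <- ncol(d$Y) == 1L
  for (v in seq_len(V)) {
    X <- design_at_voxel(d, v)
    y <- if (single_y) d$Y[, 1] else d$Y[, v]
    if (sd(y) == 0) next
    fit <- .lm.fit(X, y)
    if (fit$rank < p) next
    evaluated[v] <- TRUE
    cf <- fit$coefficients
    rss <- sum(fit$residuals^2)
    XtXinv <- chol2inv(chol(crossprod(X)))
    se <- sqrt(pmax(diag(XtXinv), 0) * rss / df)
    beta[, v] <- cf
    tval[, v] <- ifelse(se > 0, cf / se, ifelse(cf == 0, 0, Inf))
  }
  pval <- 2 * pt(-abs(tval), df)
  to_map <- function(M) {
    lapply(seq_len(p), function(j) {
      arr <- array(NA_real_, d$grid)
      arr[d$mask_idx] <- M[j, ]
      arr
    })
  }
  bm <- to_map(beta); tm <- to_map(tval); pm <- to_map(pval)
  names(bm) <- names(tm) <- names(pm) <- d$term_names
  structure(list(terms = d$term_names, beta = bm, t = tm, p = pm, df = df,
                 evaluated = evaluated, n_not_evaluated = sum(!evaluated),
                 mask_idx = d$mask_idx, grid = d$grid,
                 suprathreshold = NULL, correction = NULL, design = d),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> %d terms, %d voxels evaluated (%d not), df = %d\n",
              length(x$terms), sum(x$evaluated), x$n_not_evaluated, x$df))
  if (!is.null(x$correction))
    cat(sprintf("  corrected: %s, term '%s', alpha = %g, %d suprathreshold\n",
                x$correction$method, x$correction$term, x$correction$alpha,
                sum(x$suprathreshold, na.rm = TRUE)))
  invisible(x)
}

#' Family-wise error correction of a statistical map
#'
#' Default method: Freedman-Lane max-|t| permutation. The focal term's
#' column and the outcome are residualised on the nuisance columns per
#' voxel; permuting the residualised outcome and refitting yields the
#' permutation distribution of the map-wide maximum |t|, from which
#' corrected per-voxel p-values follow. Bonferroni over evaluated voxels is
#' available as a fast alternative.
#'
#' @param map A `stat_map` from [fit_voxelwise()].
#' @param term Focal term name.
#' @param method `"permutation_maxT"` or `"bonferroni"`.
#' @param alpha Family-wise error level.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Seed for the permutation draws.
#' @param perm_scheme What each permutation shuffles before the full model
#'   is refit: `"outcome"` (the raw outcome rows -- exact when the outcome
#'   is independent of every predictor, the situation the null-calibration
#'   study targets, and near-exact for moderate nuisance effects),
#'   `"freedman_lane"` (the nuisance-residualised outcome, the classic
#'   scheme for strong nuisance effects), or `"huh_jhun"` (its coordinates
#'   in an orthonormal basis of the nuisance null space, exchangeable
#'   under Gaussian errors).
#' @return The map with `suprathreshold` (3-D logical array), corrected
#'   p-values (`p_fwer`), and correction metadata filled in.
#' @export
fwer_correct <- function(map, term,
                         method = c("permutation_maxT", "bonferroni"),
                         alpha = 0.05, n_perm = 1000, seed = 1L,
                         perm_scheme = c("outcome", "freedman_lane",
                                         "huh_jhun")) {
  method <- match.arg(method)
  perm_scheme <- match.arg(perm_scheme)
  if (!term %in% map$terms) stop("unknown term: ", term)
  if (!any(map$evaluated)) stop("map has no evaluated voxels")
  V <- sum(map$evaluated)
  t_term <- map$t[[term]][map$mask_idx]
  supra <- rep(NA, length(map$mask_idx))
  p_fwer <- rep(NA_real_, length(map$mask_idx))
  if (method == "bonferroni") {
    pv <- map$p[[term]][map$mask_idx]
    p_fwer <- pmin(pv * V, 1)
    supra <- p_fwer <= alpha
  } else {
    if (n_perm < 100) stop("n_perm < 100 gives an unstable null tail")
    d <- map$design
    term_idx <- match(term, map$terms)
    scheme <- match(perm_scheme, c("outcome", "huh_jhun",
                                   "freedman_lane")) - 1L
    m <- if (scheme == 1L) d$n - (length(map$terms) - 1L) else d$n
    set.seed(seed)
    perms <- vapply(seq_len(n_perm), function(i) sample.int(m),
                    integer(m))
    ev <- map$evaluated
    vox_sub <- lapply(d$vox, function(M) M[, ev, drop = FALSE])
    Y_sub <- if (ncol(d$Y) == 1L) d$Y else d$Y[, ev, drop = FALSE]
    res <- fl_max_t_cpp(Y_sub, d$C, vox_sub, d$inter, term_idx, perms,
                        scheme)
    pf <- vapply(abs(res$t_obs), function(tv)
      if (is.na(tv)) NA_real_ else (1 + sum(res$max_t >= tv)) / (n_perm + 1),
      numeric(1))
    p_fwer[ev] <- pf
    supra[ev] <- pf <= alpha
    supra[!ev] <- NA
  }
  arr_s <- array(NA, map$grid); arr_s[map$mask_idx] <- supra
  arr_p <- array(NA_real_, map$grid); arr_p[map$mask_idx] <- p_fwer
  map$suprathreshold <- arr_s
  map$p_fwer <- arr_p
  map$correction <- list(method = method, term = term, alpha = alpha,
                         n_perm = if (method == "bonferroni") NA_integer_
                                  else n_perm,
                         seed = if (method == "bonferroni") NA_integer_
                                else seed,
                         perm_scheme = if (method == "bonferroni")
                           NA_character_ else perm_scheme,
                         m_tests = V)
  map
}

#' The standard Abeta-metabolism voxel model
#'
#' Outcome: voxel FDG; predictors: voxel Abeta and the global Abeta
#' composite; covariates: age, sex, education, APOE e4, p-tau, and voxel
#' gray-matter density.
#'
#' @param groups Optional group filter.
#' @param covariates Covariate set (defaults to the human set).
#' @return A [voxel_model_spec()].
#' @export
abeta_metabolism_spec <- function(groups = NULL,
                                  covariates = HUMAN_COVARIATES) {
  voxel_model_spec(outcome = "voxel_fdg", voxel_terms = "abeta",
                   global_terms = "global_abeta", covariates = covariates,
                   group_filter = groups)
}

#' Voxel-wise Abeta-by-metabolism interaction model of cognitive decline
#'
#' Per-subject cognitive slope regressed on the voxel's Abeta value, the
#' voxel's FDG value, their product, and covariates (global Abeta, age,
#' sex, education, APOE e4, p-tau, voxel gray-matter density, and follow-up
#' duration by default).
#'
#' @param cohort A preprocessed [cohort_dataset()] with slopes.
#' @param groups Group filter (e.g. `"MCI_pos"`).
#' @param abeta_modality,fdg_modality Modality tags for the two voxel terms.
#' @param covariates Adjustment set.
#' @return A `stat_map`; the product term is named
#'   `"<abeta_modality>:<fdg_modality>"`.
#' @export
fit_interaction_model <- function(cohort, groups = "MCI_pos",
                                  abeta_modality = "abeta",
                                  fdg_modality = "fdg",
                                  covariates = c("global_abeta",
                                                 setdiff(HUMAN_COVARIATES,
                                                         "gm_density"),
                                                 "gm_density",
                                                 "followup_years")) {
  spec <- voxel_model_spec(
    outcome = "cognitive_slope",
    voxel_terms = c(abeta_modality, fdg_modality),
    interaction_pairs = list(c(abeta_modality, fdg_modality)),
    covariates = covariates,
    group_filter = groups)
  fit_voxelwise(cohort, spec)
}

#' Per-voxel nested-model comparison
#'
#' Partial F-test of a full model against each nested reduced model at every
#' evaluated voxel, plus the fraction of default-mode voxels preferring the
#' full model at `alpha`.
#'
#' @param cohort A preprocessed [cohort_dataset()].
#' @param full_spec Full [voxel_model_spec()].
#' @param reduced_specs Named list of reduced specs, each nested in the full
#'   model (same outcome, terms a subset).
#' @param alpha Level used for the "full preferred" summary.
#' @return Named list per comparison with 3-D `F` and `p` arrays, degrees of
#'   freedom, and `frac_dmn_preferring_full`.
#' @export
compare_models <- function(cohort, full_spec, reduced_specs, alpha = 0.05) {
  full <- build_design(cohort, full_spec)
  out <- list()
  dmn_idx <- in_network_voxels(cohort$parcellation, "default_mode")
  for (nm in names(reduced_specs)) {
    red <- build_design(cohort, reduced_specs[[nm]])
    if (!all(red$term_names %in% full$term_names) ||
        !identical(reduced_specs[[nm]]$outcome, full_spec$outcome) ||
        !identical(red$ids, full$ids))
      stop("reduced model '", nm, "' is not nested in the full model")
    V <- length(full$mask_idx)
    p_f <- length(full$term_names); p_r <- length(red$term_names)
    df1 <- p_f - p_r; df2 <- full$n - p_f
    Fv <- rep(NA_real_, V); pv <- rep(NA_real_, V)
    single_y <- ncol(full$Y) == 1L
    for (v in seq_len(V)) {
      y <- if (single_y) full$Y[, 1] else full$Y[, v]
      if (sd(y) == 0) next
      Xf <- design_at_voxel(full, v); Xr <- design_at_voxel(red, v)
      ff <- .lm.fit(Xf, y); fr <- .lm.fit(Xr, y)
      if (ff$rank < p_f || fr$rank < p_r) next
      rssf <- sum(ff$residuals^2); rssr <- sum(fr$residuals^2)
      if (df1 == 0L) { Fv[v] <- 0; pv[v] <- 1; next }
      Fv[v] <- max(0, (rssr - rssf) / df1) / (rssf / df2)
      pv[v] <- pf(Fv[v], df1, df2, lower.tail = FALSE)
    }
    arrF <- array(NA_real_, full$grid); arrF[full$mask_idx] <- Fv
    arrP <- array(NA_real_, full$grid); arrP[full$mask_idx] <- pv
    dmn_sel <- full$mask_idx %in% dmn_idx
    frac <- mean(pv[dmn_sel] <= alpha, na.rm = TRUE)
    out[[nm]] <- list(F = arrF, p = arrP, df1 = df1, df2 = df2,
                      frac_dmn_preferring_full = frac)
  }
  out
}

# Flat indices of voxels belonging to a network's regions.
in_network_voxels <- function(parcellation, network) {
  rn <- unname(parcellation$roi_names)
  codes <- as.integer(names(parcellation$roi_names))
  sel <- codes[parcellation$network_of[rn] == network]
  which(parcellation$labels$data %in% sel)
}

#' Bootstrap stability of a coefficient under a competing term
#'
#' Resamples subjects with replacement and refits a region-level model of a
#' region's FDG mean with and without a competing predictor, recording the
#' focal coefficient each time. Collinearity between the focal and competing
#' predictors (e.g. global vs regional Abeta) would show as an inflated
#' empirical SD with the competing term present.
#'
#' @param cohort A preprocessed [cohort_dataset()].
#' @param roi Outcome region (FDG mean).
#' @param focal_term `"global_abeta"` or a subject-table column or
#'   `roi:<region>`.
#' @param competing_term Term added/removed between fits (same vocabulary;
#'   `roi:<region>` gives the region's Abeta mean).
#' @param covariates Adjustment set (scalar columns only).
#' @param groups Optional group filter.
#' @param n_reps Bootstrap replicates (>= 1; SDs undefined at 1).
#' @param seed Resampling seed.
#' @return A `bootstrap_result`: per-rep estimates with/without the
#'   competing term, their SDs, and the SD ratio.
#' @export
bootstrap_stability <- function(cohort, roi = "posterior_cingulate",
                                focal_term = "global_abeta",
                                competing_term = paste0("roi:", roi),
                                covariates = setdiff(HUMAN_COVARIATES,
                                                     "gm_density"),
                                groups = NULL, n_reps = 10000, seed = 1L) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  subjects <- cohort$subjects
  if (!is.null(groups))
    subjects <- subjects[subjects$group %in% groups, , drop = FALSE]
  fdg <- roi_mean_matrix(cohort, "fdg")[subjects$id, roi]
  focal <- scalar_column(cohort, subjects, focal_term)
  comp <- scalar_column(cohort, subjects, competing_term)
  Cov <- vapply(covariates, function(nm)
    scalar_column(cohort, subjects, nm), numeric(nrow(subjects)))
  X_with <- cbind(1, focal, comp, Cov)
  X_wo <- cbind(1, focal, Cov)
  n <- nrow(subjects)
  est_with <- numeric(n_reps); est_wo <- numeric(n_reps)
  set.seed(seed)
  redraws <- 0L
  for (r in seq_len(n_reps)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      fw <- .lm.fit(X_with[idx, , drop = FALSE], fdg[idx])
      fo <- .lm.fit(X_wo[idx, , drop = FALSE], fdg[idx])
      if (fw$rank == ncol(X_with) && fo$rank == ncol(X_wo)) break
      redraws <- redraws + 1L
    }
    est_with[r] <- fw$coefficients[2]
    est_wo[r] <- fo$coefficients[2]
  }
  sd_with <- if (n_reps > 1) sd(est_with) else NA_real_
  sd_wo <- if (n_reps > 1) sd(est_wo) else NA_real_
  structure(list(term = focal_term, competing_term = competing_term,
                 n_reps = n_reps, estimates_with = est_with,
                 estimates_without = est_wo, sd_with = sd_with,
                 sd_without = sd_wo, sd_ratio = sd_with / sd_wo,
                 n_redraws = redraws),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "<bootstrap_result> '%s' (vs '%s'), %d reps: SD with = %.4g, without = %.4g, ratio = %.3f\n",
    x$term, x$competing_term, x$n_reps, x$sd_with, x$sd_without, x$sd_ratio))
  invisible(x)
}
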