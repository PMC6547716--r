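# Region-level partial-correlation connectivity: symmetric glucose-glucose
# matrices, asymmetric Abeta-to-glucose matrices, matrix-element
# correlation, Euclidean-distance control, seed-to-voxel maps, and the
# seven-network overlap decomposition.

#' Region mean values of one volume
#'
#' @param vol An [image_volume()].
#' @param parcellation A [parcellation()].
#' @param roi_set Region names (default: all).
#' @return Named numeric of means over each region's voxels.
#' @export
extract_roi_means <- function(vol, parcellation,
                              roi_set = unname(parcellation$roi_names)) {
  rn <- unname(parcellation$roi_names)
  miss <- setdiff(roi_set, rn)
  if (length(miss)) stop("missing ROI label(s): ", paste(miss, collapse = ", "))
  codes <- as.integer(names(parcellation$roi_names))[match(roi_set, rn)]
  m <- vapply(seq_along(roi_set), function(i)
    mean(vol$data[parcellation$labels$data == codes[i]]), numeric(1))
  setNames(m, roi_set)
}

#' Subject x region matrix of region means
#'
#' @param cohort A [cohort_dataset()].
#' @param modality Modality to summarise.
#' @param roi_set Region names.
#' @param pvc Apply geometric-transfer-matrix partial-volume correction of
#'   the region means ([gtm_correct()]), renormalised to `reference`.
#' @param fwhm_mm Smoothing FWHM used for the GTM (defaults to the cohort's
#'   provenance record, else 8).
#' @param reference Reference region for renormalisation when `pvc = TRUE`.
#' @return Subjects x regions matrix.
#' @export
roi_mean_matrix <- function(cohort, modality,
                            roi_set = unname(cohort$parcellation$roi_names),
                            pvc = FALSE, fwhm_mm = NULL, reference = NULL) {
  p <- cohort$parcellation
  ids <- cohort$subjects$id
  if (pvc) {
    if (is.null(fwhm_mm)) {
      prov <- attr(cohort, "provenance")
      fwhm_mm <- prov$config$smoothing_fwhm_mm %||% 8
    }
    G <- roi_transfer_matrix(p, fwhm_mm)
  }
  out <- matrix(NA_real_, length(ids), length(roi_set),
                dimnames = list(ids, roi_set))
  for (id in ids) {
    m <- extract_roi_means(cohort$volumes[[id]][[modality]], p)
    if (pvc) m <- gtm_correct(m, G, reference = reference)
    out[id, ] <- m[roi_set]
  }
  out
}

#' Pearson partial correlation
#'
#' Correlation of the OLS residuals of `x` and `y` after each is regressed
#' on an intercept plus the covariates; the p-value uses
#' t = r sqrt(df / (1 - r^2)) with df = n - 2 - n_covariates.
#'
#' @param x,y Numeric vectors.
#' @param covariate_table Data frame or matrix of covariates (may have zero
#'   columns for a plain Pearson correlation).
#' @return List with `r`, `p`, `df`.
#' @export
partial_corr <- function(x, y, covariate_table = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (is.null(covariate_table) || NCOL(covariate_table) == 0L ||
      NROW(covariate_table) == 0L) {
    Z <- matrix(1, n, 1)
    k <- 0L
  } else {
    Z <- cbind(1, as.matrix(covariate_table))
    k <- ncol(Z) - 1L
    if (qr(Z)$rank < ncol(Z)) stop("collinear covariates")
  }
  if (n <= k + 2L) stop("need n > n_covariates + 2")
  rx <- .lm.fit(Z, x)$residuals
  ry <- .lm.fit(Z, y)$residuals
  if (sd(rx) <= 1e-12 * max(sd(x), 1) || sd(ry) <= 1e-12 * max(sd(y), 1))
    stop("zero residual variance")
  r <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  r <- max(-1, min(1, r))
  df <- n - 2L - k
  tt <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * pt(-abs(tt), df), df = df)
}

# Subject-level covariate matrix for connectivity models; "gm_density"
# resolves to the subject's in-mask mean gray-matter density.
connectivity_covariates <- function(cohort, subjects, covariates) {
  if (!length(covariates)) return(NULL)
  cols <- lapply(covariates, function(nm) {
    if (nm == "gm_density") {
      idx <- which(cohort$mask$data != 0)
      vapply(subjects$id, function(id)
        mean(cohort$volumes[[id]]$gm_density$data[idx]), numeric(1))
    } else {
      scalar_column(cohort, subjects, nm)
    }
  })
  out <- do.call(cbind, cols)
  colnames(out) <- covariates
  out
}

new_connectivity_matrix <- function(r, p, row_nodes, col_nodes, symmetric,
                                    controlled_for, correction) {
  dimnames(r) <- dimnames(p) <- list(row_nodes, col_nodes)
  structure(list(row_nodes = row_nodes, col_nodes = col_nodes, r = r, p = p,
                 symmetric = symmetric, controlled_for = controlled_for,
                 correction = correction),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %dx%d (%s), Bonferroni m = %d\n",
              length(x$row_nodes), length(x$col_nodes),
              if (x$symmetric) "symmetric" else "asymmetric",
              x$correction$m_tests))
  invisible(x)
}

#' Metabolic connectivity matrix
#'
#' Symmetric matrix of pairwise partial correlations of regional FDG means
#' across subjects, Bonferroni-corrected over the R(R-1)/2 unique
#' off-diagonal tests.
#'
#' @param cohort A preprocessed [cohort_dataset()].
#' @param roi_set Region names (default: all non-reference analysis
#'   regions).
#' @param covariates Partial-correlation adjustment set.
#' @param groups Optional group filter.
#' @param alpha Level for the Bonferroni-corrected significance flags.
#' @return A `connectivity_matrix` with fields `r`, `p` (uncorrected),
#'   `significant` (Bonferroni at `alpha`).
#' @export
metabolic_matrix <- function(cohort, roi_set = analysis_rois(cohort),
                             covariates = HUMAN_COVARIATES,
                             groups = NULL, alpha = 0.05) {
  subjects <- filter_subjects(cohort, groups)
  M <- roi_mean_matrix(cohort, "fdg", roi_set)[subjects$id, , drop = FALSE]
  Z <- connectivity_covariates(cohort, subjects, covariates)
  R <- length(roi_set)
  r <- diag(1, R); p <- matrix(0, R, R); diag(p) <- 0
  for (i in seq_len(R - 1)) {
    for (j in (i + 1):R) {
      pc <- partial_corr(M[, i], M[, j], Z)
      r[i, j] <- r[j, i] <- pc$r
      p[i, j] <- p[j, i] <- pc$p
    }
  }
  m <- R * (R - 1) / 2
  out <- new_connectivity_matrix(r, p, roi_set, roi_set, TRUE, covariates,
                                 list(method = "bonferroni", alpha = alpha,
                                      m_tests = as.integer(m)))
  out$significant <- p * m <= alpha & row(p) != col(p)
  dimnames(out$significant) <- dimnames(out$r)
  out
}

#' Cross-modal Abeta-to-glucose connectivity matrix
#'
#' Asymmetric matrix whose (i, j) entry is the partial correlation of the
#' Abeta mean in region i with the FDG mean in region j; Bonferroni over all
#' R^2 tests (the diagonal, i.e. local associations, is itself a finding
#' and is kept).
#'
#' @inheritParams metabolic_matrix
#' @param row_modality,col_modality Modalities summarised on the rows and
#'   columns (defaults Abeta rows, FDG columns; swapping them transposes
#'   the matrix).
#' @return A `connectivity_matrix` (asymmetric).
#' @export
cross_modal_matrix <- function(cohort, roi_set = analysis_rois(cohort),
                               covariates = HUMAN_COVARIATES,
                               groups = NULL, alpha = 0.05,
                               row_modality = "abeta",
                               col_modality = "fdg") {
  subjects <- filter_subjects(cohort, groups)
  A <- roi_mean_matrix(cohort, row_modality,
                       roi_set)[subjects$id, , drop = FALSE]
  Fm <- roi_mean_matrix(cohort, col_modality,
                        roi_set)[subjects$id, , drop = FALSE]
  Z <- connectivity_covariates(cohort, subjects, covariates)
  R <- length(roi_set)
  r <- matrix(NA_real_, R, R); p <- matrix(NA_real_, R, R)
  for (i in seq_len(R)) {
    for (j in seq_len(R)) {
      pc <- partial_corr(A[, i], Fm[, j], Z)
      r[i, j] <- pc$r; p[i, j] <- pc$p
    }
  }
  m <- R * R
  out <- new_connectivity_matrix(r, p, roi_set, roi_set, FALSE, covariates,
                                 list(method = "bonferroni", alpha = alpha,
                                      m_tests = as.integer(m)))
  out$significant <- p * m <= alpha
  dimnames(out$significant) <- dimnames(out$r)
  out
}

#' Correlation between the elements of two connectivity matrices
#'
#' @param matA,matB `connectivity_matrix` objects (or plain matrices) over
#'   the same node sets.
#' @param entries `"offdiag"` (default) or `"all"`.
#' @return List with Pearson `r` and `p` over the selected entries.
#' @export
element_correlation <- function(matA, matB, entries = c("offdiag", "all")) {
  entries <- match.arg(entries)
  a <- if (inherits(matA, "connectivity_matrix")) matA$r else matA
  b <- if (inherits(matB, "connectivity_matrix")) matB$r else matB
  if (!all(dim(a) == dim(b))) stop("non-conformable matrices")
  sel <- if (entries == "offdiag") row(a) != col(a) else
    matrix(TRUE, nrow(a), ncol(a))
  ct <- stats::cor.test(a[sel], b[sel])
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Matrix elements versus internode Euclidean distance
#'
#' Pearson correlation between the off-diagonal matrix entries and the
#' Euclidean distances (mm) between region centroids, to check that
#' associations are not driven by regions' proximity.
#'
#' @param mat A `connectivity_matrix`.
#' @param centroids_mm Regions x 3 matrix of world centroids with rownames
#'   covering the matrix's nodes.
#' @return List with `r` and `p`.
#' @export
distance_control <- function(mat, centroids_mm) {
  nodes_r <- mat$row_nodes; nodes_c <- mat$col_nodes
  if (!all(nodes_r %in% rownames(centroids_mm)) ||
      !all(nodes_c %in% rownames(centroids_mm)))
    stop("centroid rownames do not cover the matrix nodes")
  D <- matrix(NA_real_, length(nodes_r), length(nodes_c))
  for (i in seq_along(nodes_r)) {
    for (j in seq_along(nodes_c)) {
      D[i, j] <- sqrt(sum((centroids_mm[nodes_r[i], ] -
                             centroids_mm[nodes_c[j], ])^2))
    }
  }
  sel <- if (identical(nodes_r, nodes_c)) row(D) != col(D) else
    matrix(TRUE, nrow(D), ncol(D))
  ct <- stats::cor.test(mat$r[sel], D[sel])
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Seed-region to voxel association map
#'
#' Regression of the target modality at every voxel on the seed region's
#' Abeta mean plus covariates (a delegation to [fit_voxelwise()] with the
#' seed mean as a global term), FWER-corrected for the seed term.
#'
#' @param cohort A preprocessed [cohort_dataset()].
#' @param seed_roi Seed region name (Abeta mean across its voxels).
#' @param target_modality Outcome modality (only `"fdg"` supported).
#' @param covariates Adjustment set.
#' @param groups Optional group filter.
#' @param correction `"permutation_maxT"`, `"bonferroni"`, or `"none"`.
#' @param alpha,n_perm,seed Correction parameters.
#' @return A `stat_map` corrected for the seed term (named
#'   `roi:<seed_roi>`).
#' @export
seed_to_voxel_map <- function(cohort, seed_roi, target_modality = "fdg",
                              covariates = HUMAN_COVARIATES, groups = NULL,
                              correction = "permutation_maxT", alpha = 0.05,
                              n_perm = 500, seed = 1L) {
  if (target_modality != "fdg") stop("only fdg outcomes are supported")
  term <- paste0("roi:", seed_roi)
  spec <- voxel_model_spec(outcome = "voxel_fdg",
                           global_terms = term,
                           covariates = covariates,
                           group_filter = groups)
  map <- fit_voxelwise(cohort, spec)
  if (correction != "none")
    map <- fwer_correct(map, term, method = correction, alpha = alpha,
                        n_perm = n_perm, seed = seed)
  map
}

#' Seven-network decomposition of a suprathreshold mask
#'
#' Percentage of suprathreshold voxels falling in each of the seven
#' networks; the percentages sum to exactly 100 at the reported precision
#' (the largest entry absorbs the rounding remainder).
#'
#' @param suprathreshold_mask 3-D logical array (or a corrected `stat_map`).
#' @param parcellation A [parcellation()].
#' @param digits Reporting precision.
#' @return Named numeric over [network_names()], summing to 100.
#' @export
network_overlap <- function(suprathreshold_mask, parcellation, digits = 1) {
  if (inherits(suprathreshold_mask, "stat_map")) {
    if (is.null(suprathreshold_mask$suprathreshold))
      stop("map has no suprathreshold mask; run fwer_correct() first")
    suprathreshold_mask <- suprathreshold_mask$suprathreshold
  }
  sel <- which(suprathreshold_mask %in% TRUE)
  if (!length(sel)) stop("empty suprathreshold mask")
  labs <- parcellation$labels$data[sel]
  if (any(labs == 0)) stop("suprathreshold voxels outside labelled regions")
  rn <- unname(parcellation$roi_names)
  codes <- as.integer(names(parcellation$roi_names))
  nets <- parcellation$network_of[rn][match(labs, codes)]
  counts <- vapply(network_names(), function(nw) sum(nets == nw), numeric(1))
  pct <- round(100 * counts / sum(counts), digits)
  top <- which.max(pct)
  pct[top] <- round(100 - sum(pct[-top]), digits)
  pct
}

# Non-reference analysis regions of a cohort's parcellation.
analysis_rois <- function(cohort) {
  setdiff(unname(cohort$parcellation$roi_names), c("cerebellum", "pons"))
}

filter_subjects <- function(cohort, groups) {
  s <- cohort$subjects
  if (!is.null(groups)) s <- s[s$group %in% groups, , drop = FALSE]
  if (nrow(s) < 4L) stop("too few subjects after group filtering")
  s
}
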