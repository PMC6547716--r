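# Image-level normalisation and scalar derivations: Gaussian smoothing,
# SUVR, global Abeta composite, Abeta positivity, cognitive slopes, and
# geometric-transfer-matrix (GTM) correction of ROI means.

#' 1-D Gaussian smoothing operator with reflective (zero-flux) boundaries
#'
#' Returns an L x L row-stochastic matrix; because reflection keeps every
#' kernel weight inside the domain, column sums are also 1, so convolution
#' preserves both constants and the total image sum.
#' @noRd
gauss_operator_1d <- function(L, sigma_vox) {
  if (sigma_vox <= 0) return(diag(L))
  r <- max(1L, ceiling(4 * sigma_vox))
  w <- dnorm(seq(-r, r), sd = sigma_vox)
  w <- w / sum(w)
  K <- matrix(0, L, L)
  for (i in seq_len(L)) {
    for (k in seq(-r, r)) {
      j <- i + k
      # reflect about the boundary edges (scipy-style 'reflect')
      while (j < 1L || j > L) {
        if (j < 1L) j <- 1L - j
        if (j > L) j <- 2L * L + 1L - j
      }
      K[j, i] <- K[j, i] + w[k + r + 1L]
    }
  }
  K
}

#' Smooth a volume with an isotropic Gaussian kernel
#'
#' Separable Gaussian smoothing with sigma = fwhm / (2 sqrt(2 ln 2)) in mm,
#' converted to voxels per axis. Boundaries are handled by reflection
#' (zero-flux), which preserves the total image sum and leaves constant
#' volumes unchanged. `fwhm_mm = 0` is the identity.
#'
#' @param vol An [image_volume()].
#' @param fwhm_mm Full-width at half-maximum in mm (>= 0).
#' @param intrinsic_fwhm_mm If the input already carries intrinsic smoothness,
#'   the applied kernel is sqrt(fwhm_mm^2 - intrinsic_fwhm_mm^2) so that the
#'   output reaches the target resolution.
#' @return A smoothed [image_volume()] of the same modality.
#' @export
smooth_volume <- function(vol, fwhm_mm, intrinsic_fwhm_mm = 0) {
  stopifnot(is_image_volume(vol))
  if (fwhm_mm < 0) stop("'fwhm_mm' must be >= 0")
  if (intrinsic_fwhm_mm < 0 || intrinsic_fwhm_mm > fwhm_mm)
    stop("'intrinsic_fwhm_mm' must lie in [0, fwhm_mm]")
  eff <- sqrt(fwhm_mm^2 - intrinsic_fwhm_mm^2)
  if (eff == 0) return(vol)
  out <- smooth_array(vol$data, eff, vol$voxel_size_mm)
  image_volume(out, vol$voxel_size_mm, vol$affine, vol$modality)
}

#' @noRd
smooth_array <- function(arr, fwhm_mm, voxel_size_mm) {
  d <- dim(arr)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  x <- arr
  for (ax in 1:3) {
    K <- gauss_operator_1d(d[ax], sigma_mm / voxel_size_mm[ax])
    perm <- c(ax, setdiff(1:3, ax))
    xp <- aperm(x, perm)
    dim(xp) <- c(d[ax], prod(d[-ax]))
    xp <- K %*% xp
    dim(xp) <- d[perm]
    x <- aperm(xp, order(perm))
  }
  x
}

#' Standardized uptake value ratio (SUVR) image
#'
#' Divides every voxel by the mean over a reference-region mask (cerebellar
#' gray matter for Abeta, pons for FDG).
#'
#' @param vol An [image_volume()].
#' @param reference_mask Logical/0-1 array on the same grid.
#' @return An [image_volume()] in SUVR units.
#' @export
compute_suvr <- function(vol, reference_mask) {
  stopifnot(is_image_volume(vol))
  ref <- vol$data[reference_mask != 0]
  if (!length(ref)) stop("empty reference region")
  m <- mean(ref)
  if (!is.finite(m) || m <= 0) stop("non-positive reference mean: ", m)
  image_volume(vol$data / m, vol$voxel_size_mm, vol$affine, vol$modality)
}

#' Composite region specification
#'
#' @param roi_names Regions entering the composite (unweighted mean of ROI
#'   means).
#' @param reference_region Reference region name, disjoint from the
#'   composite set.
#' @return Object of class `composite_spec`.
#' @export
composite_spec <- function(roi_names, reference_region) {
  if (!length(roi_names)) stop("composite ROI list must be non-empty")
  if (reference_region %in% roi_names)
    stop("reference region must be disjoint from the composite ROIs")
  structure(list(roi_names = roi_names, reference_region = reference_region),
            class = "composite_spec")
}

#' Default global Abeta composite
#'
#' The eight cortical regions entering the global Abeta value: precuneus,
#' posterior and anterior cingulate, inferior parietal, paracentral, medial
#' prefrontal, lateral temporal, and orbitofrontal cortices, referenced to
#' cerebellar gray matter.
#' @return A [composite_spec()].
#' @export
default_composite <- function() {
  composite_spec(c("precuneus", "posterior_cingulate", "anterior_cingulate",
                   "inferior_parietal", "paracentral", "medial_prefrontal",
                   "lateral_temporal", "orbitofrontal"),
                 reference_region = "cerebellum")
}

#' Global composite value from an SUVR image
#'
#' Unweighted mean of the ROI mean values over the composite regions.
#'
#' @param suvr_vol An SUVR [image_volume()].
#' @param parcellation A [parcellation()].
#' @param spec A [composite_spec()].
#' @return Scalar composite value.
#' @export
global_composite <- function(suvr_vol, parcellation, spec = default_composite()) {
  m <- extract_roi_means(suvr_vol, parcellation, spec$roi_names)
  mean(m)
}

#' Classify amyloid status from the global composite
#'
#' Positive iff the composite strictly exceeds the threshold (default 1.15);
#' the boundary value itself is negative.
#'
#' @param global_suvr Scalar (finite) composite SUVR.
#' @param threshold Positivity cutoff.
#' @return Logical: amyloid positive?
#' @export
classify_amyloid_status <- function(global_suvr, threshold = 1.15) {
  if (!is.finite(global_suvr)) stop("non-finite composite value")
  global_suvr > threshold
}

#' Per-subject cognitive slope
#'
#' Ordinary least-squares slope of score on time (per year), using all
#' available visits.
#'
#' @param times Visit times in years from baseline (>= 2 distinct values).
#' @param scores Cognitive scores, same length.
#' @return Slope in score units per year.
#' @export
cognitive_slope <- function(times, scores) {
  if (length(times) != length(scores)) stop("length mismatch")
  if (length(times) < 2L) stop("need at least 2 visits to define a slope")
  if (length(unique(times)) < 2L) stop("all visit times identical")
  tc <- times - mean(times)
  sum(tc * (scores - mean(scores))) / sum(tc^2)
}

#' ROI geometric transfer matrix of the smoothing kernel
#'
#' Entry (r, s) is the mean over region r's voxels of the smoothed indicator
#' of region s: the fraction of region s's signal observed inside region r
#' after Gaussian smoothing. Solving the linear system with this matrix
#' undoes the partial-volume attenuation of ROI means for piecewise-constant
#' sources on a zero background.
#'
#' @param parcellation A [parcellation()].
#' @param fwhm_mm Smoothing FWHM that was applied to the images.
#' @return R x R matrix with region-name dimnames.
#' @export
roi_transfer_matrix <- function(parcellation, fwhm_mm) {
  labs <- parcellation$labels
  rn <- unname(parcellation$roi_names)
  codes <- as.integer(names(parcellation$roi_names))
  G <- matrix(NA_real_, length(codes), length(codes), dimnames = list(rn, rn))
  roi_idx <- lapply(codes, function(k) which(labs$data == k))
  for (s in seq_along(codes)) {
    ind <- array(0, dim(labs$data))
    ind[roi_idx[[s]]] <- 1
    sm <- smooth_array(ind, fwhm_mm, labs$voxel_size_mm)
    for (r in seq_along(codes)) G[r, s] <- mean(sm[roi_idx[[r]]])
  }
  G
}

#' GTM-corrected ROI means
#'
#' Given observed ROI means of a smoothed volume, returns the
#' partial-volume-corrected region values G^{-1} m, optionally renormalized
#' so that a reference region equals 1 (ROI-level SUVR after correction).
#'
#' @param observed_means Named numeric of observed ROI means (names matching
#'   the rows of `G`).
#' @param G Matrix from [roi_transfer_matrix()].
#' @param reference Optional reference region name for renormalization.
#' @return Named numeric of corrected region values.
#' @export
gtm_correct <- function(observed_means, G, reference = NULL) {
  rn <- rownames(G)
  u <- solve(G, observed_means[rn])
  names(u) <- rn
  if (!is.null(reference)) {
    if (!reference %in% rn) stop("unknown reference region: ", reference)
    u <- u / u[reference]
  }
  u
}

#' Derive SUVR volumes, global composites, and cognitive slopes for a cohort
#'
#' Applies [compute_suvr()] per subject (Abeta referenced to the composite
#' spec's reference region; FDG referenced to `fdg_reference`), fills the
#' cohort's `global_abeta` field via [global_composite()], and attaches a
#' `slope` column (and the per-subject visit count) to the subject table.
#'
#' @param cohort A [cohort_dataset()] with raw tracer volumes.
#' @param spec A [composite_spec()].
#' @param fdg_reference Reference region name for the FDG SUVR (pons).
#' @return The cohort with SUVR volumes, `global_abeta`, and slopes.
#' @export
preprocess_cohort <- function(cohort, spec = default_composite(),
                              fdg_reference = "pons") {
  p <- cohort$parcellation
  ref_mask_of <- function(region) {
    code <- as.integer(names(p$roi_names)[match(region, p$roi_names)])
    if (is.na(code)) stop("missing reference region: ", region)
    p$labels$data == code
  }
  ab_ref <- ref_mask_of(spec$reference_region)
  fd_ref <- ref_mask_of(fdg_reference)
  ids <- cohort$subjects$id
  ga <- setNames(numeric(length(ids)), ids)
  for (id in ids) {
    cohort$volumes[[id]]$abeta <- compute_suvr(cohort$volumes[[id]]$abeta, ab_ref)
    cohort$volumes[[id]]$fdg <- compute_suvr(cohort$volumes[[id]]$fdg, fd_ref)
    ga[id] <- global_composite(cohort$volumes[[id]]$abeta, p, spec)
  }
  cohort$global_abeta <- ga
  cg <- cohort$cognition
  slope <- rep(NA_real_, length(ids))
  nvis <- rep(NA_integer_, length(ids))
  if (!is.null(cg)) {
    for (i in seq_along(ids)) {
      sel <- cg$id == ids[i]
      nvis[i] <- sum(sel)
      if (sum(sel) >= 2L)
        slope[i] <- cognitive_slope(cg$time_years[sel], cg$score[sel])
    }
  }
  cohort$subjects$slope <- slope
  cohort$subjects$n_visits <- nvis
  cohort$subjects$amyloid_positive <-
    as.integer(vapply(ga, classify_amyloid_status, logical(1)))
  validate_cohort(cohort)
  cohort
}
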