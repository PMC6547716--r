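# Synthetic multimodal cohort generator.
#
# Region-level generative model with voxel broadcasting:
#   a_r  ~ Normal(group mean, network-structured covariance)      (Abeta)
#   g_r  = b0 - gamma * (W a)_r + delta * a_r + covariate effects
#          + network-structured noise                              (FDG)
#   slope = c0 + beta3 * mean_{r in DMN}( a_r * -(g_r - E g_r) )
#          + covariate effects + residual
# Voxel volumes broadcast the region values onto contiguous blocks, add
# voxel noise, and are Gaussian-smoothed; raw tracer volumes carry a
# per-scan multiplicative scale that the SUVR step removes.

# Group-level covariate distributions: age/sex/education/APOE4/follow-up
# and MMSE-scale parameters encode a realistic elderly amyloid-imaging
# cohort; p-tau levels are plausible CSF immunoassay values.
GROUP_PARAMS <- list(
  CN_neg  = list(age = c(74.5, 6.7), male = 0.57, edu = c(16.5, 2.8),
                 apoe4 = 0.20, ptau = c(20, 8), fup = c(3.41, 0.97),
                 mmse0 = c(29.1, 1.2), slope0 = -0.08, abeta = 1.07,
                 gm_shift = 0),
  CN_pos  = list(age = c(75.3, 6.9), male = 0.28, edu = c(16.0, 2.3),
                 apoe4 = 0.38, ptau = c(28, 10), fup = c(3.49, 1.00),
                 mmse0 = c(28.9, 1.1), slope0 = -0.12, abeta = 1.30,
                 gm_shift = -0.02),
  MCI_pos = list(age = c(73.2, 6.7), male = 0.52, edu = c(15.9, 2.7),
                 apoe4 = 0.62, ptau = c(35, 12), fup = c(3.26, 1.07),
                 mmse0 = c(27.7, 1.9), slope0 = -0.95, abeta = 1.35,
                 gm_shift = -0.05),
  tg_rat  = list(age = c(0.92, 0.05), male = 0.5, edu = c(0, 0),
                 apoe4 = 0, ptau = c(0, 0), fup = c(0.67, 0.02),
                 mmse0 = c(60, 5), slope0 = -5, abeta = 1.5,
                 gm_shift = -0.03),
  wt_rat  = list(age = c(0.92, 0.05), male = 0.5, edu = c(0, 0),
                 apoe4 = 0, ptau = c(0, 0), fup = c(0.67, 0.02),
                 mmse0 = c(60, 5), slope0 = 0, abeta = 1.0,
                 gm_shift = 0))

# Fixed standardisation constants for covariates entering effect terms, so
# that the null configuration stays exchangeable.
COVARIATE_SCALE <- list(age = c(74, 7), sex = c(0.5, 0.5),
                        education = c(16, 2.7), apoe4 = c(0.4, 0.5),
                        ptau = c(28, 12))

#' Configuration for the synthetic cohort generator
#'
#' Defaults encode a realistic elderly amyloid-imaging cohort: group sizes
#' of 99 / 53 / 170, literature-typical covariate distributions, 8-mm
#' smoothing, composite-scale Abeta group means (1.07 / 1.30 / 1.35 SUVR),
#' and four cognitive visits over ~3.4 years. Effect sizes and noise
#' scales are the package's documented power calibration (see the methods
#' vignette).
#'
#' @param n_subjects Named integer vector of subjects per group.
#' @param grid_shape 3-D grid dimensions.
#' @param voxel_size_mm Voxel size in mm.
#' @param n_rois Number of regions (12 selects the curated atlas with named
#'   cortical regions plus cerebellum/pons reference blocks).
#' @param gamma Distant Abeta-to-glucose effect size (>= 0, enters
#'   negatively through the coupling matrix `W`).
#' @param delta Local Abeta-to-glucose effect (default 0).
#' @param beta3 Named numeric of local interaction effects on the cognitive
#'   slope per group (<= 0 for impaired groups, 0 for controls).
#' @param W Optional region-coupling matrix (nonnegative, zero diagonal,
#'   within-network entries >= between-network entries). Default: 0.3
#'   between distinct default-mode regions, 0 elsewhere.
#' @param fdg_b0 Baseline FDG SUVR level of analysis regions.
#' @param noise_sd Named list: `roi_abeta`, `roi_fdg`, `voxel`, `slope`,
#'   `visit`, `gm_roi`, `gm_voxel`, `ref_roi`, `scan_scale`.
#' @param roi_cor Named list (`abeta`, `fdg`) of within/between-network
#'   correlations of the region noise; the FDG block encodes the
#'   default-mode metabolic covariance, while Abeta deposition noise is
#'   close to spatially independent so that local Abeta-metabolism
#'   correlations stay null under `delta = 0`.
#' @param covariate_effects List with named vectors `fdg` and `slope` of
#'   per-SD covariate effects (all zero gives the exchangeable null).
#' @param interaction_rois The designated posterior default-mode regions
#'   whose local Abeta-hypometabolism products drive the cognitive slope.
#' @param smoothing_fwhm_mm Gaussian smoothing applied to all volumes.
#' @param n_visits Cognitive visits per subject.
#' @param seed Master seed; per-subject streams are derived from it.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(n_subjects = c(CN_neg = 99, CN_pos = 53, MCI_pos = 170),
                         grid_shape = c(24, 24, 24),
                         voxel_size_mm = c(2, 2, 2),
                         n_rois = 12,
                         gamma = 0.5,
                         delta = 0,
                         beta3 = c(CN_neg = 0, CN_pos = 0, MCI_pos = -0.4,
                                   tg_rat = -0.4, wt_rat = 0),
                         W = NULL,
                         fdg_b0 = 1.3,
                         noise_sd = list(roi_abeta = 0.25, roi_fdg = 0.06,
                                         voxel = 0.05, slope = 0.003,
                                         visit = 0.006, gm_roi = 0.03,
                                         gm_voxel = 0.05, ref_roi = 0.005,
                                         scan_scale = 0.1),
                         roi_cor = list(abeta = c(within = 0.05, between = 0),
                                        fdg = c(within = 0.5, between = 0.1)),
                         covariate_effects = list(
                           fdg = c(age = -0.02, sex = 0.01, education = 0.005,
                                   apoe4 = -0.02, ptau = -0.02),
                           slope = c(age = -0.02, sex = 0, education = 0.01,
                                     apoe4 = -0.03, ptau = -0.03)),
                         interaction_rois = c("precuneus",
                                              "posterior_cingulate",
                                              "inferior_parietal"),
                         smoothing_fwhm_mm = 8,
                         n_visits = 4,
                         seed = 1L) {
  stopifnot(gamma >= 0, length(grid_shape) == 3, n_rois >= 2,
            all(n_subjects >= 0), !is.null(names(n_subjects)))
  if (!all(names(n_subjects) %in% GROUP_TAGS)) stop("unknown group tag")
  cfg <- structure(list(n_subjects = n_subjects, grid_shape = grid_shape,
                        voxel_size_mm = voxel_size_mm, n_rois = n_rois,
                        gamma = gamma, delta = delta, beta3 = beta3, W = W,
                        fdg_b0 = fdg_b0, noise_sd = noise_sd,
                        roi_cor = roi_cor,
                        covariate_effects = covariate_effects,
                        interaction_rois = interaction_rois,
                        smoothing_fwhm_mm = smoothing_fwhm_mm,
                        n_visits = n_visits, seed = as.integer(seed)),
                   class = "synth_config")
  atlas <- make_atlas(cfg)
  if (is.null(cfg$W)) cfg$W <- default_coupling(atlas)
  check_coupling(cfg$W, atlas)
  cfg$atlas <- atlas
  cfg$roi_idx <- lapply(seq_along(atlas$roi_names),
                        function(i) which(atlas$labels$data == i))
  cfg
}

check_coupling <- function(W, atlas) {
  rn <- unname(atlas$roi_names)
  stopifnot(all(rownames(W) == rn), all(colnames(W) == rn))
  if (any(W < 0)) stop("coupling matrix must be nonnegative")
  if (any(diag(W) != 0)) stop("coupling matrix must have zero diagonal")
  net <- atlas$network_of[rn]
  same <- outer(net, net, "==") & !diag(length(rn))
  analysis <- !rn %in% c("cerebellum", "pons")
  keep <- outer(analysis, analysis, "&")
  if (any(same & keep) && any(!same & keep) &&
      min(W[same & keep]) < max(W[!same & keep]))
    stop("within-network coupling must be >= between-network coupling")
  invisible(W)
}

#' Default region-coupling matrix
#'
#' 0.3 between every pair of distinct default-mode regions, 0 elsewhere
#' (reference regions have no coupling).
#'
#' @param atlas A [parcellation()].
#' @return Region x region matrix.
#' @export
default_coupling <- function(atlas) {
  rn <- unname(atlas$roi_names)
  dm <- rn[atlas$network_of[rn] == "default_mode"]
  W <- matrix(0, length(rn), length(rn), dimnames = list(rn, rn))
  W[dm, dm] <- 0.3
  diag(W) <- 0
  W
}

#' Build the synthetic parcellation
#'
#' Contiguous non-overlapping cuboid blocks (each >= 27 voxels) on a block
#' lattice with one- to two-voxel background gaps. With the default
#' `n_rois = 12` a curated atlas is produced: ten analysis regions (eight
#' composite regions plus insula and occipital pole) with the five
#' default-mode regions mutually adjacent, and two reference blocks
#' (cerebellum, pons). Other values give generically named regions.
#'
#' @param config A [synth_config()] (or any list with `grid_shape`,
#'   `voxel_size_mm`, `n_rois`).
#' @return A [parcellation()].
#' @export
make_atlas <- function(config) {
  d <- config$grid_shape
  n <- config$n_rois
  b <- ceiling(n^(1 / 3))
  bs <- floor(min(d) / b)
  if (bs - 1L < 3L) stop("grid too small for ", n, " regions")
  # block k occupies voxels (k-1)*bs + 2 .. k*bs - ... leave a 1-voxel rim
  span <- function(k) ((k - 1L) * bs + 2L):(k * bs - 1L)
  curated <- n == 12 && b == 3
  if (curated) {
    # default-mode blocks deliberately scattered across the lattice so that
    # network membership and internode distance stay unconfounded
    blocks <- list(
      precuneus = c(3, 2, 2), posterior_cingulate = c(2, 3, 1),
      inferior_parietal = c(1, 2, 3), lateral_temporal = c(2, 2, 3),
      medial_prefrontal = c(3, 3, 1), anterior_cingulate = c(1, 1, 1),
      paracentral = c(3, 1, 2), orbitofrontal = c(2, 1, 1),
      insula = c(1, 3, 2), occipital_pole = c(2, 2, 2),
      cerebellum = c(3, 3, 3), pons = c(1, 3, 3))
    networks <- c(
      precuneus = "default_mode", posterior_cingulate = "default_mode",
      inferior_parietal = "default_mode", lateral_temporal = "default_mode",
      medial_prefrontal = "default_mode", anterior_cingulate = "limbic",
      paracentral = "somatomotor", orbitofrontal = "limbic",
      insula = "ventral_attention", occipital_pole = "visual",
      cerebellum = "somatomotor", pons = "somatomotor")
  } else {
    coords <- expand.grid(x = 1:b, y = 1:b, z = 1:b)[seq_len(n), ]
    blocks <- lapply(seq_len(n), function(i) as.numeric(coords[i, ]))
    names(blocks) <- sprintf("roi_%02d", seq_len(n))
    n_dm <- max(2L, round(0.4 * n))
    nets <- c(rep("default_mode", n_dm),
              rep(setdiff(network_names(), "default_mode"),
                  length.out = n - n_dm))
    networks <- setNames(nets, names(blocks))
  }
  arr <- array(0L, d)
  for (i in seq_along(blocks)) {
    bc <- blocks[[i]]
    arr[span(bc[1]), span(bc[2]), span(bc[3])] <- i
  }
  labels <- image_volume(arr, voxel_size_mm = config$voxel_size_mm,
                         affine = diag(c(config$voxel_size_mm, 1)),
                         modality = "label")
  parcellation(labels, setNames(names(blocks), as.character(seq_along(blocks))),
               networks)
}

synth_reference_rois <- function(atlas) {
  intersect(c("cerebellum", "pons"), unname(atlas$roi_names))
}

std_covariates <- function(record) {
  vapply(names(COVARIATE_SCALE), function(v) {
    sc <- COVARIATE_SCALE[[v]]
    (record[[v]] - sc[1]) / sc[2]
  }, numeric(1))
}

# Cholesky of the network-structured region correlation (analysis ROIs)
roi_noise_chol <- function(atlas, cor_pair) {
  rn <- setdiff(unname(atlas$roi_names), synth_reference_rois(atlas))
  net <- atlas$network_of[rn]
  C <- outer(net, net, function(a, b)
    ifelse(a == b, cor_pair[["within"]], cor_pair[["between"]]))
  diag(C) <- 1
  dimnames(C) <- list(rn, rn)
  chol(C)
}

# Expected region-level FDG given the group (covariates standardised, so
# their expected contribution is ~0); used to centre the interaction driver.
expected_fdg <- function(config, group) {
  atlas <- config$atlas
  rn <- unname(atlas$roi_names)
  refs <- synth_reference_rois(atlas)
  mu_a <- setNames(rep(GROUP_PARAMS[[group]]$abeta, length(rn)), rn)
  mu_a[refs] <- 1
  eg <- config$fdg_b0 - config$gamma * as.vector(config$W %*% mu_a) +
    config$delta * mu_a
  names(eg) <- rn
  eg[refs] <- 1
  eg
}

#' Simulate one subject
#'
#' @param config A [synth_config()].
#' @param group Group tag.
#' @param seed Integer seed for this subject's stream.
#' @param id Subject identifier.
#' @return List with raw `abeta`, `fdg`, `gm` [image_volume()]s, a one-row
#'   `record` data frame, and a `cognition` data frame of visits.
#' @export
simulate_subject <- function(config, group, seed, id = "s1") {
  if (!group %in% GROUP_TAGS) stop("invalid group: ", group)
  gp <- GROUP_PARAMS[[group]]
  atlas <- config$atlas
  rn <- unname(atlas$roi_names)
  refs <- synth_reference_rois(atlas)
  ana <- setdiff(rn, refs)
  ns <- config$noise_sd
  set.seed(seed)

  record <- data.frame(
    id = id, group = group,
    age = rnorm(1, gp$age[1], gp$age[2]),
    sex = rbinom(1, 1, gp$male),
    education = max(0, rnorm(1, gp$edu[1], gp$edu[2])),
    apoe4 = rbinom(1, 1, gp$apoe4),
    ptau = max(0, rnorm(1, gp$ptau[1], gp$ptau[2])),
    followup_years = max(1, rnorm(1, gp$fup[1], gp$fup[2])),
    stringsAsFactors = FALSE)
  z <- std_covariates(record)
  ce <- config$covariate_effects

  La <- roi_noise_chol(atlas, config$roi_cor$abeta)
  Lg <- roi_noise_chol(atlas, config$roi_cor$fdg)
  a <- setNames(rep(gp$abeta, length(rn)), rn)
  a[refs] <- 1
  a[ana] <- a[ana] + ns$roi_abeta * as.vector(rnorm(length(ana)) %*% La)
  a[refs] <- a[refs] + rnorm(length(refs), 0, ns$ref_roi)

  eff_fdg <- sum(ce$fdg[names(z)] * z, na.rm = TRUE)
  g <- config$fdg_b0 - config$gamma * as.vector(config$W %*% a) +
    config$delta * a + eff_fdg
  names(g) <- rn
  g[ana] <- g[ana] + ns$roi_fdg * as.vector(rnorm(length(ana)) %*% Lg)
  g[refs] <- 1 + rnorm(length(refs), 0, ns$ref_roi)

  gm <- setNames(rep(0.65 + gp$gm_shift, length(rn)), rn) +
    rnorm(length(rn), 0, ns$gm_roi)

  eg <- expected_fdg(config, group)
  dm <- config$interaction_rois %||%
    ana[atlas$network_of[ana] == "default_mode"]
  dm <- intersect(dm, ana)
  # both factors centred: the driver is a pure local synergy between
  # excess Abeta and hypometabolism, not a rescaled main effect
  x_int <- mean((a[dm] - gp$abeta) * (-(g[dm] - eg[dm])))
  b3 <- config$beta3[[group]]
  slope <- gp$slope0 + b3 * x_int +
    sum(ce$slope[names(z)] * z, na.rm = TRUE) + rnorm(1, 0, ns$slope)

  times <- seq(0, record$followup_years, length.out = config$n_visits)
  scores <- gp$mmse0[1] + rnorm(1, 0, gp$mmse0[2]) + slope * times +
    rnorm(length(times), 0, ns$visit)
  cognition <- data.frame(id = id, time_years = times, score = scores,
                          stringsAsFactors = FALSE)

  roi_idx <- config$roi_idx %||%
    lapply(seq_along(rn), function(i) which(atlas$labels$data == i))
  broadcast <- function(values, voxel_sd, scale = 1) {
    arr <- array(0, config$grid_shape)
    for (i in seq_along(rn))
      arr[roi_idx[[i]]] <- values[rn[i]]
    arr <- arr + rnorm(length(arr), 0, voxel_sd)
    arr <- smooth_array(arr, config$smoothing_fwhm_mm, config$voxel_size_mm)
    image_volume(arr * scale, config$voxel_size_mm, atlas$labels$affine)
  }
  sc_a <- exp(rnorm(1, 0, ns$scan_scale))
  sc_f <- exp(rnorm(1, 0, ns$scan_scale))
  ab <- broadcast(a, ns$voxel, sc_a); ab$modality <- "abeta"
  fd <- broadcast(g, ns$voxel, sc_f); fd$modality <- "fdg"
  gmv <- broadcast(gm, ns$gm_voxel); gmv$modality <- "gm_density"

  list(abeta = ab, fdg = fd, gm = gmv, record = record,
       cognition = cognition, roi_truth = list(abeta = a, fdg = g,
                                               interaction = x_int,
                                               slope = slope))
}

#' Simulate a multimodal cohort
#'
#' Applies [simulate_subject()] per subject with per-subject seeds derived
#' from `config$seed`, and returns a validated [cohort_dataset()] of raw
#' (pre-SUVR) volumes. A provenance record (full configuration and seed) is
#' attached as the `"provenance"` attribute.
#'
#' @param config A [synth_config()].
#' @return A [cohort_dataset()].
#' @export
simulate_cohort <- function(config) {
  groups <- rep(names(config$n_subjects), config$n_subjects)
  n <- length(groups)
  if (n == 0) stop("empty cohort requested")
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  ids <- sprintf("s%04d", seq_len(n))
  vols <- vector("list", n); names(vols) <- ids
  recs <- vector("list", n); cogs <- vector("list", n)
  for (i in seq_len(n)) {
    s <- simulate_subject(config, groups[i], seeds[i], ids[i])
    vols[[i]] <- list(abeta = s$abeta, fdg = s$fdg, gm_density = s$gm)
    recs[[i]] <- s$record
    cogs[[i]] <- s$cognition
  }
  subjects <- do.call(rbind, recs)
  cognition <- do.call(rbind, cogs)
  atlas <- config$atlas
  mask <- analysis_mask(atlas)
  cohort <- cohort_dataset(subjects, cognition, vols, mask, atlas)
  attr(cohort, "provenance") <- list(
    config = config[setdiff(names(config), c("atlas", "roi_idx"))],
    effects = list(gamma = config$gamma, delta = config$delta,
                   beta3 = config$beta3,
                   covariate_effects = config$covariate_effects),
    seed = config$seed)
  cohort
}

#' Null cohort for error-rate calibration
#'
#' Forces all generative effects to zero (`gamma = delta = 0`, all `beta3`
#' and covariate effects zero), giving an exchangeable null in which no
#' Abeta-metabolism or biomarker-cognition association exists.
#'
#' @param config A [synth_config()]; its effect fields are overridden.
#' @return A [cohort_dataset()].
#' @export
null_cohort <- function(config) {
  config$gamma <- 0
  config$delta <- 0
  config$beta3[] <- 0
  config$covariate_effects$fdg[] <- 0
  config$covariate_effects$slope[] <- 0
  simulate_cohort(config)
}
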