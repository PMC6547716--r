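# Shared fixtures: small synthetic cohorts cached across test files.

.amynet_test_cache <- new.env(parent = emptyenv())

cached_cohort <- function(key, maker) {
  if (!exists(key, envir = .amynet_test_cache))
    assign(key, maker(), envir = .amynet_test_cache)
  get(key, envir = .amynet_test_cache)
}

small_mci_cohort <- function() {
  cached_cohort("mci60", function() {
    cfg <- synth_config(n_subjects = c(CN_pos = 16, MCI_pos = 44), seed = 42)
    preprocess_cohort(simulate_cohort(cfg))
  })
}

null_small_cohort <- function() {
  cached_cohort("null40", function() {
    cfg <- synth_config(n_subjects = c(MCI_pos = 40), seed = 7)
    preprocess_cohort(null_cohort(cfg))
  })
}

dmn_rois <- function() {
  c("precuneus", "posterior_cingulate", "inferior_parietal",
    "lateral_temporal", "medial_prefrontal")
}

# A deliberately hand-built miniature cohort with fully controlled voxel
# values (no generator involved), for exact-identification tests.
toy_cohort <- function(n = 12, fdg_fun = function(ab) 2 * ab, seed = 5) {
  set.seed(seed)
  cfg <- synth_config(n_subjects = c(CN_pos = 1), seed = 1)
  atlas <- cfg$atlas
  d <- dim(atlas$labels$data)
  mask <- image_volume(array(as.numeric(atlas$labels$data != 0), d),
                       atlas$labels$voxel_size_mm, atlas$labels$affine)
  ids <- sprintf("t%02d", seq_len(n))
  vols <- list()
  for (id in ids) {
    ab <- array(rnorm(prod(d), 1.3, 0.2), d)
    fd <- fdg_fun(ab)
    gm <- array(runif(prod(d), 0.4, 0.8), d)
    vols[[id]] <- list(
      abeta = image_volume(ab, atlas$labels$voxel_size_mm,
                           atlas$labels$affine, "abeta"),
      fdg = image_volume(fd, atlas$labels$voxel_size_mm,
                         atlas$labels$affine, "fdg"),
      gm_density = image_volume(gm, atlas$labels$voxel_size_mm,
                                atlas$labels$affine, "gm_density"))
  }
  subjects <- data.frame(id = ids, group = "MCI_pos",
                         age = rnorm(n, 73, 6), sex = rbinom(n, 1, 0.5),
                         education = rnorm(n, 16, 2),
                         apoe4 = rbinom(n, 1, 0.5),
                         ptau = rnorm(n, 30, 8),
                         followup_years = runif(n, 2, 4))
  cognition <- do.call(rbind, lapply(ids, function(id)
    data.frame(id = id, time_years = 0:3,
               score = 29 - runif(1, 0, 1) * (0:3))))
  cohort_dataset(subjects, cognition, vols, mask, atlas)
}
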