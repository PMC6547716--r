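# Partial correlations, connectivity matrices, distance control, seed
# maps, and the network overlap decomposition.

test_that("region means: constants, single voxels, and mass conservation", {
  cfg <- synth_config(n_subjects = c(CN_neg = 1), seed = 1)
  atlas <- cfg$atlas
  const <- image_volume(array(2.5, dim(atlas$labels$data)),
                        atlas$labels$voxel_size_mm, atlas$labels$affine)
  m <- extract_roi_means(const, atlas)
  expect_true(all(m == 2.5))
  expect_error(extract_roi_means(const, atlas, "amygdala"), "missing ROI")
  # single-voxel region
  arr <- array(0L, c(4, 4, 4)); arr[2, 3, 1] <- 1L
  p1 <- parcellation(image_volume(arr, modality = "label"), c("1" = "spot"),
                     c(spot = "visual"))
  v <- image_volume(array(seq_len(64), c(4, 4, 4)))
  expect_equal(unname(extract_roi_means(v, p1)["spot"]), v$data[2, 3, 1])
  # size-weighted mean of region means equals the overall labelled mean
  set.seed(10)
  rnd <- image_volume(array(rnorm(prod(dim(atlas$labels$data))),
                            dim(atlas$labels$data)),
                      atlas$labels$voxel_size_mm, atlas$labels$affine)
  mm <- extract_roi_means(rnd, atlas)
  sizes <- table(atlas$labels$data[atlas$labels$data != 0])
  sizes <- sizes[as.character(seq_along(mm))]
  expect_equal(sum(mm * as.numeric(sizes)) / sum(sizes),
               mean(rnd$data[atlas$labels$data != 0]), tolerance = 1e-12)
})

test_that("partial correlation reduces to Pearson and matches its identity", {
  set.seed(11)
  x <- rnorm(50); y <- 0.4 * x + rnorm(50)
  pc <- partial_corr(x, y)
  ct <- cor.test(x, y)
  expect_equal(pc$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(pc$p, ct$p.value, tolerance = 1e-10)
  z <- rnorm(50)
  expect_equal(partial_corr(x, x, data.frame(z = z))$r, 1)
  expect_error(partial_corr(x, y, cbind(z, 2 * z)), "collinear")
  expect_error(partial_corr(x, rep(1, 50)), "zero residual")
})

test_that("controlling a common cause removes the correlation", {
  set.seed(12)
  z <- rnorm(1e4)
  x <- z + rnorm(1e4); y <- z + rnorm(1e4)
  expect_gt(abs(cor(x, y)), 0.4)
  expect_lt(abs(partial_corr(x, y, data.frame(z = z))$r), 0.03)
})

test_that("the metabolic matrix is symmetric with a strong DMN block", {
  co <- small_mci_cohort()
  mm <- metabolic_matrix(co, groups = "MCI_pos")
  expect_true(all(mm$r == t(mm$r)))
  expect_true(all(diag(mm$r) == 1))
  expect_true(all(mm$r >= -1 & mm$r <= 1))
  expect_equal(mm$correction$m_tests, 10 * 9 / 2)
  dm <- dmn_rois(); oth <- setdiff(mm$row_nodes, dm)
  rdm <- mm$r[dm, dm]
  expect_gt(mean(rdm[row(rdm) != col(rdm)]), mean(mm$r[dm, oth]))
  # subject order invariance
  co2 <- co
  ord <- rev(seq_len(nrow(co2$subjects)))
  co2$subjects <- co2$subjects[ord, ]
  mm2 <- metabolic_matrix(co2, groups = "MCI_pos")
  expect_equal(mm$r, mm2$r, tolerance = 1e-12)
})

test_that("the cross-modal matrix transposes under modality swap", {
  co <- small_mci_cohort()
  ab_fd <- cross_modal_matrix(co, groups = "MCI_pos")
  fd_ab <- cross_modal_matrix(co, groups = "MCI_pos",
                              row_modality = "fdg", col_modality = "abeta")
  expect_equal(ab_fd$r, t(fd_ab$r), tolerance = 1e-12)
  expect_false(ab_fd$symmetric)
  expect_equal(ab_fd$correction$m_tests, 100L)
  # region order permutes rows and columns consistently
  rois <- rev(amynet:::analysis_rois(co))
  perm <- cross_modal_matrix(co, roi_set = rois, groups = "MCI_pos")
  expect_equal(perm$r, ab_fd$r[rois, rois], tolerance = 1e-12)
})

test_that("element correlation handles identity, negation, and filters", {
  co <- small_mci_cohort()
  xm <- cross_modal_matrix(co, groups = "MCI_pos")
  expect_equal(element_correlation(xm, xm)$r, 1)
  neg <- xm; neg$r <- -xm$r
  expect_equal(element_correlation(xm, neg)$r, -1)
  mm <- metabolic_matrix(co, groups = "MCI_pos")
  # glucose coupling mediates the Abeta effect: elements anticorrelate
  expect_lt(element_correlation(xm, mm)$r, 0)
  expect_error(element_correlation(xm$r, xm$r[1:3, 1:3]), "conformable")
})

test_that("distance control flags distance-driven structure and only that", {
  co <- small_mci_cohort()
  cen <- co$parcellation$centroids_mm
  rois <- amynet:::analysis_rois(co)
  D <- as.matrix(dist(cen[rois, ]))
  fake <- list(row_nodes = rois, col_nodes = rois, r = exp(-D / 40),
               symmetric = TRUE)
  class(fake) <- "connectivity_matrix"
  dc <- distance_control(fake, cen)
  expect_lt(dc$r, -0.95)
  expect_error(distance_control(fake, cen[1:3, ]), "cover")
})

test_that("network overlap percentages tally voxels and sum to 100", {
  cfg <- synth_config(n_subjects = c(CN_neg = 1), seed = 1)
  atlas <- cfg$atlas
  labs <- atlas$labels$data
  # a mask entirely inside one default-mode region
  m1 <- array(FALSE, dim(labs)); m1[labs == 1] <- TRUE
  ov1 <- network_overlap(m1, atlas)
  expect_equal(unname(ov1["default_mode"]), 100)
  expect_true(all(ov1[setdiff(names(ov1), "default_mode")] == 0))
  # an even split between a default-mode and a limbic region
  i_dm <- which(labs == 1)[1:50]; i_lim <- which(labs == 6)[1:50]
  m2 <- array(FALSE, dim(labs)); m2[c(i_dm, i_lim)] <- TRUE
  ov2 <- network_overlap(m2, atlas)
  expect_equal(unname(ov2["default_mode"]), 50)
  expect_equal(unname(ov2["limbic"]), 50)
  # random masks match a brute-force voxel tally and always sum to 100
  set.seed(13)
  rn <- unname(atlas$roi_names)
  for (k in 1:10) {
    sel <- sample(which(labs != 0), sample(5:400, 1))
    m <- array(FALSE, dim(labs)); m[sel] <- TRUE
    ov <- network_overlap(m, atlas, digits = 1)
    nets <- atlas$network_of[rn][match(labs[sel], seq_along(rn))]
    brute <- table(factor(nets, levels = network_names()))
    expect_equal(unname(round(100 * as.numeric(brute) / length(sel), 1)),
                 unname(ov), tolerance = 0.11)
    expect_equal(sum(ov), 100, tolerance = 1e-12)
  }
  expect_error(network_overlap(array(FALSE, dim(labs)), atlas), "empty")
})

test_that("seed maps delegate exactly to the voxel engine", {
  co <- small_mci_cohort()
  sm <- seed_to_voxel_map(co, "precuneus", groups = "MCI_pos",
                          correction = "none")
  spec <- voxel_model_spec(outcome = "voxel_fdg",
                           global_terms = "roi:precuneus",
                           covariates = c("age", "sex", "education", "apoe4",
                                          "ptau", "gm_density"),
                           group_filter = "MCI_pos")
  direct <- fit_voxelwise(co, spec)
  expect_equal(sm$t[["roi:precuneus"]], direct$t[["roi:precuneus"]],
               tolerance = 1e-12)
})
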