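# The per-voxel GLM engine, FWER correction, interaction model,
# nested-model comparison, and bootstrap stability.

test_that("the engine equals an independent per-voxel lm() fit", {
  co <- small_mci_cohort()
  spec <- abeta_metabolism_spec(groups = "MCI_pos")
  map <- fit_voxelwise(co, spec)
  sub <- co$subjects[co$subjects$group == "MCI_pos", ]
  idx <- which(co$mask$data != 0)
  set.seed(8)
  for (v in sample(seq_along(idx), 40)) {
    df <- data.frame(
      y = vapply(sub$id, function(id)
        co$volumes[[id]]$fdg$data[idx[v]], numeric(1)),
      ab = vapply(sub$id, function(id)
        co$volumes[[id]]$abeta$data[idx[v]], numeric(1)),
      gm = vapply(sub$id, function(id)
        co$volumes[[id]]$gm_density$data[idx[v]], numeric(1)),
      ga = unname(co$global_abeta[sub$id]),
      age = sub$age, sex = sub$sex, edu = sub$education,
      apoe = sub$apoe4, ptau = sub$ptau)
    ref <- lm(y ~ ga + age + sex + edu + apoe + ptau + ab + gm, data = df)
    expect_equal(map$beta[["abeta"]][idx[v]], unname(coef(ref)["ab"]),
                 tolerance = 1e-8)
    expect_equal(map$beta[["global_abeta"]][idx[v]], unname(coef(ref)["ga"]),
                 tolerance = 1e-8)
    tref <- summary(ref)$coefficients
    expect_equal(map$t[["abeta"]][idx[v]], unname(tref["ab", "t value"]),
                 tolerance = 1e-8)
    expect_equal(map$p[["global_abeta"]][idx[v]],
                 unname(tref["ga", "Pr(>|t|)"]), tolerance = 1e-8)
  }
  expect_equal(map$df, nrow(sub) - 9)
})

test_that("a noiseless proportional cohort is identified exactly", {
  co <- toy_cohort(fdg_fun = function(ab) 2 * ab)
  spec <- voxel_model_spec(outcome = "voxel_fdg", voxel_terms = "abeta")
  map <- fit_voxelwise(co, spec)
  idx <- which(co$mask$data != 0)
  expect_lt(max(abs(map$beta[["abeta"]][idx] - 2)), 1e-8)
  expect_lt(max(abs(map$beta[["(Intercept)"]][idx])), 1e-8)
})

test_that("a constant covariate is reported by name", {
  co <- preprocess_cohort(toy_cohort())
  co$subjects$education <- 16
  spec <- abeta_metabolism_spec()
  expect_error(fit_voxelwise(co, spec), "education")
})

test_that("spec validation rejects duplicates and orphan interactions", {
  expect_error(voxel_model_spec(voxel_terms = c("abeta", "abeta")),
               "duplicate")
  expect_error(voxel_model_spec(voxel_terms = "abeta",
                                interaction_pairs = list(c("abeta", "fdg"))),
               "declared voxel terms")
})

test_that("Bonferroni thresholding follows the direct arithmetic", {
  co <- small_mci_cohort()
  map <- fit_voxelwise(co, abeta_metabolism_spec(groups = "MCI_pos"))
  mb <- fwer_correct(map, "global_abeta", method = "bonferroni",
                     alpha = 0.05)
  V <- sum(map$evaluated)
  pv <- map$p[["global_abeta"]][map$mask_idx]
  expect_identical(mb$suprathreshold[map$mask_idx], pv * V <= 0.05)
  # degenerate alpha = 1 keeps every evaluated voxel
  m1 <- fwer_correct(map, "global_abeta", method = "bonferroni", alpha = 1)
  expect_equal(sum(m1$suprathreshold, na.rm = TRUE), V)
  expect_error(fwer_correct(map, "global_abeta", n_perm = 50), "unstable")
  expect_error(fwer_correct(map, "nope"), "unknown term")
})

test_that("permutation correction is deterministic given its seed", {
  co <- null_small_cohort()
  map <- fit_voxelwise(co, abeta_metabolism_spec())
  a <- fwer_correct(map, "global_abeta", n_perm = 120, seed = 5)
  b <- fwer_correct(map, "global_abeta", n_perm = 120, seed = 5)
  expect_identical(a$p_fwer, b$p_fwer)
  expect_identical(a$suprathreshold, b$suprathreshold)
  expect_equal(a$correction$n_perm, 120)
})

test_that("the interaction product term is symmetric in its parents", {
  co <- small_mci_cohort()
  m1 <- fit_interaction_model(co, groups = "MCI_pos")
  m2 <- fit_interaction_model(co, groups = "MCI_pos",
                              abeta_modality = "fdg", fdg_modality = "abeta")
  expect_equal(m1$beta[["abeta:fdg"]], m2$beta[["fdg:abeta"]],
               tolerance = 1e-10)
})

test_that("nested-model comparison: identical models give F = 0, p = 1", {
  co <- small_mci_cohort()
  spec <- abeta_metabolism_spec(groups = "MCI_pos")
  cmp <- compare_models(co, spec, list(same = spec))
  idx <- which(co$mask$data != 0)
  expect_true(all(cmp$same$F[idx] == 0))
  expect_true(all(cmp$same$p[idx] == 1))
  expect_error(compare_models(co, spec,
                              list(bad = voxel_model_spec(
                                outcome = "voxel_fdg",
                                voxel_terms = "gm_density"))),
               "not nested")
})

test_that("with a true interaction the full model is strongly preferred", {
  cfg <- synth_config(n_subjects = c(MCI_pos = 100), seed = 13)
  co <- preprocess_cohort(simulate_cohort(cfg))
  full <- voxel_model_spec(outcome = "cognitive_slope",
                           voxel_terms = c("abeta", "fdg"),
                           interaction_pairs = list(c("abeta", "fdg")),
                           covariates = c("global_abeta", "age", "sex",
                                          "education", "apoe4", "ptau",
                                          "gm_density", "followup_years"),
                           group_filter = "MCI_pos")
  reduced <- list(
    abeta_only = voxel_model_spec(outcome = "cognitive_slope",
                                  voxel_terms = "abeta",
                                  covariates = full$covariates,
                                  group_filter = "MCI_pos"),
    fdg_only = voxel_model_spec(outcome = "cognitive_slope",
                                voxel_terms = "fdg",
                                covariates = full$covariates,
                                group_filter = "MCI_pos"),
    both_main = voxel_model_spec(outcome = "cognitive_slope",
                                 voxel_terms = c("abeta", "fdg"),
                                 covariates = full$covariates,
                                 group_filter = "MCI_pos"))
  cmp <- compare_models(co, full, reduced)
  dmn_idx <- amynet:::in_network_voxels(co$parcellation, "default_mode")
  for (nm in names(cmp)) {
    expect_lt(min(cmp[[nm]]$p[dmn_idx], na.rm = TRUE), 1e-4)
    expect_gt(cmp[[nm]]$frac_dmn_preferring_full, 0.2)
  }
})

test_that("bootstrap stability: orthogonal competing term leaves the SD alone", {
  cfg <- synth_config(n_subjects = c(MCI_pos = 80), seed = 3)
  co <- preprocess_cohort(simulate_cohort(cfg))
  # insula Abeta is independent of the composite regions by construction
  b <- bootstrap_stability(co, roi = "posterior_cingulate",
                           competing_term = "roi:insula",
                           n_reps = 2000, seed = 9)
  expect_gt(b$sd_ratio, 0.9)
  expect_lt(b$sd_ratio, 1.1)
  b2 <- bootstrap_stability(co, roi = "posterior_cingulate",
                            competing_term = "roi:insula",
                            n_reps = 2000, seed = 9)
  expect_identical(b$estimates_with, b2$estimates_with)
  b1 <- bootstrap_stability(co, n_reps = 1, seed = 1)
  expect_true(is.na(b1$sd_with) && is.na(b1$sd_without))
  expect_error(bootstrap_stability(co, n_reps = 0), ">= 1")
})
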