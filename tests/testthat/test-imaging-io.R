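# NIfTI round trips, volume validation, parcellation geometry, and cohort
# assembly.

test_that("write/read round trip is bit-exact and keeps the affine", {
  set.seed(1)
  aff <- diag(c(2, 2, 2, 1)); aff[1:3, 4] <- c(-10, 4, 7)
  vol <- image_volume(array(rnorm(8^3), c(8, 8, 8)),
                      voxel_size_mm = c(2, 2, 2), affine = aff,
                      modality = "fdg")
  path <- tempfile(fileext = ".nii.gz")
  write_volume(vol, path)
  back <- read_volume(path, modality = "fdg")
  expect_identical(back$data, vol$data)
  expect_lt(max(abs(back$affine - vol$affine)), 1e-6)
  expect_equal(back$voxel_size_mm, c(2, 2, 2), tolerance = 1e-6)
})

test_that("label volumes preserve integer codes through I/O", {
  set.seed(2)
  lab <- image_volume(array(sample(0:9, 6^3, TRUE), c(6, 6, 6)),
                      modality = "label")
  path <- tempfile(fileext = ".nii.gz")
  write_volume(lab, path)
  back <- read_volume(path, modality = "label")
  expect_true(all(back$data == lab$data))
})

test_that("a 4-D file is rejected with its dimensionality named", {
  path <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(4, 4, 4, 2))), path)
  expect_error(read_volume(path), "4")
  expect_error(read_volume(tempfile(fileext = ".nii")), "not found")
})

test_that("non-finite voxels inside the mask are rejected with a count", {
  arr <- array(1, c(4, 4, 4)); arr[1:3] <- NA
  path <- tempfile(fileext = ".nii.gz")
  write_volume(image_volume(arr), path)
  mask <- array(TRUE, c(4, 4, 4))
  expect_error(read_volume(path, mask = mask), "3 non-finite")
})

test_that("volume invariants are enforced", {
  expect_error(image_volume(matrix(1, 2, 2)), "3-D")
  expect_error(image_volume(array(1, c(2, 2, 2)), voxel_size_mm = c(1, 0, 1)),
               "positive")
  expect_error(image_volume(array(-1, c(2, 2, 2)), modality = "label"),
               "non-negative integers")
  expect_error(image_volume(array(0.5, c(2, 2, 2)), modality = "label"),
               "integers")
})

test_that("centroids apply the affine to 0-based indices", {
  arr <- array(0L, c(4, 4, 4))
  arr[2, 2, 2] <- 1L  # 0-based index (1,1,1)
  lab <- image_volume(arr, voxel_size_mm = c(2, 2, 2),
                      affine = diag(c(2, 2, 2, 1)), modality = "label")
  cen <- label_centroids(lab)
  expect_equal(unname(cen["1", ]), c(2, 2, 2))
  # recomputable from the parcellation constructor
  p <- parcellation(lab, c("1" = "precuneus"),
                    c(precuneus = "default_mode"))
  expect_equal(unname(p$centroids_mm["precuneus", ]), c(2, 2, 2))
})

test_that("parcellation validates names and network vocabulary", {
  arr <- array(0L, c(4, 4, 4)); arr[1:8] <- 1L; arr[9:16] <- 2L
  lab <- image_volume(arr, modality = "label")
  expect_error(parcellation(lab, c("1" = "a"), c(a = "default_mode")),
               "unnamed label")
  expect_error(parcellation(lab, c("1" = "a", "2" = "b"),
                            c(a = "default_mode", b = "cortex")),
               "network_names")
})

write_toy_subject <- function(dir, id, mods = c("abeta", "fdg", "gm_density"),
                              voxel = c(2, 2, 2)) {
  rows <- NULL
  for (m in mods) {
    v <- image_volume(array(rnorm(4^3, 10), c(4, 4, 4)),
                      voxel_size_mm = voxel, modality = m)
    path <- file.path(dir, sprintf("%s_%s.nii.gz", id, m))
    write_volume(v, path)
    rows <- rbind(rows, data.frame(id = id, modality = m, path = path))
  }
  rows
}

toy_parcellation <- function(voxel = c(2, 2, 2)) {
  arr <- array(0L, c(4, 4, 4)); arr[1:8] <- 1L
  parcellation(image_volume(arr, voxel_size_mm = voxel, modality = "label"),
               c("1" = "precuneus"), c(precuneus = "default_mode"))
}

test_that("assemble_cohort validates, excludes incomplete subjects, sorts ids", {
  dir <- tempfile(); dir.create(dir)
  set.seed(3)
  man <- rbind(write_toy_subject(dir, "s2"), write_toy_subject(dir, "s1"),
               write_toy_subject(dir, "s3", mods = c("abeta", "gm_density")))
  cov <- data.frame(id = c("s1", "s2", "s3"), group = "CN_neg", age = 70,
                    sex = 0, education = 16, apoe4 = 0, ptau = 20,
                    followup_years = 3)
  expect_warning(co <- assemble_cohort(man, cov, toy_parcellation()),
                 "s3")
  expect_equal(co$subjects$id, c("s1", "s2"))  # sorted, s3 dropped
  # manifest row order does not matter
  suppressWarnings({
    co2 <- assemble_cohort(man[sample(nrow(man)), ], cov, toy_parcellation())
  })
  expect_identical(co$subjects, co2$subjects)

  expect_error(assemble_cohort(man[1:6, ], rbind(cov, cov[1, ]),
                               toy_parcellation()), "duplicate")
  badcov <- cov; badcov$group[1] <- "patient"
  expect_error(assemble_cohort(man[1:6, ], badcov, toy_parcellation()),
               "group")
})

test_that("grid mismatches across subjects are rejected", {
  dir <- tempfile(); dir.create(dir)
  man <- rbind(write_toy_subject(dir, "s1"),
               write_toy_subject(dir, "s2", voxel = c(3, 3, 3)))
  cov <- data.frame(id = c("s1", "s2"), group = "CN_neg", age = 70, sex = 0,
                    education = 16, apoe4 = 0, ptau = 20, followup_years = 3)
  expect_error(assemble_cohort(man, cov, toy_parcellation()), "mismatch")
})

test_that("cognitive visit times must strictly increase", {
  co <- toy_cohort(n = 4)
  co$cognition$time_years[2] <- 0  # duplicate baseline for subject 1
  expect_error(validate_cohort(co), "strictly increasing")
})
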