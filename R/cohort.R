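# Cohort assembly and validation: aligned multi-subject, multi-modality
# volumes + mask + parcellation + covariates + longitudinal cognition.

GROUP_TAGS <- c("CN_neg", "CN_pos", "MCI_pos", "tg_rat", "wt_rat")
REQUIRED_MODALITIES <- c("abeta", "fdg", "gm_density")
COVARIATE_COLUMNS <- c("age", "sex", "education", "apoe4", "ptau")

#' Construct a cohort dataset
#'
#' @param subjects Data frame with columns `id`, `group` (one of CN_neg,
#'   CN_pos, MCI_pos, tg_rat, wt_rat), `age`, `sex` (0/1), `education`,
#'   `apoe4` (0/1 carrier), `ptau`, `followup_years`.
#' @param cognition Long data frame with columns `id`, `time_years`, `score`
#'   (times strictly increasing within subject).
#' @param volumes Named list (by subject id) of named lists (by modality) of
#'   [image_volume()] objects; every subject needs every modality in
#'   `c("abeta", "fdg", "gm_density")`.
#' @param mask Binary [image_volume()] on the shared grid; statistics are
#'   computed only where the mask is 1.
#' @param parcellation A [parcellation()] on the shared grid.
#' @param global_abeta Optional named numeric of per-subject global Abeta
#'   composites (filled by [preprocess_cohort()]).
#' @return Object of class `cohort_dataset`.
#' @export
cohort_dataset <- function(subjects, cognition, volumes, mask, parcellation,
                           global_abeta = NULL) {
  x <- structure(list(subjects = subjects, cognition = cognition,
                      volumes = volumes, mask = mask,
                      parcellation = parcellation,
                      global_abeta = global_abeta),
                 class = "cohort_dataset")
  validate_cohort(x)
  x
}

#' Validate a cohort dataset
#'
#' Checks the invariants: shared grid across all volumes and the mask, all
#' required modalities per subject, unique ids, known group tags, strictly
#' increasing cognitive visit times.
#'
#' @param cohort A `cohort_dataset`.
#' @return The cohort, invisibly; errors on violation.
#' @export
validate_cohort <- function(cohort) {
  s <- cohort$subjects
  need <- c("id", "group", COVARIATE_COLUMNS, "followup_years")
  if (!all(need %in% names(s)))
    stop("subject table missing column(s): ",
         paste(setdiff(need, names(s)), collapse = ", "))
  if (anyDuplicated(s$id)) stop("duplicate subject ids")
  if (!all(s$group %in% GROUP_TAGS))
    stop("unknown group tag(s): ",
         paste(unique(setdiff(s$group, GROUP_TAGS)), collapse = ", "))
  if (!setequal(names(cohort$volumes), s$id))
    stop("volume list and subject table disagree on subject ids")
  ref <- cohort$mask
  stopifnot(is_image_volume(ref))
  if (!grids_match(ref, cohort$parcellation$labels))
    stop("parcellation grid does not match the mask grid")
  for (id in s$id) {
    mods <- names(cohort$volumes[[id]])
    miss <- setdiff(REQUIRED_MODALITIES, mods)
    if (length(miss))
      stop("subject ", id, " missing modality: ", paste(miss, collapse = ", "))
    for (m in REQUIRED_MODALITIES) {
      if (!grids_match(ref, cohort$volumes[[id]][[m]]))
        stop("grid mismatch for subject ", id, ", modality ", m)
    }
  }
  cg <- cohort$cognition
  if (!is.null(cg) && nrow(cg)) {
    stopifnot(all(c("id", "time_years", "score") %in% names(cg)))
    for (id in unique(cg$id)) {
      tt <- cg$time_years[cg$id == id]
      if (length(tt) && any(diff(tt) <= 0))
        stop("cognitive times not strictly increasing for subject ", id)
    }
  }
  invisible(cohort)
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("<cohort_dataset> %d subjects (%s), %d regions, mask %d voxels\n",
              nrow(x$subjects),
              paste(sprintf("%s=%d", names(table(x$subjects$group)),
                            table(x$subjects$group)), collapse = ", "),
              length(x$parcellation$roi_names),
              sum(x$mask$data != 0)))
  invisible(x)
}

#' Assemble a validated cohort from files
#'
#' Reads volumes listed in a manifest, joins the covariate table and
#' longitudinal cognition, and validates the result. Subjects missing any
#' required modality are excluded with a warning (only subjects with the
#' complete multimodal set are analyzable).
#'
#' @param volume_manifest Data frame (or CSV path) with columns `id`,
#'   `modality`, `path`.
#' @param covariates Data frame (or CSV path) with one row per subject (see
#'   [cohort_dataset()]).
#' @param parcellation A [parcellation()].
#' @param cognition Optional long data frame (or CSV path) with `id`,
#'   `time_years`, `score`.
#' @param mask Optional binary [image_volume()]; defaults to the labelled
#'   voxels of the parcellation.
#' @return A [cohort_dataset()], subjects sorted by id.
#' @export
assemble_cohort <- function(volume_manifest, covariates, parcellation,
                            cognition = NULL, mask = NULL) {
  if (is.character(volume_manifest))
    volume_manifest <- read.csv(volume_manifest, stringsAsFactors = FALSE)
  if (is.character(covariates))
    covariates <- read.csv(covariates, stringsAsFactors = FALSE)
  if (is.character(cognition))
    cognition <- read.csv(cognition, stringsAsFactors = FALSE)
  covariates$id <- as.character(covariates$id)
  if (anyDuplicated(covariates$id)) stop("duplicate subject ids in covariates")
  volume_manifest$id <- as.character(volume_manifest$id)

  vols <- list()
  for (id in unique(volume_manifest$id)) {
    rows <- volume_manifest[volume_manifest$id == id, , drop = FALSE]
    vols[[id]] <- setNames(
      lapply(seq_len(nrow(rows)),
             function(i) read_volume(rows$path[i], modality = rows$modality[i])),
      rows$modality)
  }
  complete <- vapply(vols, function(v)
    all(REQUIRED_MODALITIES %in% names(v)), logical(1))
  if (any(!complete)) {
    warning("excluding subject(s) without all modalities: ",
            paste(names(vols)[!complete], collapse = ", "))
    vols <- vols[complete]
  }
  keep <- intersect(covariates$id, names(vols))
  keep <- sort(keep)
  if (!length(keep)) stop("no subject has all required modalities")
  subjects <- covariates[match(keep, covariates$id), , drop = FALSE]
  rownames(subjects) <- NULL
  if (is.null(mask)) mask <- analysis_mask(parcellation)
  if (!is.null(cognition)) {
    cognition$id <- as.character(cognition$id)
    cognition <- cognition[cognition$id %in% keep, , drop = FALSE]
    cognition <- cognition[order(cognition$id, cognition$time_years), ,
                           drop = FALSE]
  }
  cohort_dataset(subjects, cognition, vols[keep], mask, parcellation)
}

#' Subject-level matrix of masked voxel values
#'
#' @param cohort A [cohort_dataset()].
#' @param modality Modality to extract.
#' @param mask_idx Optional integer indices into the flattened grid;
#'   defaults to all in-mask voxels.
#' @return n_subjects x n_voxels numeric matrix (rows in subject-id order).
#' @export
voxel_matrix <- function(cohort, modality, mask_idx = NULL) {
  if (is.null(mask_idx)) mask_idx <- which(cohort$mask$data != 0)
  ids <- cohort$subjects$id
  out <- matrix(NA_real_, length(ids), length(mask_idx))
  for (i in seq_along(ids))
    out[i, ] <- cohort$volumes[[ids[i]]][[modality]]$data[mask_idx]
  rownames(out) <- ids
  out
}
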