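# Orchestration: a single YAML/JSON configuration drives simulate ->
# preprocess -> voxelwise -> connectivity -> interaction -> sem, with a
# provenance report of seeds, settings, and the statistics each stage
# produced.

default_run_config <- function() {
  list(seed = 1L,
       out_dir = "amynet_run",
       stages = list(simulate = TRUE, preprocess = TRUE, voxelwise = TRUE,
                     connectivity = TRUE, interaction = TRUE, sem = TRUE),
       synthetic = list(),
       correction = list(method = "permutation_maxT", alpha = 0.05,
                         n_perm = 500),
       analysis_group = NULL,
       seed_rois = list("precuneus"),
       write_volumes = FALSE)
}

read_run_config <- function(path) {
  if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

#' Validate a pipeline configuration
#'
#' @param config A configuration list or a path to a YAML/JSON file.
#' @return Character vector of problems; empty if the configuration is
#'   valid.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  errs <- character()
  if (is.null(config$seed) || !is.finite(as.numeric(config$seed)))
    errs <- c(errs, "missing or non-numeric 'seed'")
  corr <- config$correction
  if (!is.null(corr)) {
    if (!is.null(corr$alpha) &&
        (corr$alpha <= 0 || corr$alpha > 1))
      errs <- c(errs, "correction alpha must lie in (0, 1]")
    if (!is.null(corr$method) &&
        !corr$method %in% c("permutation_maxT", "bonferroni"))
      errs <- c(errs, paste0("unknown correction method: ", corr$method))
    if (identical(corr$method, "permutation_maxT") &&
        !is.null(corr$n_perm) && corr$n_perm < 100)
      errs <- c(errs, "n_perm must be >= 100 for permutation correction")
  }
  if (!is.null(config$stages) &&
      !all(vapply(config$stages, is.logical, logical(1))))
    errs <- c(errs, "stage toggles must be logical")
  errs
}

merge_config <- function(user) {
  base <- default_run_config()
  for (nm in names(user)) {
    if (nm %in% c("stages", "correction", "synthetic") && is.list(user[[nm]])) {
      for (k in names(user[[nm]])) base[[nm]][[k]] <- user[[nm]][[k]]
    } else base[[nm]] <- user[[nm]]
  }
  base
}

#' Write a cohort's files to a directory
#'
#' Emits per-subject NIfTI volumes (raw modalities), the parcellation label
#' volume and metadata JSON, `covariates.csv`, `cognition.csv`, a volume
#' manifest, and `provenance.json`.
#'
#' @param cohort A [cohort_dataset()].
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- NULL
  for (id in cohort$subjects$id) {
    for (m in REQUIRED_MODALITIES) {
      path <- file.path(dir, sprintf("%s_%s.nii.gz", id, m))
      write_volume(cohort$volumes[[id]][[m]], path)
      manifest <- rbind(manifest,
                        data.frame(id = id, modality = m, path = path))
    }
  }
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  write.csv(cohort$subjects, file.path(dir, "covariates.csv"),
            row.names = FALSE)
  if (!is.null(cohort$cognition))
    write.csv(cohort$cognition, file.path(dir, "cognition.csv"),
              row.names = FALSE)
  p <- cohort$parcellation
  write_volume(p$labels, file.path(dir, "parcellation.nii.gz"))
  jsonlite::write_json(
    list(roi_names = as.list(p$roi_names),
         network_of = as.list(p$network_of),
         centroids_mm = p$centroids_mm),
    file.path(dir, "parcellation.json"), auto_unbox = TRUE, digits = NA)
  prov <- attr(cohort, "provenance")
  if (!is.null(prov))
    jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}

#' Run the full analysis pipeline from a configuration
#'
#' Stages run in dependency order; toggled-off stages are skipped and
#' absent from the report. All randomness derives from `config$seed`, so
#' two runs from one configuration produce identical numeric outputs.
#'
#' @param config Configuration list or path to a YAML/JSON file (see the
#'   package vignette; unspecified fields take documented defaults).
#' @return The run report (also written as `report.json` in the output
#'   directory), invisibly.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- read_run_config(config)
  errs <- validate_config(config)
  if (length(errs)) stop("invalid config: ", paste(errs, collapse = "; "))
  cfg <- merge_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(config = cfg, stages = list())
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  syn <- cfg$synthetic
  if (!is.null(syn$n_subjects)) syn$n_subjects <- unlist(syn$n_subjects)
  if (!is.null(syn$beta3)) syn$beta3 <- unlist(syn$beta3)
  syn$seed <- cfg$seed
  scfg <- do.call(synth_config, syn)

  cohort <- NULL
  if (isTRUE(cfg$stages$simulate)) {
    cohort <- run_stage("simulate", function() simulate_cohort(scfg))
    if (isTRUE(cfg$write_volumes))
      write_cohort(cohort, file.path(cfg$out_dir, "cohort"))
    report$stages$simulate <- list(
      n_subjects = nrow(cohort$subjects),
      groups = as.list(table(cohort$subjects$group)), seed = cfg$seed)
  }
  if (isTRUE(cfg$stages$preprocess)) {
    if (is.null(cohort)) stop("preprocess requires the simulate stage")
    cohort <- run_stage("preprocess", function() preprocess_cohort(cohort))
    write.csv(data.frame(id = names(cohort$global_abeta),
                         global_abeta = unname(cohort$global_abeta)),
              file.path(cfg$out_dir, "global_abeta.csv"), row.names = FALSE)
    write.csv(cohort$subjects[, c("id", "slope", "n_visits",
                                  "amyloid_positive")],
              file.path(cfg$out_dir, "slopes.csv"), row.names = FALSE)
    report$stages$preprocess <- list(
      mean_global_abeta = mean(cohort$global_abeta),
      n_amyloid_positive = sum(cohort$subjects$amyloid_positive))
  }

  groups_present <- unique(cohort$subjects$group)
  grp <- cfg$analysis_group %||%
    intersect(c("MCI_pos", "tg_rat"), groups_present)[1]
  if (is.na(grp)) grp <- NULL
  corr <- cfg$correction

  if (isTRUE(cfg$stages$voxelwise)) {
    report$stages$voxelwise <- run_stage("voxelwise", function() {
      map <- fit_voxelwise(cohort, abeta_metabolism_spec(groups = grp))
      map <- fwer_correct(map, "global_abeta", method = corr$method,
                          alpha = corr$alpha, n_perm = corr$n_perm,
                          seed = cfg$seed + 1L)
      list(group = grp, term = "global_abeta",
           n_suprathreshold = sum(map$suprathreshold, na.rm = TRUE),
           n_not_evaluated = map$n_not_evaluated,
           correction = map$correction)
    })
  }
  if (isTRUE(cfg$stages$connectivity)) {
    report$stages$connectivity <- run_stage("connectivity", function() {
      mm <- metabolic_matrix(cohort, groups = grp)
      xm <- cross_modal_matrix(cohort, groups = grp)
      write.csv(mm$r, file.path(cfg$out_dir, "metabolic_r.csv"))
      write.csv(xm$r, file.path(cfg$out_dir, "crossmodal_r.csv"))
      write.csv(xm$p, file.path(cfg$out_dir, "crossmodal_p.csv"))
      ec <- element_correlation(xm, mm)
      dc <- distance_control(xm, cohort$parcellation$centroids_mm)
      overlaps <- list()
      for (seed_roi in unlist(cfg$seed_rois)) {
        sm <- seed_to_voxel_map(cohort, seed_roi, groups = grp,
                                correction = corr$method,
                                alpha = corr$alpha, n_perm = corr$n_perm,
                                seed = cfg$seed + 2L)
        overlaps[[seed_roi]] <-
          if (any(sm$suprathreshold, na.rm = TRUE))
            as.list(network_overlap(sm, cohort$parcellation))
          else "empty mask"
      }
      list(element_correlation = ec, distance_control = dc,
           network_overlap = overlaps)
    })
  }
  if (isTRUE(cfg$stages$interaction)) {
    report$stages$interaction <- run_stage("interaction", function() {
      imap <- fit_interaction_model(cohort, groups = grp)
      imap <- fwer_correct(imap, "abeta:fdg", method = corr$method,
                           alpha = corr$alpha, n_perm = corr$n_perm,
                           seed = cfg$seed + 3L)
      list(group = grp,
           n_suprathreshold = sum(imap$suprathreshold, na.rm = TRUE),
           n_not_evaluated = imap$n_not_evaluated)
    })
  }
  if (isTRUE(cfg$stages$sem)) {
    report$stages$sem <- run_stage("sem", function() {
      tab <- build_design_table(cohort,
                                groups = intersect(c("CN_pos", "MCI_pos",
                                                     "tg_rat", "wt_rat"),
                                                   groups_present))
      fit <- fit_sem(sem_default_model(), tab)
      write.csv(data.frame(path = names(fit$estimates),
                           estimate = unname(fit$estimates)),
                file.path(cfg$out_dir, "sem_estimates.csv"),
                row.names = FALSE)
      out <- list(n = fit$n, chi_square = fit$chi_square, df = fit$df,
                  cfi = fit$cfi, srmr = fit$srmr,
                  satisfactory = classify_fit(fit))
      jsonlite::write_json(out, file.path(cfg$out_dir, "sem_fit.json"),
                           auto_unbox = TRUE, digits = NA)
      out
    })
  }
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}
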