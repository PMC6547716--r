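# 3-D image volumes, parcellations, and NIfTI-1 I/O.
#
# Conventions: voxel indices are 0-based when mapped through the affine;
# world coordinates are millimetres; the affine is the standard 4x4
# voxel-to-world map (NIfTI sform).

MODALITIES <- c("abeta", "fdg", "gm_density", "label")

#' Construct an in-memory image volume
#'
#' @param data 3-D numeric array.
#' @param voxel_size_mm Length-3 positive voxel dimensions in mm.
#' @param affine 4x4 voxel(0-based)-to-world-mm matrix. Defaults to a
#'   diagonal scaling by `voxel_size_mm`.
#' @param modality One of `"abeta"`, `"fdg"`, `"gm_density"`, `"label"`.
#'   Label volumes must hold non-negative integers.
#' @return An object of class `image_volume` with fields `data`,
#'   `voxel_size_mm`, `affine`, `modality`.
#' @export
image_volume <- function(data, voxel_size_mm = c(1, 1, 1), affine = NULL,
                         modality = "fdg") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3-D array, got dimensionality ",
         if (is.array(data)) length(dim(data)) else 0L)
  if (any(dim(data) < 1L)) stop("all image dimensions must be >= 1")
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0))
    stop("'voxel_size_mm' must be three positive reals")
  if (is.null(affine)) {
    affine <- diag(c(voxel_size_mm, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("'affine' must be a 4x4 matrix")
  modality <- match.arg(modality, MODALITIES)
  if (modality == "label") {
    v <- data[is.finite(data)]
    if (any(v < 0) || any(v != round(v)))
      stop("label volumes must contain only non-negative integers")
    storage.mode(data) <- "integer"
  }
  structure(list(data = data, voxel_size_mm = voxel_size_mm,
                 affine = affine, modality = modality),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s  %s voxels  %.3g x %.3g x %.3g mm\n",
              x$modality, paste(dim(x$data), collapse = "x"),
              x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3]))
  invisible(x)
}

is_image_volume <- function(x) inherits(x, "image_volume")

#' Read a 3-D NIfTI-1 volume
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param modality Modality tag to attach (see [image_volume()]).
#' @param mask Optional logical array; if supplied, non-finite voxels inside
#'   the mask cause a rejection with a diagnostic count.
#' @return An [image_volume()].
#' @export
read_volume <- function(path, modality = "fdg", mask = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop("expected a 3-D image, got dimensionality ", length(dim(arr)),
         " in ", path)
  aff <- tryCatch(unclass(RNifti::xform(img)), error = function(e) NULL)
  if (is.null(aff) || all(aff == 0)) aff <- diag(4)
  attributes(aff) <- list(dim = c(4L, 4L))
  vox <- sqrt(colSums(aff[1:3, 1:3]^2))
  if (any(vox <= 0)) vox <- abs(RNifti::pixdim(img))[1:3]
  if (!is.null(mask)) {
    bad <- sum(!is.finite(arr[mask]))
    if (bad > 0)
      stop(bad, " non-finite voxel(s) inside the mask in ", path)
  }
  arr2 <- arr
  attributes(arr2) <- list(dim = dim(arr))
  image_volume(arr2, voxel_size_mm = vox, affine = aff, modality = modality)
}

#' Write a volume as NIfTI-1
#'
#' Inverse of [read_volume()]: the affine is stored as the sform and the
#' voxel sizes in pixdim. Label volumes are written with an integer datatype
#' so that codes round-trip exactly.
#'
#' @param vol An [image_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(is_image_volume(vol))
  dat <- vol$data
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- vol$voxel_size_mm
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  dtype <- if (vol$modality == "label") "int32" else "double"
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

#' Map 0-based voxel indices to world mm
#' @noRd
voxel_to_world <- function(idx0, affine) {
  idx0 <- rbind(t(idx0), 1)
  t(affine %*% idx0)[, 1:3, drop = FALSE]
}

#' Construct a parcellation
#'
#' A parcellation couples a label volume with region names, a seven-network
#' assignment, and world-space centroids.
#'
#' @param labels An [image_volume()] with `modality = "label"`.
#' @param roi_names Named character vector mapping label codes (names) to
#'   region names. Every nonzero code present in the volume must be named.
#' @param network_of Named character vector mapping region names to one of
#'   [network_names()].
#' @param centroids_mm Optional matrix (regions x 3) of world centroids; if
#'   `NULL`, computed as the mean world coordinate of each label's voxels.
#' @return An object of class `parcellation`.
#' @export
parcellation <- function(labels, roi_names, network_of, centroids_mm = NULL) {
  stopifnot(is_image_volume(labels), labels$modality == "label")
  codes <- sort(unique(as.vector(labels$data)))
  codes <- codes[codes != 0L]
  if (!all(as.character(codes) %in% names(roi_names)))
    stop("unnamed label code(s): ",
         paste(setdiff(as.character(codes), names(roi_names)), collapse = ", "))
  rn <- unname(roi_names[as.character(codes)])
  if (anyDuplicated(rn)) stop("duplicate region names")
  if (!all(rn %in% names(network_of)))
    stop("region(s) without network assignment: ",
         paste(setdiff(rn, names(network_of)), collapse = ", "))
  if (!all(network_of[rn] %in% network_names()))
    stop("network names must come from network_names()")
  if (is.null(centroids_mm))
    centroids_mm <- label_centroids(
      labels, setNames(rn, as.character(codes)))[rn, , drop = FALSE]
  structure(list(labels = labels,
                 roi_names = setNames(rn, as.character(codes)),
                 network_of = network_of[rn],
                 centroids_mm = centroids_mm),
            class = "parcellation")
}

#' Compute label centroids in world mm
#'
#' Mean world coordinate (through the affine, 0-based indices) of each
#' nonzero label's voxels.
#'
#' @param labels A label [image_volume()].
#' @param roi_names Optional named character vector (code -> name) used to
#'   name the rows.
#' @return Matrix with one row per label and columns x, y, z (mm).
#' @export
label_centroids <- function(labels, roi_names = NULL) {
  arr <- labels$data
  codes <- sort(unique(as.vector(arr)))
  codes <- codes[codes != 0L]
  out <- matrix(NA_real_, length(codes), 3,
                dimnames = list(as.character(codes), c("x", "y", "z")))
  idx <- which(arr != 0L, arr.ind = TRUE) - 1L  # 0-based
  lab <- arr[arr != 0L]
  for (i in seq_along(codes)) {
    sel <- lab == codes[i]
    out[i, ] <- colMeans(voxel_to_world(idx[sel, , drop = FALSE], labels$affine))
  }
  if (!is.null(roi_names)) rownames(out) <- unname(roi_names[rownames(out)])
  out
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("<parcellation> %d regions over %s voxels\n",
              length(x$roi_names), paste(dim(x$labels$data), collapse = "x")))
  invisible(x)
}

#' Analysis mask of a parcellation
#'
#' Binary mask over the labelled voxels, excluding intensity-normalisation
#' reference regions (cerebellum, pons): statistics are never computed
#' inside the regions a modality is normalised by.
#'
#' @param parcellation A [parcellation()].
#' @param exclude Region names to leave out of the mask.
#' @return A binary [image_volume()].
#' @export
analysis_mask <- function(parcellation,
                          exclude = c("cerebellum", "pons")) {
  labs <- parcellation$labels
  keep <- as.integer(names(parcellation$roi_names)[
    !parcellation$roi_names %in% exclude])
  image_volume(array(as.numeric(labs$data %in% keep), dim(labs$data)),
               labs$voxel_size_mm, labs$affine)
}

grids_match <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$voxel_size_mm - b$voxel_size_mm)) < tol &&
    max(abs(a$affine - b$affine)) < tol
}
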