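#' PET volume in SUV units
#'
#' Container for a 3D PET image whose voxel values are standardized uptake
#' values (SUV). Voxel indices are 1-based `(i, j, k)` over `(x, y, z)`; world
#' coordinates follow the NIfTI affine convention `world = origin +
#' (index - 1) * spacing`.
#'
#' @param values 3D numeric array of SUVs; all values must be finite and
#'   non-negative.
#' @param spacing Numeric length-3, voxel spacing `(dx, dy, dz)` in mm;
#'   strictly positive.
#' @param origin Numeric length-3, world coordinate of the first voxel center
#'   in mm.
#' @return An object of class `pet_volume` with fields `values`, `spacing`,
#'   `origin`.
#' @export
pet_volume <- function(values, spacing = c(4.07, 4.07, 2), origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3)
    stop("`values` must be a 3D array")
  if (!all(is.finite(values)))
    stop("all SUV values must be finite")
  if (any(values < 0))
    stop("all SUV values must be >= 0")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive values (mm)")
  structure(
    list(values = values, spacing = spacing, origin = as.numeric(origin)),
    class = "pet_volume")
}

#' @export
print.pet_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<pet_volume> %d x %d x %d voxels, spacing %.2f x %.2f x %.2f mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  SUV range [%.3f, %.3f], voxel volume %.5f ml\n",
              min(x$values), max(x$values), voxel_volume_ml(x)))
  invisible(x)
}

#' Voxel volume in ml
#'
#' @param x A `pet_volume` or `voi_mask`.
#' @return Volume of one voxel in ml (`dx * dy * dz / 1000`).
#' @export
voxel_volume_ml <- function(x) prod(x$spacing) / 1000

#' Volume-of-interest mask
#'
#' A boolean voxel mask aligned to a [pet_volume()], tagged with the
#' delineation method and observer that produced it. The metabolic tumor
#' volume (MTV) in ml is `n_voxels * voxel volume`.
#'
#' @param mask 3D logical array, same dimensions as the source volume.
#' @param volume The `pet_volume` the mask is aligned to (geometry source).
#' @param method Provenance tag; one of [segmentation_methods()] or `"TRUTH"`
#'   for generator ground-truth masks.
#' @param observer Observer identifier (free-form string).
#' @return Object of class `voi_mask` with fields `mask`, `method`,
#'   `observer`, `spacing`, `n_voxels`, `volume_ml`.
#' @export
voi_mask <- function(mask, volume, method = "TRUTH", observer = "obs1") {
  if (!is.array(mask) || !is.logical(mask))
    stop("`mask` must be a logical 3D array")
  if (!identical(dim(mask), dim(volume$values)))
    stop("mask and volume grids do not match; exact alignment is required")
  method <- match.arg(method, c(SEGMENTATION_METHODS, "TRUTH"))
  n <- sum(mask)
  structure(
    list(mask = mask, method = method, observer = as.character(observer),
         spacing = volume$spacing, n_voxels = n,
         volume_ml = n * prod(volume$spacing) / 1000),
    class = "voi_mask")
}

#' @export
print.voi_mask <- function(x, ...) {
  cat(sprintf("<voi_mask> %s / %s: %d voxels, %.3f ml\n",
              x$method, x$observer, x$n_voxels, x$volume_ml))
  invisible(x)
}

#' Read a PET volume from a NIfTI-1 file
#'
#' The image must be 3D with strictly positive voxel spacing; values are
#' interpreted as SUVs. Spacing is taken from the header `pixdim`, the origin
#' from the translation column of the stored affine.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A [pet_volume()].
#' @export
load_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3) stop("expected a 3D image, got ", length(d), " dimensions")
  spacing <- RNifti::pixdim(img)
  if (length(spacing) < 3 || any(spacing[1:3] <= 0))
    stop("non-positive voxel spacing in header")
  origin <- as.numeric(RNifti::xform(img)[1:3, 4])
  pet_volume(array(as.numeric(img), dim = d), spacing = spacing[1:3],
             origin = origin)
}

#' Write a PET volume to a NIfTI-1 file
#'
#' @param volume A [pet_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
save_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$values)
  RNifti::pixdim(img) <- volume$spacing
  aff <- diag(c(volume$spacing, 1))
  aff[1:3, 4] <- volume$origin
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a VOI mask to a NIfTI-1 file
#'
#' The mask is stored as 0/1 in an 8-bit integer payload with the geometry of
#' its source volume, and round-trips losslessly through [load_volume()] /
#' [load_mask()].
#'
#' @param mask A [voi_mask()].
#' @param path Output path.
#' @param origin World origin to record (defaults to zero).
#' @return `path`, invisibly.
#' @export
save_mask <- function(mask, path, origin = c(0, 0, 0)) {
  img <- RNifti::asNifti(array(as.integer(mask$mask), dim = dim(mask$mask)))
  RNifti::pixdim(img) <- mask$spacing
  aff <- diag(c(mask$spacing, 1))
  aff[1:3, 4] <- origin
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Read a VOI mask from a NIfTI-1 file
#'
#' @param path Path to a mask written by [save_mask()] (values 0/1).
#' @param volume Optional `pet_volume` to align the mask to; when omitted the
#'   geometry is taken from the mask file itself.
#' @param method,observer Provenance tags for the returned mask.
#' @return A [voi_mask()].
#' @export
load_mask <- function(path, volume = NULL, method = "TRUTH", observer = "obs1") {
  v <- load_volume(path)
  arr <- v$values != 0
  if (is.null(volume)) {
    volume <- pet_volume(array(0, dim(arr)), spacing = v$spacing,
                         origin = v$origin)
  }
  voi_mask(arr, volume, method = method, observer = observer)
}

#' Minimum-volume eligibility of a VOI
#'
#' Texture analysis requires at least `min_voxels` voxels in the VOI (64 by
#' default, i.e. 2.12 ml at 4.07 x 4.07 x 2 mm spacing). The voxel count is
#' the primary rule; the ml figure is derived from the spacing.
#'
#' @param mask A [voi_mask()].
#' @param min_voxels Minimum voxel count (default 64).
#' @return Object of class `eligibility_result`: `eligible`, `n_voxels`,
#'   `min_voxels`, `min_volume_ml`.
#' @export
check_min_volume <- function(mask, min_voxels = 64L) {
  structure(
    list(eligible = mask$n_voxels >= min_voxels,
         n_voxels = mask$n_voxels,
         min_voxels = as.integer(min_voxels),
         min_volume_ml = min_voxels * prod(mask$spacing) / 1000),
    class = "eligibility_result")
}

#' @export
print.eligibility_result <- function(x, ...) {
  cat(sprintf("<eligibility> %s: %d voxels (floor %d = %.2f ml)\n",
              if (x$eligible) "eligible" else "NOT eligible",
              x$n_voxels, x$min_voxels, x$min_volume_ml))
  invisible(x)
}
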