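#' Labeled segmentation volumes and binary ribbon masks
#'
#' A `labeled_volume` is a 3D grid of non-negative integer labels
#' (0 = background) with voxel spacing in mm; a `binary_mask` is a 3D logical
#' grid selecting one region's grey-matter ribbon. All geometry downstream is
#' computed in voxel units; only morphometry converts to mm.
#'
#' @param grid 3D integer (or logical) array.
#' @param spacing numeric length-3, voxel edge lengths in mm (strictly positive).
#' @return `labeled_volume()` and `binary_mask()` return objects of the
#'   respective class: a list with elements `grid`, `spacing` and, for masks,
#'   `voxel_count`.
#' @examples
#' m <- binary_mask(array(TRUE, c(4, 4, 4)))
#' m$voxel_count
#' @export
labeled_volume <- function(grid, spacing = c(1, 1, 1)) {
  if (length(dim(grid)) != 3L) {
    abort("`grid` must be a 3D array.")
  }
  if (is.double(grid)) {
    if (any(grid != round(grid), na.rm = TRUE)) {
      abort("Label grid contains non-integer voxel values (type double); labels must be integers.")
    }
    storage.mode(grid) <- "integer"
  }
  if (!is.integer(grid)) {
    abort(paste0("Label grid must be integer-valued, got type '", typeof(grid), "'."))
  }
  if (anyNA(grid) || any(grid < 0L)) {
    abort("Labels must be non-negative integers with no missing values.")
  }
  spacing <- as.numeric(spacing)
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  structure(
    list(grid = grid, spacing = spacing, shape = dim(grid)),
    class = "labeled_volume"
  )
}

#' @rdname labeled_volume
#' @export
binary_mask <- function(grid, spacing = c(1, 1, 1)) {
  if (length(dim(grid)) != 3L) {
    abort("`grid` must be a 3D array.")
  }
  if (!is.logical(grid)) {
    if (!all(grid %in% c(0, 1))) {
      abort("Mask grid must be logical or 0/1.")
    }
    grid <- array(as.logical(grid), dim(grid))
  }
  spacing <- as.numeric(spacing)
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  structure(
    list(grid = grid, spacing = spacing, voxel_count = sum(grid)),
    class = "binary_mask"
  )
}

#' @export
print.labeled_volume <- function(x, ...) {
  cat("<labeled_volume> ", paste(x$shape, collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm, ", length(setdiff(unique(as.vector(x$grid)), 0L)),
      " non-zero labels\n", sep = "")
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask> ", paste(dim(x$grid), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm, ", x$voxel_count, " foreground voxels\n", sep = "")
  invisible(x)
}

is_isotropic <- function(spacing, tol = 1e-6) {
  max(abs(spacing - spacing[1])) <= tol * abs(spacing[1])
}

assert_isotropic <- function(spacing, what = "Fractal-dimension estimation") {
  if (!is_isotropic(spacing)) {
    abort(paste0(
      what, " requires isotropic voxels; got spacing (",
      paste(signif(spacing, 6), collapse = ", "),
      ") mm. Scale units are voxels, so anisotropy would distort D."
    ))
  }
  invisible(TRUE)
}

#' Read a labeled segmentation volume from NIfTI
#'
#' Reads a 3D NIfTI-1 volume of integer labels (e.g. a FreeSurfer
#' segmentation exported to NIfTI). Voxel spacing is taken from the header;
#' no resampling or reorientation is performed, so the array keeps the file's
#' native voxel order. Floating-point storage is accepted only when every
#' voxel value is an exact integer.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [labeled_volume()].
#' @export
load_label_volume <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Volume file not found: ", path))
  }
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- array(img[, , , 1], d[1:3])
    d <- d[1:3]
  }
  if (length(d) != 3L) {
    abort(paste0("Expected a 3D volume, got ", length(d), "D input: ", path))
  }
  spacing <- RNifti::pixdim(img)[1:3]
  labeled_volume(array(as.vector(img), d), spacing)
}

#' Write a binary mask as a 0/1 NIfTI volume
#'
#' @param mask a [binary_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask_nifti <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  arr <- array(as.integer(mask$grid), dim(mask$grid))
  attr(arr, "pixdim") <- mask$spacing
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "uint8"), path)
  invisible(path)
}

#' Extract a region's binary ribbon mask from a labeled volume
#'
#' The mask is true exactly where the volume's label belongs to the region's
#' label set. Spacing is copied from the volume. An empty result is returned
#' with a warning naming the region; fractal-dimension estimation refuses
#' empty masks downstream.
#'
#' @param vol a [labeled_volume()].
#' @param region one row of a region atlas (see [default_region_atlas()]), or
#'   any list with elements `name` and `label_ids`.
#' @return A [binary_mask()].
#' @export
extract_region_mask <- function(vol, region) {
  stopifnot(inherits(vol, "labeled_volume"))
  if (is.data.frame(region)) {
    stopifnot(nrow(region) == 1L)
    region <- list(name = region$name, label_ids = region$label_ids[[1]])
  }
  ids <- as.integer(unlist(region$label_ids))
  stopifnot(length(ids) > 0L)
  g <- array(vol$grid %in% ids, dim(vol$grid))
  m <- binary_mask(g, vol$spacing)
  if (m$voxel_count == 0L) {
    warn(paste0("Region '", region$name, "' has no voxels in this volume."))
  }
  m
}
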