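#' Volumetric scalar image with physical geometry
#'
#' The basic container of the package: a 3-D array of scalars together with
#' the voxel spacing (mm), the physical position of the first voxel centre
#' (mm) and a unit tag. Voxel index `(i, j, k)` (1-based) maps to the
#' physical point `origin + (c(i, j, k) - 1) * spacing`; the geometry is
#' axis-aligned, there are no direction cosines.
#'
#' Unit tags carry physical constraints: count, count-rate, attenuation
#' (`per_mm`) and concentration images must be non-negative; attenuation
#' correction factor (`acf`) images must be >= 1.
#'
#' @param values numeric 3-D array.
#' @param spacing numeric length-3, voxel size per axis in mm; all > 0.
#' @param origin numeric length-3, physical position (mm) of the centre of
#'   voxel `(1, 1, 1)`.
#' @param unit one of `"cps"`, `"counts"`, `"HU"`, `"per_mm"`, `"acf"`,
#'   `"MBq_per_mL"`, `"dimensionless"`.
#' @return An object of class `scalar_image`.
#' @export
scalar_image <- function(values, spacing, origin = c(0, 0, 0),
                         unit = "dimensionless") {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("`values` must be a 3-D array", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be three strictly positive finite values (mm)",
         call. = FALSE)
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("`origin` must be three finite values (mm)", call. = FALSE)
  }
  unit <- match.arg(unit, image_units())
  storage.mode(values) <- "double"
  img <- structure(
    list(values = values, spacing = spacing, origin = origin, unit = unit),
    class = "scalar_image"
  )
  validate_image(img)
  img
}

image_units <- function() {
  c("cps", "counts", "HU", "per_mm", "acf", "MBq_per_mL", "dimensionless")
}

validate_image <- function(img) {
  bad <- which(!is.finite(img$values))
  if (length(bad)) {
    idx <- arrayInd(bad[1L], dim(img$values))
    stop(sprintf("non-finite voxel value at index (%d, %d, %d)",
                 idx[1L], idx[2L], idx[3L]), call. = FALSE)
  }
  nonneg <- c("cps", "counts", "per_mm", "MBq_per_mL")
  if (img$unit %in% nonneg && any(img$values < 0)) {
    stop(sprintf("'%s' image contains negative voxels", img$unit),
         call. = FALSE)
  }
  if (img$unit == "acf" && any(img$values < 1 - 1e-9)) {
    stop("ACF image contains voxels < 1", call. = FALSE)
  }
  invisible(img)
}

#' @export
print.scalar_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<scalar_image> %d x %d x %d voxels, spacing (%g, %g, %g) mm, unit '%s'\n",
    d[1L], d[2L], d[3L], x$spacing[1L], x$spacing[2L], x$spacing[3L], x$unit))
  cat(sprintf("  origin (%g, %g, %g) mm, value range [%g, %g]\n",
              x$origin[1L], x$origin[2L], x$origin[3L],
              min(x$values), max(x$values)))
  invisible(x)
}

#' Do two images share one sampling grid?
#'
#' Shape must match exactly; spacing and origin within `tol` mm.
#'
#' @param a,b `scalar_image` (or `voi_mask`) objects.
#' @param tol geometric tolerance in mm.
#' @return logical scalar.
#' @export
same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing - b$spacing) <= tol) &&
    all(abs(a$origin - b$origin) <= tol)
}

stop_if_grid_mismatch <- function(a, b, what = "images") {
  if (!same_grid(a, b)) {
    stop(sprintf("%s are not on the same grid", what), call. = FALSE)
  }
  invisible(TRUE)
}

#' Voxel volume in millilitres
#'
#' @param img a `scalar_image` or `voi_mask`.
#' @return scalar, `prod(spacing) / 1000` (mm^3 to mL).
#' @export
voxel_volume_mL <- function(img) prod(img$spacing) / 1000

## Replace the voxel values of an image, keeping its geometry; used by every
## voxelwise operation so geometry/unit handling lives in one place.
with_values <- function(img, values, unit = img$unit) {
  scalar_image(values, img$spacing, img$origin, unit)
}

## Physical coordinates of all voxel centres along one axis.
axis_coords <- function(img, axis) {
  n <- dim(img$values)[axis]
  img$origin[axis] + (seq_len(n) - 1) * img$spacing[axis]
}

#' Binary volume of interest mask
#'
#' A logical voxel grid on a reference sampling, with a provenance tag
#' recording how it was derived. The enclosed volume in mL is always
#' `sum(values) * prod(spacing) / 1000`.
#'
#' @param values logical (or 0/1 numeric) 3-D array.
#' @param spacing,origin grid geometry in mm, as for [scalar_image()].
#' @param provenance one of `"ct-threshold"`, `"spect-kidney"`,
#'   `"spect-tumor"`, `"phantom-truth"`, `"manual"`.
#' @return An object of class `voi_mask`.
#' @export
voi_mask <- function(values, spacing, origin = c(0, 0, 0),
                     provenance = "manual") {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("`values` must be a 3-D array", call. = FALSE)
  }
  if (is.numeric(values)) {
    if (!all(values %in% c(0, 1))) {
      stop("mask values must be strictly binary", call. = FALSE)
    }
    values <- array(values != 0, dim = dim(values))
  }
  if (!is.logical(values) || anyNA(values)) {
    stop("mask values must be strictly binary", call. = FALSE)
  }
  provenance <- match.arg(
    provenance,
    c("ct-threshold", "spect-kidney", "spect-tumor", "phantom-truth", "manual"))
  structure(
    list(values = values, spacing = as.numeric(spacing),
         origin = as.numeric(origin), provenance = provenance),
    class = "voi_mask")
}

#' @export
print.voi_mask <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<voi_mask> %d x %d x %d voxels, %d set (%.4g mL), provenance '%s'\n",
    d[1L], d[2L], d[3L], sum(x$values), mask_volume_mL(x), x$provenance))
  invisible(x)
}

#' Mask volume in millilitres
#'
#' @param mask a `voi_mask`.
#' @return scalar mL, exactly voxel count times voxel volume.
#' @export
mask_volume_mL <- function(mask) sum(mask$values) * prod(mask$spacing) / 1000

## Mask on the same grid as an image, as plain logical array.
mask_on <- function(mask, img) {
  stop_if_grid_mismatch(mask, img, "mask and image")
  mask$values
}
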