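#' VOI selection parameters
#'
#' Parameters of the three VOI definition procedures. The tumour recipe
#' follows the three-step protocol: Gaussian blur with sigma of 1.5 voxel
#' sizes, threshold at 8% of the blurred maximum within a local region,
#' then dilation by 2 voxels.
#'
#' @param ct_hu_threshold HU threshold for CT binarization.
#' @param kidney_rate_threshold_fraction SPECT threshold as a fraction of
#'   the regional maximum, in (0, 1).
#' @param kidney_erosion_voxels non-negative integer erosion passes.
#' @param tumor_sigma_factor blur sigma in voxel units.
#' @param tumor_threshold_fraction threshold fraction of the blurred
#'   regional maximum, in (0, 1).
#' @param tumor_dilate_voxels non-negative integer dilation passes.
#' @param local_region optional 2x3 matrix `rbind(lo, hi)` of a bounding
#'   box in mm restricting where the maximum is sought (and, for the
#'   kidney, where the threshold is applied); default: whole image.
#' @return An object of class `voi_params`.
#' @export
voi_params <- function(ct_hu_threshold = -400,
                       kidney_rate_threshold_fraction = 0.5,
                       kidney_erosion_voxels = 1L,
                       tumor_sigma_factor = 1.5,
                       tumor_threshold_fraction = 0.08,
                       tumor_dilate_voxels = 2L,
                       local_region = NULL) {
  for (f in c(kidney_rate_threshold_fraction, tumor_threshold_fraction)) {
    if (f <= 0 || f >= 1) {
      stop("threshold fractions must lie in (0, 1)", call. = FALSE)
    }
  }
  if (kidney_erosion_voxels < 0 || tumor_dilate_voxels < 0) {
    stop("morphology radii must be non-negative integers", call. = FALSE)
  }
  if (!is.null(local_region)) {
    local_region <- matrix(local_region, nrow = 2L)
    stopifnot(ncol(local_region) == 3L, all(local_region[1L, ] <=
                                              local_region[2L, ]))
  }
  structure(list(ct_hu_threshold = ct_hu_threshold,
                 kidney_rate_threshold_fraction =
                   kidney_rate_threshold_fraction,
                 kidney_erosion_voxels = as.integer(kidney_erosion_voxels),
                 tumor_sigma_factor = tumor_sigma_factor,
                 tumor_threshold_fraction = tumor_threshold_fraction,
                 tumor_dilate_voxels = as.integer(tumor_dilate_voxels),
                 local_region = local_region),
            class = "voi_params")
}

region_array <- function(img, local_region) {
  if (is.null(local_region)) {
    return(array(TRUE, dim = dim(img$values)))
  }
  co <- coord_arrays(list(dim = dim(img$values), spacing = img$spacing,
                          origin = img$origin))
  co$X >= local_region[1L, 1L] & co$X <= local_region[2L, 1L] &
    co$Y >= local_region[1L, 2L] & co$Y <= local_region[2L, 2L] &
    co$Z >= local_region[1L, 3L] & co$Z <= local_region[2L, 3L]
}

#' CT-threshold VOI (phantom / ex vivo)
#'
#' Binarizes the CT at `ct_hu_threshold` and keeps the largest connected
#' component. Water or soft tissue against air separates cleanly; a
#' threshold below the global minimum selects the whole image and is
#' flagged with a warning.
#'
#' @param ct a [scalar_image()] in HU.
#' @param params a [voi_params()].
#' @param target_grid optional reference image/mask; when given, the mask
#'   is nearest-resampled onto it (CT-derived masks are stored on the
#'   SPECT grid before quantification).
#' @return A [voi_mask()] with provenance `"ct-threshold"`.
#' @export
ct_threshold_voi <- function(ct, params = voi_params(), target_grid = NULL) {
  if (ct$unit != "HU") stop("`ct` must be in HU", call. = FALSE)
  m <- ct$values >= params$ct_hu_threshold
  if (!any(m)) stop("CT threshold selected no voxels", call. = FALSE)
  if (all(m)) {
    warning("CT threshold below the image minimum: whole image selected",
            call. = FALSE)
  }
  mask <- voi_mask(largest_component(m), ct$spacing, ct$origin,
                   "ct-threshold")
  if (!is.null(target_grid)) mask <- resample_mask(mask, target_grid)
  mask
}

#' Kidney VOI: SPECT threshold plus erosion
#'
#' Thresholds the SPECT image at a fraction of its maximum within the
#' local region, keeps the largest connected component, and erodes it so
#' that PVE spill-out does not push the border beyond the anatomic organ
#' boundary.
#'
#' @param spect a non-negative [scalar_image()].
#' @param params a [voi_params()].
#' @return A [voi_mask()] with provenance `"spect-kidney"`.
#' @export
kidney_voi <- function(spect, params = voi_params()) {
  if (any(spect$values < 0)) {
    stop("`spect` must be non-negative", call. = FALSE)
  }
  reg <- region_array(spect, params$local_region)
  mx <- max(spect$values[reg])
  if (mx <= 0) stop("no signal in the local region", call. = FALSE)
  m <- reg & (spect$values >= params$kidney_rate_threshold_fraction * mx)
  m <- largest_component(m)
  m <- morph_apply(m, params$kidney_erosion_voxels, erode_once)
  if (!any(m)) {
    stop("kidney VOI empty after erosion; reduce `kidney_erosion_voxels`",
         call. = FALSE)
  }
  voi_mask(m, spect$spacing, spect$origin, "spect-kidney")
}

#' Tumour VOI: blur, local threshold, dilate
#'
#' (i) Gaussian blur with sigma of `tumor_sigma_factor` voxel sizes per
#' axis, (ii) threshold at `tumor_threshold_fraction` of the blurred
#' maximum within the local region, keep the largest connected component,
#' (iii) dilate by `tumor_dilate_voxels` voxels.
#'
#' @param spect a non-negative [scalar_image()].
#' @param params a [voi_params()].
#' @return A [voi_mask()] with provenance `"spect-tumor"`.
#' @export
tumor_voi <- function(spect, params = voi_params()) {
  if (any(spect$values < 0)) {
    stop("`spect` must be non-negative", call. = FALSE)
  }
  if (all(spect$values == 0)) {
    stop("SPECT image is identically zero", call. = FALSE)
  }
  blurred <- blur_gaussian(spect, sigma_vox = params$tumor_sigma_factor)
  reg <- region_array(spect, params$local_region)
  mx <- max(blurred$values[reg])
  if (mx <= 0) stop("no signal in the local region", call. = FALSE)
  m <- reg & (blurred$values >= params$tumor_threshold_fraction * mx)
  m <- largest_component(m)
  m <- morph_apply(m, params$tumor_dilate_voxels, dilate_once)
  voi_mask(m, spect$spacing, spect$origin, "spect-tumor")
}
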