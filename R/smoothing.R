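#' Isotropic Gaussian point-spread-function model
#'
#' The collimator-detector response of the reconstructed images is modelled
#' as an isotropic Gaussian of given full width at half maximum. The same
#' model serves as the forward blur in the simulator and as the resolution
#' model of the partial-volume correction.
#'
#' @param fwhm_mm full width at half maximum in mm; 0 means a delta
#'   (no blur).
#' @return An object of class `psf_model`.
#' @export
psf_model <- function(fwhm_mm) {
  fwhm_mm <- as.numeric(fwhm_mm)
  if (length(fwhm_mm) != 1L || !is.finite(fwhm_mm) || fwhm_mm < 0) {
    stop("`fwhm_mm` must be a single non-negative number", call. = FALSE)
  }
  structure(list(kind = "gaussian", fwhm_mm = fwhm_mm), class = "psf_model")
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

## Normalised 1-D Gaussian kernel, sigma in voxels, truncated at 4 sigma.
gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-((-r):r)^2 / (2 * sigma_vox^2))
  k / sum(k)
}

## Convolve a 3-D array along one axis with a centred kernel
## (zero-padded boundaries), via a banded matrix product.
convolve_axis <- function(arr, kernel, axis) {
  if (length(kernel) == 1L) return(arr * kernel)
  d <- dim(arr)
  n <- d[axis]
  r <- (length(kernel) - 1L) / 2L
  C <- matrix(0, n, n)
  for (off in -r:r) {
    i <- seq_len(n)
    j <- i + off
    ok <- j >= 1L & j <= n
    C[cbind(i[ok], j[ok])] <- kernel[off + r + 1L]
  }
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  m <- C %*% matrix(a, nrow = n)
  a <- array(m, dim = d[perm])
  aperm(a, order(perm))
}

## Separable Gaussian blur of a 3-D array; sigma given in voxels per axis.
blur_array <- function(arr, sigma_vox) {
  for (a in 1:3) {
    if (sigma_vox[a] > 0) {
      arr <- convolve_axis(arr, gaussian_kernel_1d(sigma_vox[a]), a)
    }
  }
  arr
}

#' Gaussian blur of an image
#'
#' Separable convolution with an isotropic Gaussian specified in physical
#' mm (converted per axis to voxel units), zero-padded at the grid
#' boundary.
#'
#' @param img a [scalar_image()].
#' @param fwhm_mm full width at half maximum in mm (scalar), or a
#'   [psf_model()].
#' @param sigma_vox alternatively, the standard deviation in voxel units
#'   (scalar or per-axis); overrides `fwhm_mm`.
#' @return Blurred [scalar_image()].
#' @export
blur_gaussian <- function(img, fwhm_mm = NULL, sigma_vox = NULL) {
  if (inherits(fwhm_mm, "psf_model")) fwhm_mm <- fwhm_mm$fwhm_mm
  if (is.null(sigma_vox)) {
    stopifnot(!is.null(fwhm_mm))
    sigma_vox <- fwhm_to_sigma(fwhm_mm) / img$spacing
  } else {
    sigma_vox <- rep(sigma_vox, length.out = 3L)
  }
  if (all(sigma_vox <= 0)) return(img)
  with_values(img, blur_array(img$values, sigma_vox))
}
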