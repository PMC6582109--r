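#' Forward-simulation configuration
#'
#' Parameters of the reconstruction-domain forward model used by
#' [simulate_windows()]. The simulator emulates already-reconstructed
#' SPECT window images: voxelwise attenuation by the angle-averaged
#' transmission (the exact reciprocal of the Chang ACF), isotropic
#' Gaussian PSF blur, a spatially broad Gaussian scatter tail apportioned
#' to the three energy windows, and Poisson counting noise over a single
#' effective acquisition duration.
#'
#' The two mismatch knobs deliberately break the match between the
#' forward model and the corrections for robustness tests:
#' `psf_fwhm_error_fraction` simulates with a PSF wider (or narrower) than
#' the nominal one the corrections will assume, and `scatter_tail_width_mm`
#' sets the scatter kernel width.
#'
#' @param psf_fwhm_mm nominal PSF full width at half maximum, mm.
#' @param scatter_fraction fraction of primary counts appearing as
#'   scatter, in [0, 1).
#' @param sensitivity_cps_per_MBq system sensitivity per emitted line.
#' @param photopeaks data frame with columns `energy_keV`, `branching`
#'   (exactly two rows; branching in (0, 1]).
#' @param noise `"poisson"` or `"none"`.
#' @param seed integer RNG seed for the Poisson draw.
#' @param duration_s effective acquisition duration, s.
#' @param scatter_tail_width_mm FWHM-like width (Gaussian sigma is this
#'   value) of the scatter tail, mm.
#' @param psf_fwhm_error_fraction fractional error applied to the PSF in
#'   the forward direction only.
#' @param n_angles ray count for the forward attenuation ACF maps.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(psf_fwhm_mm = 1.8,
                              scatter_fraction = 0.2,
                              sensitivity_cps_per_MBq = 2110,
                              photopeaks = data.frame(
                                energy_keV = c(171.3, 245.4),
                                branching = c(0.9061, 0.9412)),
                              noise = c("poisson", "none"),
                              seed = 1L,
                              duration_s = 300,
                              scatter_tail_width_mm = 10,
                              psf_fwhm_error_fraction = 0,
                              n_angles = 64L) {
  noise <- match.arg(noise)
  if (nrow(photopeaks) != 2L) {
    stop("exactly two photopeaks are required", call. = FALSE)
  }
  if (any(photopeaks$branching <= 0) || any(photopeaks$branching > 1)) {
    stop("branching probabilities must lie in (0, 1]", call. = FALSE)
  }
  if (scatter_fraction < 0 || scatter_fraction >= 1) {
    stop("`scatter_fraction` must lie in [0, 1)", call. = FALSE)
  }
  if (psf_fwhm_mm < 0 || sensitivity_cps_per_MBq <= 0 || duration_s <= 0) {
    stop("PSF width must be >= 0; sensitivity and duration > 0",
         call. = FALSE)
  }
  structure(list(psf_fwhm_mm = psf_fwhm_mm,
                 scatter_fraction = scatter_fraction,
                 sensitivity_cps_per_MBq = sensitivity_cps_per_MBq,
                 photopeaks = photopeaks, noise = noise,
                 seed = as.integer(seed), duration_s = duration_s,
                 scatter_tail_width_mm = scatter_tail_width_mm,
                 psf_fwhm_error_fraction = psf_fwhm_error_fraction,
                 n_angles = as.integer(n_angles)),
            class = "simulation_config")
}

## Body support for attenuation: tissue/water on CT, largest component.
body_mask_from_ct <- function(ct_on_grid, hu_threshold = -400) {
  m <- ct_on_grid$values >= hu_threshold
  if (!any(m)) return(NULL)
  voi_mask(largest_component(m), ct_on_grid$spacing, ct_on_grid$origin,
           "ct-threshold")
}

#' Simulate post-reconstruction SPECT energy-window images
#'
#' Runs the forward model on a ground-truth activity map and CT: per
#' photopeak, the voxel activity is attenuated by the angle-averaged
#' transmission computed from the CT-derived mu map (the reciprocal of the
#' Chang ACF at that energy), blurred with the PSF and scaled by the
#' sensitivity and branching ratio; in-peak scatter is a broad Gaussian
#' tail of the primaries scaled by `scatter_fraction`; the 209 keV scatter
#' window collects the tails of both peaks scaled by the ratio of window
#' widths; Poisson noise (if enabled) is applied to expected counts over
#' the acquisition duration and converted back to count rates.
#'
#' @param activity [scalar_image()] in MBq/mL on the SPECT grid.
#' @param ct [scalar_image()] in HU (any grid; resampled internally).
#' @param config a [simulation_config()].
#' @param windows an [energy_window_set()].
#' @param model an [attenuation_model()].
#' @return A [windowed_counts()] with attribute `"truth"`: list with
#'   `total_MBq`, per-peak ACF maps, the noise-free expected window
#'   images, the body mask, and the configuration.
#' @export
simulate_windows <- function(activity, ct, config = simulation_config(),
                             windows = energy_window_set(),
                             model = attenuation_model()) {
  stopifnot(inherits(activity, "scalar_image"),
            inherits(config, "simulation_config"))
  if (activity$unit != "MBq_per_mL") {
    stop("`activity` must be in MBq/mL", call. = FALSE)
  }
  ct_s <- if (same_grid(ct, activity)) ct else {
    resample_to_grid(ct, activity, "linear", fill = -1000)
  }
  body <- body_mask_from_ct(ct_s)

  voxvol <- voxel_volume_mL(activity)
  a_vox <- activity$values * voxvol  # MBq per voxel
  fwhm <- config$psf_fwhm_mm * (1 + config$psf_fwhm_error_fraction)
  sigma_psf <- fwhm_to_sigma(fwhm) / activity$spacing
  sigma_tail <- config$scatter_tail_width_mm / activity$spacing

  peaks <- list(windows$peak1, windows$peak2)
  ws <- window_width_keV(windows$scatter)
  acf_maps <- vector("list", 2L)
  expected <- vector("list", 2L)
  scatter_exp <- array(0, dim = dim(a_vox))
  for (p in 1:2) {
    e <- config$photopeaks$energy_keV[p]
    b <- config$photopeaks$branching[p]
    if (!is.null(body)) {
      mu <- hu_to_mu(ct_s, e, model)
      acf <- chang_acf(mu, body, config$n_angles)
    } else {
      acf <- with_values(ct_s, array(1, dim = dim(a_vox)), unit = "acf")
    }
    acf_maps[[p]] <- acf
    att <- a_vox / acf$values
    primary <- config$sensitivity_cps_per_MBq * b *
      blur_array(att, sigma_psf)
    if (config$scatter_fraction > 0) {
      tail_p <- config$scatter_fraction * blur_array(primary, sigma_tail)
      expected[[p]] <- primary + tail_p
      scatter_exp <- scatter_exp +
        tail_p * ws / window_width_keV(peaks[[p]])
    } else {
      expected[[p]] <- primary
    }
  }

  imgs <- list(expected[[1L]], scatter_exp, expected[[2L]])
  if (config$noise == "poisson") {
    old_seed <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", envir = globalenv())) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old_seed, envir = globalenv())
      }
    })
    set.seed(config$seed)
    imgs <- lapply(imgs, function(e) {
      lambda <- pmax(e, 0) * config$duration_s
      counts <- array(stats::rpois(length(lambda), lambda), dim = dim(e))
      counts / config$duration_s
    })
  }
  mk <- function(v) scalar_image(v, activity$spacing, activity$origin, "cps")
  out <- windowed_counts(mk(imgs[[1L]]), mk(imgs[[2L]]), mk(imgs[[3L]]),
                         windows)
  attr(out, "truth") <- list(
    total_MBq = sum(a_vox),
    acf171 = acf_maps[[1L]], acf245 = acf_maps[[2L]],
    expected_peak1 = mk(expected[[1L]]),
    expected_scatter = mk(scatter_exp),
    expected_peak2 = mk(expected[[2L]]),
    body_mask = body, config = config)
  out
}
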