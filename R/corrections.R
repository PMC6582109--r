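#' Acquisition energy windows for In-111
#'
#' In-111 emits 171.3 keV (90.61%) and 245.4 keV (94.12%) gammas. The
#' acquisition uses a 10% relative window around each photopeak plus a
#' 209 keV +/- 10% window between them for the dual-energy-window scatter
#' estimate. Window width in keV is `2 * rel_width * center`.
#'
#' @param peak1,scatter,peak2 lists with `center` (keV), `rel_width`
#'   (fraction) and, for peaks, `branching` (emission probability).
#' @return An object of class `energy_window_set`.
#' @export
energy_window_set <- function(
    peak1 = list(center = 171.3, rel_width = 0.10, branching = 0.9061),
    scatter = list(center = 209, rel_width = 0.10),
    peak2 = list(center = 245.4, rel_width = 0.10, branching = 0.9412)) {
  for (w in list(peak1, scatter, peak2)) {
    if (w$center <= 0 || w$rel_width <= 0 || w$rel_width >= 0.5) {
      stop("window centers must be > 0 and relative widths in (0, 0.5)",
           call. = FALSE)
    }
  }
  for (p in list(peak1, peak2)) {
    if (is.null(p$branching) || p$branching <= 0 || p$branching > 1) {
      stop("photopeak branching probabilities must lie in (0, 1]",
           call. = FALSE)
    }
  }
  if (!(peak1$center < scatter$center && scatter$center < peak2$center)) {
    stop("scatter window must lie strictly between the photopeaks",
         call. = FALSE)
  }
  ## The nominal 10% windows of the three lines overlap at their edges
  ## (188.1-188.4 and 220.9-229.9 keV), so edge-disjointness cannot be
  ## required; instead demand that no photopeak centre falls inside the
  ## scatter window, which keeps the DEW estimate free of primary counts.
  hw <- function(w) w$rel_width * w$center
  if (peak1$center > scatter$center - hw(scatter) ||
      peak2$center < scatter$center + hw(scatter)) {
    stop("photopeak centre lies inside the scatter window", call. = FALSE)
  }
  structure(list(peak1 = peak1, scatter = scatter, peak2 = peak2),
            class = "energy_window_set")
}

#' Width of an energy window in keV
#'
#' @param window one element of an [energy_window_set()].
#' @return scalar keV, `2 * rel_width * center`.
#' @export
window_width_keV <- function(window) 2 * window$rel_width * window$center

#' Triplet of count-rate images per energy window
#'
#' @param peak1_img,scatter_img,peak2_img [scalar_image()]s in cps on a
#'   common grid.
#' @param windows an [energy_window_set()].
#' @return An object of class `windowed_counts`.
#' @export
windowed_counts <- function(peak1_img, scatter_img, peak2_img,
                            windows = energy_window_set()) {
  stopifnot(inherits(windows, "energy_window_set"))
  stop_if_grid_mismatch(peak1_img, scatter_img, "window images")
  stop_if_grid_mismatch(peak1_img, peak2_img, "window images")
  for (img in list(peak1_img, scatter_img, peak2_img)) {
    if (any(img$values < 0)) {
      stop("window count-rate images must be non-negative", call. = FALSE)
    }
  }
  structure(list(peak1_img = peak1_img, scatter_img = scatter_img,
                 peak2_img = peak2_img, windows = windows),
            class = "windowed_counts")
}

#' Bilinear HU-to-mu attenuation model with dual-peak ACF weights
#'
#' Linear attenuation coefficients of water and cortical bone at the two
#' In-111 photopeak energies (NIST-derived defaults), the HU anchor of the
#' bone segment, and the experimentally defined weights used to combine
#' the two per-peak attenuation correction factor maps
#' (`w171 = 0.635`, `w245 = 0.365`).
#'
#' @param mu_water,mu_bone named numeric vectors (names = energies in keV)
#'   in 1/mm; bone must exceed water at each energy.
#' @param bone_hu HU value at which `mu_bone` is anchored.
#' @param weights length-2 numeric `(w171, w245)` summing to 1.
#' @return An object of class `attenuation_model`.
#' @export
attenuation_model <- function(
    mu_water = c("171.3" = 0.0146, "245.4" = 0.0127),
    mu_bone = c("171.3" = 0.0270, "245.4" = 0.0225),
    bone_hu = 1000,
    weights = c(0.635, 0.365)) {
  if (abs(sum(weights) - 1) > 1e-12) {
    stop("ACF weights must sum to 1 exactly", call. = FALSE)
  }
  if (!all(mu_bone > mu_water) || !all(mu_water > 0)) {
    stop("need mu_bone > mu_water > 0 at each energy", call. = FALSE)
  }
  if (!identical(names(mu_water), names(mu_bone))) {
    stop("mu_water and mu_bone must cover the same energies", call. = FALSE)
  }
  structure(list(mu_water = mu_water, mu_bone = mu_bone, bone_hu = bone_hu,
                 hu_breakpoint = 0, weights = weights),
            class = "attenuation_model")
}

#' Dual-energy-window scatter correction
#'
#' Subtracts a scaled copy of the scatter-window image from each photopeak
#' image: `corrected_p = max(0, peak_p - k_p * scatter)` with
#' `k_p = (width_p / width_scatter) * split_p`. The width ratio accounts
#' for the different keV widths of the windows; `split` apportions the
#' single scatter estimate between the two peaks (default an even 0.5/0.5).
#' Negative voxels are clipped to zero (count rates are physical); the
#' number of clipped voxels is recorded in attribute `"n_clipped"`.
#'
#' @param counts a [windowed_counts()].
#' @param split length-2 non-negative apportionment of the scatter
#'   estimate to (peak1, peak2).
#' @return list with `peak1` and `peak2` corrected [scalar_image()]s.
#' @export
dew_scatter_correct <- function(counts, split = c(0.5, 0.5)) {
  stopifnot(inherits(counts, "windowed_counts"))
  if (length(split) != 2L || any(split < 0)) {
    stop("`split` must be two non-negative fractions", call. = FALSE)
  }
  ws <- window_width_keV(counts$windows$scatter)
  out <- list()
  for (p in 1:2) {
    peak <- counts[[c("peak1_img", "peak2_img")[p]]]
    wp <- window_width_keV(counts$windows[[c("peak1", "peak2")[p]]])
    k <- (wp / ws) * split[p]
    corr <- peak$values - k * counts$scatter_img$values
    n_clip <- sum(corr < 0)
    corr[corr < 0] <- 0
    img <- with_values(peak, corr)
    attr(img, "n_clipped") <- n_clip
    out[[c("peak1", "peak2")[p]]] <- img
  }
  out
}

#' Convert a CT image in HU to linear attenuation coefficients
#'
#' Bilinear model: for HU <= 0, `mu = mu_water(E) * (1 + HU/1000)` clamped
#' at zero (air at -1000 HU maps to 0); for HU > 0, linear interpolation
#' from `mu_water(E)` at 0 HU towards `mu_bone(E)` at the bone anchor HU.
#'
#' @param ct a [scalar_image()] in HU.
#' @param energy_keV one of the energies modelled by `model` (171.3 or
#'   245.4 by default).
#' @param model an [attenuation_model()].
#' @return A [scalar_image()] in 1/mm.
#' @export
hu_to_mu <- function(ct, energy_keV, model = attenuation_model()) {
  if (ct$unit != "HU") stop("`ct` must be in HU", call. = FALSE)
  key <- as.character(energy_keV)
  if (!key %in% names(model$mu_water)) {
    stop(sprintf("energy %s keV is not modelled (have: %s)", key,
                 paste(names(model$mu_water), collapse = ", ")),
         call. = FALSE)
  }
  muw <- model$mu_water[[key]]
  mub <- model$mu_bone[[key]]
  hu <- ct$values
  mu <- ifelse(hu <= 0,
               pmax(0, muw * (1 + hu / 1000)),
               muw + hu * (mub - muw) / model$bone_hu)
  scalar_image(array(mu, dim = dim(hu)), ct$spacing, ct$origin, "per_mm")
}

#' Chang multiplicative attenuation correction factors
#'
#' For each voxel inside the body mask, the transmission
#' `exp(-integral of mu)` is averaged over `n_angles` equally spaced
#' in-plane directions from the voxel to the body boundary (mu vanishes
#' outside the body, so the line integrals run to the grid edge); the ACF
#' is the reciprocal of that mean. Line integrals use fixed-step midpoint
#' sampling with bilinear interpolation of mu. Outside the body the ACF
#' is 1.
#'
#' @param mu a [scalar_image()] in 1/mm.
#' @param body_mask a [voi_mask()] on the same grid (tissue support,
#'   typically CT threshold at -400 HU).
#' @param n_angles number of in-plane ray directions (>= 8; default 64).
#' @param step_mm integration step; default half the smallest voxel
#'   dimension.
#' @return A [scalar_image()] of ACF values (>= 1 inside the body).
#' @export
chang_acf <- function(mu, body_mask, n_angles = 64L, step_mm = NULL) {
  stop_if_grid_mismatch(mu, body_mask, "mu image and body mask")
  if (any(mu$values < 0)) stop("mu must be non-negative", call. = FALSE)
  if (n_angles < 8L) stop("`n_angles` must be >= 8", call. = FALSE)
  if (!any(body_mask$values)) {
    stop("body mask is empty", call. = FALSE)
  }
  if (is.null(step_mm)) step_mm <- min(mu$spacing) / 2
  vals <- chang_acf_cpp(as.numeric(mu$values), dim(mu$values),
                        mu$spacing, as.logical(body_mask$values),
                        as.integer(n_angles), step_mm)
  scalar_image(array(vals, dim = dim(mu$values)), mu$spacing, mu$origin,
               "acf")
}

#' Weighted combination of the two photopeak ACF maps
#'
#' `ACF = w171 * ACF171 + w245 * ACF245` voxelwise, with the
#' experimentally defined weights of the [attenuation_model()].
#'
#' @param acf171,acf245 per-peak ACF [scalar_image()]s on one grid.
#' @param model an [attenuation_model()] carrying the weights.
#' @return Combined ACF [scalar_image()].
#' @export
combine_acf <- function(acf171, acf245, model = attenuation_model()) {
  stop_if_grid_mismatch(acf171, acf245, "ACF maps")
  w <- model$weights
  if (abs(sum(w) - 1) > 1e-12) {
    stop("ACF weights must sum to 1", call. = FALSE)
  }
  with_values(acf171, w[1L] * acf171$values + w[2L] * acf245$values)
}

#' Apply an attenuation correction factor map
#'
#' Voxel-by-voxel multiplication of a count-rate image with an ACF map.
#'
#' @param img a [scalar_image()].
#' @param acf an ACF [scalar_image()] on the same grid.
#' @return Corrected [scalar_image()].
#' @export
apply_attenuation <- function(img, acf) {
  stop_if_grid_mismatch(img, acf, "image and ACF map")
  with_values(img, img$values * acf$values)
}

#' Two-region Mueller-Gaertner partial volume correction
#'
#' Post-reconstruction PVE correction for a target region embedded in a
#' background region. The background level `b` is estimated as the mean of
#' the image over the background mask eroded by one PSF FWHM (to avoid
#' target spill-out contaminating the estimate). Spill-in is removed by
#' subtracting `b * (PSF (x) background indicator)`; spill-out is restored
#' by dividing by the PSF-smoothed target indicator wherever it exceeds
#' `recovery_floor`. Activity outside the target VOI is masked out.
#'
#' @param img a [scalar_image()] (count-rate, possibly already scatter and
#'   attenuation corrected).
#' @param target a [voi_mask()] on the image grid.
#' @param background a [voi_mask()] disjoint from `target`, or `NULL` when
#'   there is no surrounding activity (then `b = 0`).
#' @param psf a [psf_model()].
#' @param recovery_floor lower bound on the smoothed target indicator used
#'   in the division (default 0.1); prevents blow-up at the VOI rim.
#' @return Corrected [scalar_image()], zero outside the target.
#' @export
mgm_correct <- function(img, target, background = NULL, psf = psf_model(1.8),
                        recovery_floor = 0.1) {
  stop_if_grid_mismatch(img, target, "image and target mask")
  tgt <- target$values
  b <- 0
  bg_blur <- NULL
  if (!is.null(background)) {
    stop_if_grid_mismatch(img, background, "image and background mask")
    bg <- background$values
    if (any(bg & tgt)) {
      stop("target and background masks must be disjoint", call. = FALSE)
    }
    if (any(bg)) {
      er_vox <- max(0L, round(psf$fwhm_mm / min(img$spacing)))
      bg_er <- morph_apply(bg, er_vox, erode_once)
      if (!any(bg_er)) {
        warning("background mask vanished under erosion; ",
                "using the uneroded mask for the background level",
                call. = FALSE)
        bg_er <- bg
      }
      b <- mean(img$values[bg_er])
      bg_blur <- blur_array(array(as.numeric(bg), dim = dim(bg)),
                            fwhm_to_sigma(psf$fwhm_mm) / img$spacing)
    }
  }
  vals <- img$values
  if (b > 0 && !is.null(bg_blur)) vals <- vals - b * bg_blur
  rc <- blur_array(array(as.numeric(tgt), dim = dim(tgt)),
                   fwhm_to_sigma(psf$fwhm_mm) / img$spacing)
  feasible <- tgt & (rc >= recovery_floor)
  if (!any(feasible)) {
    stop("smoothed target indicator is below the recovery floor ",
         "everywhere: VOI too small relative to the PSF", call. = FALSE)
  }
  out <- array(0, dim = dim(vals))
  out[feasible] <- vals[feasible] / rc[feasible]
  out[out < 0] <- 0
  with_values(img, out)
}
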