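#' VOI count rate and its statistical spread
#'
#' `R` is the sum of voxel count rates over the mask. The count-rate
#' uncertainty component is the per-voxel (population) standard deviation
#' divided by the mean, scaled by `1/sqrt(n)` — i.e. the relative spread
#' of the VOI mean, which is also the relative spread of `R`.
#'
#' @param img a [scalar_image()] in cps on the mask grid.
#' @param mask a [voi_mask()].
#' @return list with `R_cps` and `sd_rel`.
#' @export
voi_count_rate <- function(img, mask) {
  m <- mask_on(mask, img)
  if (!any(m)) stop("empty VOI mask", call. = FALSE)
  v <- img$values[m]
  n <- length(v)
  mu <- mean(v)
  sd_vox <- sqrt(mean((v - mu)^2))
  sd_rel <- if (n < 2L || mu == 0) 0 else sd_vox / mu / sqrt(n)
  list(R_cps = sum(v), sd_rel = sd_rel)
}

#' In-Gd proportionality coefficient
#'
#' `alpha_InGd(t) = m_Gd / A_In(t)`: gadolinium mass per unit In-111
#' activity, tied to a reference time (the activity decays, the Gd mass
#' does not, so the coefficient grows with time).
#'
#' @param value coefficient in ug/MBq (> 0).
#' @param reference_time timestamp the activity refers to.
#' @param method `"fitted"` (from paired gamma-counter / ICP-MS samples)
#'   or `"calculated"` (from injection-preparation proportions).
#' @param fit_details optional list (slope/intercept errors, excluded
#'   indices) for fitted coefficients.
#' @return An object of class `alpha_coefficient`.
#' @export
alpha_coefficient <- function(value, reference_time = 0,
                              method = c("fitted", "calculated"),
                              fit_details = NULL) {
  method <- match.arg(method)
  if (!is.finite(value) || value <= 0) {
    stop("`value` must be > 0", call. = FALSE)
  }
  structure(list(value = value, reference_time = as_seconds(reference_time),
                 method = method, fit_details = fit_details),
            class = "alpha_coefficient")
}

#' Fit the In-Gd coefficient from paired samples
#'
#' Ordinary least squares of Gd mass on In-111 activity (both referred to
#' one common time), with intercept by default. The slope is the
#' coefficient. Outliers can be excluded by an explicit index list
#' (`exclude = c(i, j)`), or automatically by externally studentized
#' residuals exceeding `cutoff` (`exclude = "auto"`); `exclude = "none"`
#' keeps all points. Automatic exclusion is iterative — one worst point
#' per refit — because simultaneous outliers mask one another in a single
#' residual pass.
#'
#' With `exclude = "auto"` a robust (M-estimator) pre-fit screens for
#' points whose scaled residual exceeds `cutoff` before the OLS pass;
#' gross outliers would otherwise inflate the OLS residual scale enough
#' to mask one another entirely.
#'
#' @param a_in_MBq activities at the common reference time, MBq.
#' @param m_gd_ug Gd masses, ug.
#' @param exclude `"none"`, `"auto"`, or integer indices to drop.
#' @param cutoff studentized-residual cutoff for `exclude = "auto"`.
#' @param reference_time timestamp the activities refer to.
#' @param through_origin fit without intercept.
#' @return An [alpha_coefficient()] with `fit_details` (slope, intercept,
#'   their standard errors, excluded indices).
#' @export
fit_alpha <- function(a_in_MBq, m_gd_ug, exclude = "none", cutoff = 3,
                      reference_time = 0, through_origin = FALSE) {
  stopifnot(length(a_in_MBq) == length(m_gd_ug))
  keep <- seq_along(a_in_MBq)
  excluded <- integer(0)
  if (is.numeric(exclude)) {
    excluded <- as.integer(exclude)
    keep <- setdiff(keep, excluded)
  }
  fit1 <- function(idx) {
    a <- a_in_MBq[idx]
    m <- m_gd_ug[idx]
    if (length(idx) < 2L) stop("fewer than 2 retained samples",
                               call. = FALSE)
    if (stats::var(a) == 0) {
      stop("degenerate design: no variance in activity", call. = FALSE)
    }
    if (through_origin) stats::lm(m ~ a + 0) else stats::lm(m ~ a)
  }
  if (length(keep) < 2L) {
    stop("fewer than 2 retained samples", call. = FALSE)
  }
  if (identical(exclude, "auto")) {
    ## robust screen first: OLS residual scale is inflated by the very
    ## outliers being hunted, so simultaneous gross outliers mask each
    ## other in a plain studentized-residual pass
    av <- a_in_MBq[keep]
    mv <- m_gd_ug[keep]
    rfit <- suppressWarnings(
      if (through_origin) MASS::rlm(mv ~ av + 0, maxit = 100) else
        MASS::rlm(mv ~ av, maxit = 100))
    scaled <- abs(stats::residuals(rfit)) / max(rfit$s, 1e-12)
    bad <- which(scaled > cutoff)
    if (length(bad) && length(keep) - length(bad) >= 2L) {
      excluded <- c(excluded, keep[bad])
      keep <- setdiff(keep, keep[bad])
    }
    fit <- fit1(keep)
    repeat {
      rs <- stats::rstudent(fit)
      worst <- which.max(abs(rs))
      if (length(worst) == 0L || !is.finite(rs[worst]) ||
          abs(rs[worst]) <= cutoff || length(keep) <= 3L) {
        break
      }
      excluded <- c(excluded, keep[worst])
      keep <- setdiff(keep, keep[worst])
      fit <- fit1(keep)
    }
  } else {
    fit <- fit1(keep)
  }
  cf <- suppressWarnings(summary(fit))$coefficients
  slope_row <- if (through_origin) 1L else 2L
  slope <- cf[slope_row, "Estimate"]
  slope_se <- cf[slope_row, "Std. Error"]
  intercept <- if (through_origin) 0 else cf[1L, "Estimate"]
  intercept_se <- if (through_origin) 0 else cf[1L, "Std. Error"]
  if (slope <= 0) stop("fitted coefficient is non-positive", call. = FALSE)
  alpha_coefficient(
    slope, reference_time, "fitted",
    fit_details = list(slope = slope, slope_se = slope_se,
                       intercept = intercept, intercept_se = intercept_se,
                       excluded = excluded, n_used = length(keep)))
}

#' In-Gd coefficient from injection-preparation proportions
#'
#' @param m_gd_prep_ug Gd mass in the preparation, ug (> 0).
#' @param a_prep_MBq In-111 activity at preparation time, MBq (> 0).
#' @param preparation_time timestamp of the preparation.
#' @return An [alpha_coefficient()] with method `"calculated"`.
#' @export
alpha_from_preparation <- function(m_gd_prep_ug, a_prep_MBq,
                                   preparation_time = 0) {
  if (!is.finite(m_gd_prep_ug) || m_gd_prep_ug <= 0 ||
      !is.finite(a_prep_MBq) || a_prep_MBq <= 0) {
    stop("preparation mass and activity must both be > 0", call. = FALSE)
  }
  alpha_coefficient(m_gd_prep_ug / a_prep_MBq, preparation_time,
                    "calculated")
}

#' Gadolinium mass from an imaged activity
#'
#' Back-corrects the activity measured at `t_img` to the coefficient's
#' reference time and multiplies: the Gd mass itself is time-invariant,
#' so `m = alpha(t_ref) * A(t_img) / decay_factor(t_img - t_ref)`.
#'
#' @param activity_MBq In-111 activity measured at `t_img`, MBq.
#' @param alpha an [alpha_coefficient()].
#' @param t_img imaging timestamp.
#' @param t_half_s half-life in seconds.
#' @return Gd mass in ug.
#' @export
gd_mass <- function(activity_MBq, alpha, t_img = alpha$reference_time,
                    t_half_s = in111_half_life_s()) {
  stopifnot(inherits(alpha, "alpha_coefficient"))
  if (is.null(t_img)) stop("imaging time is required", call. = FALSE)
  dt <- as_seconds(t_img) - alpha$reference_time
  a_ref <- activity_MBq / decay_factor(dt, t_half_s)
  alpha$value * a_ref
}

#' Quadrature combination of relative uncertainties
#'
#' The activity-measurement uncertainty budget: the count-rate spread in
#' the VOI, the mask-selection term (10%) and the reference gamma-counter
#' term (2%) combined in quadrature.
#'
#' @param count_rate_rel,mask_rel,reference_rel relative (fractional)
#'   components, each in [0, 1).
#' @return combined relative uncertainty (fraction).
#' @export
uncertainty_quadrature <- function(count_rate_rel, mask_rel = 0.10,
                                   reference_rel = 0.02) {
  comps <- c(count_rate_rel, mask_rel, reference_rel)
  if (any(comps < 0) || any(comps >= 1)) {
    stop("uncertainty components must lie in [0, 1)", call. = FALSE)
  }
  sqrt(sum(comps^2))
}
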