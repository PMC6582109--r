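#' In-111 half-life in seconds
#'
#' Default 2.8047 days; the commonly quoted rounded value 2.8 days can be
#' requested instead wherever a half-life is accepted.
#'
#' @param days half-life in days.
#' @return seconds.
#' @export
in111_half_life_s <- function(days = 2.8047) days * 86400

#' Acquisition timing record
#'
#' Book-keeping for all decay corrections: acquisition start `t0`,
#' acquisition duration `tacq_s`, activity-calibration time `tcal`, and
#' the radionuclide half-life. Timestamps may be POSIXct, ISO-8601
#' strings, or plain numeric seconds; internally everything is seconds
#' relative to `t0`.
#'
#' @param t0 acquisition start.
#' @param tacq_s acquisition duration in seconds (> 0).
#' @param tcal activity-calibration timestamp (default: `t0`).
#' @param t_half_s radionuclide half-life in seconds (> 0); default
#'   In-111.
#' @return An object of class `acquisition_timing`.
#' @export
acquisition_timing <- function(t0 = 0, tacq_s = 300, tcal = t0,
                               t_half_s = in111_half_life_s()) {
  t0 <- as_seconds(t0)
  tcal <- as_seconds(tcal)
  if (!is.finite(tacq_s) || tacq_s <= 0) {
    stop("`tacq_s` must be > 0", call. = FALSE)
  }
  if (!is.finite(t_half_s) || t_half_s <= 0) {
    stop("`t_half_s` must be > 0", call. = FALSE)
  }
  structure(list(t0 = t0, tacq_s = tacq_s, tcal = tcal,
                 t_half_s = t_half_s),
            class = "acquisition_timing")
}

as_seconds <- function(t) {
  if (inherits(t, "POSIXt")) return(as.numeric(t))
  if (is.character(t)) {
    p <- as.POSIXct(t, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                   "%Y-%m-%d"))
    return(as.numeric(p))
  }
  as.numeric(t)
}

#' Radioactive decay factor
#'
#' `exp(-ln2 * delta_t / t_half)`: the fraction of activity remaining
#' after `delta_t`. Negative `delta_t` back-corrects (factor > 1).
#'
#' @param delta_t_s elapsed time in seconds (may be negative).
#' @param t_half_s half-life in seconds.
#' @return dimensionless fraction.
#' @export
decay_factor <- function(delta_t_s, t_half_s = in111_half_life_s()) {
  stopifnot(t_half_s > 0)
  exp(-log(2) * delta_t_s / t_half_s)
}

## (Tacq/T1/2 * ln2) / (1 - exp(-Tacq/T1/2 * ln2)): ratio of the start-of-
## acquisition count rate to the rate averaged over the acquisition.
decay_during_acquisition <- function(tacq_s, t_half_s) {
  x <- log(2) * tacq_s / t_half_s
  ## series expansion below x ~ 1e-4 avoids cancellation in 1 - exp(-x)
  if (x < 1e-4) return(1 + x / 2 + x^2 / 12)
  x / (1 - exp(-x))
}

#' Calibration factor (volume sensitivity)
#'
#' @param s_vol sensitivity in cps/MBq (> 0).
#' @param relative_uncertainty fractional uncertainty on `s_vol`.
#' @param c_vol_kBq_per_mL,v_voi_mL the source concentration and VOI
#'   volume the factor was derived from (optional provenance).
#' @return An object of class `calibration_factor`.
#' @export
calibration_factor <- function(s_vol, relative_uncertainty = 0,
                               c_vol_kBq_per_mL = NA_real_,
                               v_voi_mL = NA_real_) {
  if (!is.finite(s_vol) || s_vol <= 0) {
    stop("`s_vol` must be > 0", call. = FALSE)
  }
  structure(list(s_vol = s_vol, relative_uncertainty = relative_uncertainty,
                 c_vol_kBq_per_mL = c_vol_kBq_per_mL, v_voi_mL = v_voi_mL),
            class = "calibration_factor")
}

#' NEMA-style volume sensitivity from a calibration acquisition
#'
#' Computes
#' `S_Vol = R / (c_Vol * V_VOI) * exp((T0 - Tcal)/T1/2 * ln2)
#'  * (Tacq/T1/2 * ln2) / (1 - exp(-Tacq/T1/2 * ln2))`
#' where `R` is the VOI count rate of a uniform source of concentration
#' `c_Vol` (measured at `Tcal`) filling volume `V_VOI`. The first
#' exponential refers the source activity to the acquisition start; the
#' last factor undoes the decay during the acquisition. The result is
#' expressed in cps/MBq.
#'
#' @param R_cps VOI count rate in cps (> 0).
#' @param c_vol_kBq_per_mL source concentration at `Tcal` in kBq/mL (> 0).
#' @param v_voi_mL VOI volume in mL (> 0).
#' @param timing an [acquisition_timing()].
#' @param relative_uncertainty optional fractional uncertainty attached to
#'   the result.
#' @return A [calibration_factor()] with `s_vol` in cps/MBq.
#' @export
volume_sensitivity <- function(R_cps, c_vol_kBq_per_mL, v_voi_mL, timing,
                               relative_uncertainty = 0) {
  stopifnot(inherits(timing, "acquisition_timing"))
  if (R_cps <= 0 || c_vol_kBq_per_mL <= 0 || v_voi_mL <= 0) {
    stop("R, c_vol and v_voi must all be > 0", call. = FALSE)
  }
  a_MBq <- c_vol_kBq_per_mL * v_voi_mL / 1000  # source activity at Tcal
  s <- R_cps / a_MBq *
    exp((timing$t0 - timing$tcal) / timing$t_half_s * log(2)) *
    decay_during_acquisition(timing$tacq_s, timing$t_half_s)
  calibration_factor(s, relative_uncertainty, c_vol_kBq_per_mL, v_voi_mL)
}

#' Activity from a VOI count rate
#'
#' Inverts the calibration: `A(T0) = R / S_Vol`, then decay-corrects from
#' the acquisition start to `report_time`.
#'
#' @param R_voi_cps VOI count rate in cps.
#' @param calib a [calibration_factor()].
#' @param timing an [acquisition_timing()].
#' @param report_time timestamp at which the activity is reported
#'   (default: `T0`).
#' @return activity in MBq at `report_time`.
#' @export
activity_from_rate <- function(R_voi_cps, calib, timing,
                               report_time = timing$t0) {
  stopifnot(inherits(calib, "calibration_factor"),
            inherits(timing, "acquisition_timing"))
  a0 <- R_voi_cps / calib$s_vol
  a0 * decay_factor(as_seconds(report_time) - timing$t0, timing$t_half_s)
}
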