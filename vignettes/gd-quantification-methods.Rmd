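---
title: "Quantifying In-111-labelled gadolinium nanoparticles from SPECT/CT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying In-111-labelled gadolinium nanoparticles from SPECT/CT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

Gadolinium nanoparticles are studied as radiosensitizers: the absorbed-dose
enhancement they produce depends on how much gadolinium actually sits in the
tumour, so a non-invasive readout of Gd mass per organ is needed for
treatment planning. Gd itself is invisible to emission tomography, but the
particles can be labelled with ¹¹¹In (half-life 2.8047 d, gammas at
171.3 keV with 90.61% emission probability and 245.4 keV with 94.12%).
`gdspect` implements the image-domain chain that turns reconstructed
small-animal SPECT/CT volumes into a calibrated ¹¹¹In activity and, through
the In–Gd proportionality coefficient, into a Gd mass with an uncertainty.
Because no raw scanner data can be distributed, the package also ships a
digital-phantom simulator producing every input the chain needs with known
ground truth; all tests and headline numbers are computed on those
phantoms.

## The quantification model

For a volume of interest (VOI) with count rate $R$ (cps) in the corrected
image, the activity is $A = R / S_\mathrm{Vol}$, where the volume
sensitivity is measured on a uniform calibration source of concentration
$c_\mathrm{Vol}$ filling $V_\mathrm{VOI}$:

$$
S_\mathrm{Vol} = \frac{R}{c_\mathrm{Vol} V_\mathrm{VOI}}
\exp\!\Big(\tfrac{T_0 - T_\mathrm{cal}}{T_{1/2}}\ln 2\Big)
\cdot \frac{T_\mathrm{acq}\ln 2 / T_{1/2}}
{1 - \exp(-T_\mathrm{acq}\ln 2 / T_{1/2})}.
$$

The first exponential refers the source activity from its calibration time
to the acquisition start; the last factor undoes the decay during the
acquisition (it is $\ge 1$ and increasing in $T_\mathrm{acq}$; a series
expansion is used below $x \sim 10^{-4}$ to avoid cancellation). The Gd
mass follows from $\alpha_\mathrm{InGd}(t) = m_\mathrm{Gd}/A_\mathrm{In}(t)$,
either *calculated* from the preparation proportions or *fitted* by
ordinary least squares of mass on activity over paired samples. The mass
itself is time-invariant: `gd_mass()` back-corrects the imaged activity to
the coefficient's reference time, which makes the result independent of
the chosen common reference time (a property the tests assert to 1e-10).

## Correction chain

**Scatter (DEW).** Each photopeak window is corrected as
$P_p' = \max(0,\, P_p - k_p S)$ with
$k_p = \tfrac{w_p}{w_s}\,\mathrm{split}_p$, where $w$ are window widths in
keV and $S$ the 209 keV window image. How the single scatter estimate is
apportioned between the two peaks is not prescribed anywhere we could
anchor it, so the split defaults to an even 0.5/0.5 and is exposed for
sensitivity analyses. Negative voxels are clipped to zero and counted —
count rates are physical. Note the nominal 10% windows overlap at their
edges (the 245.4 keV window starts 9 keV inside the scatter window);
validation therefore only requires that no photopeak *centre* lies inside
the scatter window.

**Attenuation (Chang).** CT numbers are converted to linear attenuation
coefficients with a bilinear model anchored at air (−1000 HU → 0), water
(0 HU → 0.0146/mm at 171.3 keV, 0.0127/mm at 245.4 keV) and cortical bone
(1000 HU → 0.0270 and 0.0225/mm); the constants are NIST-derived and live
in `attenuation_model()`, never hard-coded in operations. For each voxel
inside the body (CT ≥ −400 HU, largest component), the transmission
$e^{-\int \mu\,dl}$ is averaged over 64 equally spaced in-plane rays and
inverted to an attenuation correction factor (ACF). Rays are cast in 2-D
per slice — the axial coverage of the emulated scanner is short (25 mm) —
with fixed-step midpoint sampling (half the smallest voxel dimension) and
bilinear interpolation of $\mu$; the integral runs to the grid edge, where
$\mu$ vanishes outside the body. The two per-peak ACF maps are combined
voxelwise as $0.635\,\mathrm{ACF}_{171} + 0.365\,\mathrm{ACF}_{245}$;
on a rat-sized 40 mm water cylinder this weighted combination changes the
recovered total by well under 1% relative to correcting the two windows
separately, which is why a single combined map is the default.

**Partial volume (two-region Müller-Gärtner).** The background level $b$
is the image mean over the background mask eroded by one PSF FWHM (so
target spill-out does not contaminate it; if erosion empties the mask the
uneroded mean is used with a warning). Spill-in is removed by subtracting
$b \cdot (\mathrm{PSF} \otimes \mathbb{1}_\mathrm{bg})$, spill-out restored
by dividing by $\mathrm{PSF} \otimes \mathbb{1}_\mathrm{tgt}$ wherever that
smoothed indicator exceeds a recovery floor of 0.1 — the floor prevents
division blow-up at the VOI rim and is configurable. Outside the target
the result is masked to zero. With a delta PSF the correction is exactly
the identity on the target, which the tests assert.

## VOI selection

Three procedures, matching three imaging situations:

* **CT threshold** (phantoms, ex vivo tubes): binarize at a configurable
  HU threshold (default −400; −500 separates water from air cleanly),
  keep the largest 26-connected component. CT-derived masks are
  nearest-resampled onto the SPECT grid before quantification.
* **Kidney** (functional border usable): threshold the SPECT image at a
  fraction of its regional maximum, keep the largest component, erode
  (default 1 voxel, configurable) so PVE spill-out does not push the
  border past the anatomy.
* **Tumour** (heterogeneous uptake): blur with σ of 1.5 voxel sizes per
  axis, threshold at 8% of the blurred maximum within a user-supplied
  local region, keep the largest component, dilate by 2 voxels.

The "local region" is an explicit bounding box recorded with the result —
the procedure is only reproducible if the region is logged. Thresholds
are relative, so all masks are invariant to rescaling the image.
Morphology uses a 6-connected structuring element; components use
26-connectivity; both are pinned so voxel-exact tests are meaningful.

## The simulator, and what passing tests mean

The forward model works in the reconstruction domain — it emulates the
*output* of the vendor OSEM reconstruction rather than projecting and
reconstructing, since reconstruction belongs to the scanner software.
Per photopeak $p$:

$$
P_p = S\, b_p \cdot \mathrm{PSF} \otimes (A \cdot T_p) ,\qquad
T_p = \mathrm{ACF}_p^{-1},
$$

with $S$ the sensitivity (2110 cps/MBq), $b_p$ the branching probability,
and $T_p$ the voxelwise angle-averaged transmission computed by the *same*
Chang integrator the correction uses — deliberately, so the attenuation
correction can be validated in isolation. In-peak scatter is a broad
Gaussian tail (default 10 mm) of the primaries scaled by the scatter
fraction (default 0.2); the 209 keV window receives both peaks' tails
scaled by the width ratios. Poisson noise is applied to expected counts
over a single effective duration (300 s) and divided back to rates.

This matched-forward-model design is an inverse crime when used naively:
agreement between simulation and correction shows the corrections invert
the degradations they model, not that the model captures a real scanner.
Real acquisitions add collimator-dependent, spatially varying PSFs,
energy-dependent scatter spectra, reconstruction non-linearity and
registration error, none of which are emulated. The mismatch knobs
(`psf_fwhm_error_fraction`, `scatter_tail_width_mm`) exist precisely to
break the match in robustness checks, where only degraded-but-bounded
recovery is expected. The PSF FWHM default of 1.8 mm (three SPECT voxels)
is a free parameter — no measurement exists for the emulated collimator.

Study conditions are fixed in the generator defaults: SPECT voxels
0.6 mm, CT 0.4 mm; tubes of 500 µL holding 7.46/4.20/2.16/1.23 MBq;
a 5 mL, 0.72 kBq/mL calibration cylinder; a ~0.7 mL hot kidney cortex;
a heterogeneous union-of-spheres tumour. The calibration acquisition is
simulated noise-free: it stands in for a long dedicated protocol whose
counting noise is negligible next to the phantom runs, and at 0.72 kBq/mL
a 300 s synthetic acquisition would otherwise be dominated by Poisson
noise that the real protocol does not have.

## Numerical and design choices

* Geometry is axis-aligned (index → mm via origin + index × spacing); no
  direction cosines, and CT→SPECT registration is assumed given — only
  resampling is implemented (trilinear for CT values, nearest for masks,
  fill −1000 HU outside the CT extent).
* The vendor's resampling interpolation is unknown; linear is assumed.
* Half-life defaults to 2.8047 d; the rounded 2.8 d can be passed
  anywhere a half-life is accepted. Timestamps may be ISO-8601, POSIXct
  or seconds; internally everything is seconds relative to T0.
* The count-rate uncertainty component is the per-voxel population SD
  over the mean scaled by $1/\sqrt{n}$ (the spread of the VOI mean); the
  budget adds 10% for mask selection and 2% for the reference counter in
  quadrature. Calibration-factor uncertainty is folded into the 2% term.
* `fit_alpha()` fits with intercept by default (through-origin by flag).
  Outlier handling defaults to an explicit, logged index list; the
  optional automatic rule screens with a robust M-estimator fit before
  the studentized-residual loop, because simultaneous gross outliers
  inflate the OLS residual scale enough to mask one another.
* The volume sensitivity is always computed after the full correction
  chain, including the partial-volume stage, even when the analysis that
  consumes it omits PVE (large-container ex vivo runs); calibrating a
  partial chain with itself is available for stage-isolation studies
  (`force_pve = FALSE`).
* Degenerate inputs fail loudly: empty body masks, empty VOIs after
  erosion, targets smaller than the PSF (smoothed indicator below the
  recovery floor everywhere), non-finite voxels (reported with their
  index), rank-deficient fits.

## Problem sizes

The test-suite and acceptance runs use 20 seeded replicates per phantom
condition for the stochastic recovery bounds, 10 seeds for the four-tube
linearity regression, 150 replicates for the Poisson-mean check on a
coarse (1.2 mm) tube, and single deterministic runs for the dual-peak
weighting and correction-ladder analyses. These sizes keep every Monte
Carlo standard error far below the tolerances being asserted.

## Interface

The package's functions are the API; the numbered scripts under
`analysis/` are the runnable front end (simulate → calibrate → quantify
tubes → kidney correction ladder → tumour Gd mass), each writing its
tables under `results/`. A typical in-memory session:

```{r}
library(gdspect)

cfg <- simulation_config(seed = 1)
tim <- acquisition_timing()
cal <- nema_calibration(cfg, pipeline_params(), tim)

ras <- rasterize_phantom(phantom_tube(7.46))
w <- simulate_windows(ras$activity, ras$ct, cfg)
res <- run_pipeline(w, ras$ct, cal, tim,
                    alpha = alpha_from_preparation(36.4, 40))
res
```

## Known limitations

Beyond the inverse-crime caveat above: no projection-space modelling
(multiplexing pinholes, collimator-detector response, CT beam hardening);
no dead-time or pile-up handling; scatter is a single spatially invariant
kernel; the Chang integrator ignores axial attenuation paths; DICOM
series are not read (MetaImage and NIfTI only); and the In–Gd coefficient
is only as good as the assumption that Gd and ¹¹¹In stay together — when
metabolic clearance separates them, as the kidney analyses illustrate,
the indirect mass estimate degrades no matter how accurate the activity
quantification is.
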