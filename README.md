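# gdspect

Quantification of ¹¹¹In-labelled gadolinium nanoparticles from
reconstructed small-animal SPECT/CT images.

Gadolinium nanoparticles are candidate radiosensitizers: the dose
enhancement they deliver depends on the Gd mass concentrated in the
tumour, so treatment planning needs a non-invasive Gd readout. Gd emits
nothing a gamma camera can see, but the particles can be labelled with
¹¹¹In (T₁/₂ = 2.8 d; gammas at 171.3 keV / 90.61% and 245.4 keV / 94.12%).
This package implements the full image-domain chain from window count-rate
images to a Gd mass with uncertainty:

* **Scatter**: dual-energy-window subtraction — each photopeak corrected by
  a width-scaled share of the 209 keV window, `P'_p = max(0, P_p − k_p S)`.
* **Attenuation**: Chang's multiplicative method — bilinear HU→μ
  conversion, angle-averaged in-plane transmission per voxel, and one
  combined ACF map weighted `0.635 · ACF₁₇₁ + 0.365 · ACF₂₄₅`.
* **Partial volume**: two-region Müller-Gärtner correction (background
  spill-in subtracted, spill-out restored by dividing by the PSF-smoothed
  target indicator).
* **Calibration**: NEMA-style volume sensitivity
  `S_Vol = R/(c_Vol·V_VOI) · exp((T₀−T_cal)ln2/T₁/₂) · (T_acq ln2/T₁/₂)/(1−exp(−T_acq ln2/T₁/₂))`,
  with all decay bookkeeping explicit.
* **VOI selection**: CT binarization (phantoms/ex vivo), SPECT threshold +
  erosion (kidney), and blur → 8%-of-local-max threshold → dilate-by-2
  (tumour).
* **Gd mass**: `m_Gd = α_InGd(t) · A_In(t)` with the In–Gd coefficient
  either calculated from preparation proportions or fitted across paired
  samples (with logged outlier exclusion), and the uncertainty budget
  combined in quadrature (count-rate spread ⊕ 10% mask ⊕ 2% reference).

Because no scanner data are distributable, the package includes a
digital-phantom simulator (tubes, kidney with hot cortex, heterogeneous
tumour blobs; PSF blur, window-dependent scatter, CT-derived attenuation,
Poisson noise) that produces every input with known ground truth. The
methods vignette (`vignettes/gd-quantification-methods.Rmd`) documents the
models, defaults and limitations.

## Worked example

The analysis workflow lives in `analysis/01…05`. Steps: simulate the
phantom set, calibrate, quantify the four-tube series, walk the correction
ladder on a kidney, and estimate a tumour Gd mass. For example:

```sh
Rscript analysis/02_calibration.R
Rscript analysis/03_tube_quantification.R
```

prints (tables land in `results/`):

```
volume sensitivity S_Vol = 3885.6 cps/MBq
residual chain bias absorbed by calibration: -0.31%

measured vs true activity:
 true_MBq measured_MBq      rel_err
     7.46     7.387326 -0.009741889
     4.20     4.156976 -0.010243706
     2.16     2.137495 -0.010418752
     1.23     1.217894 -0.009842373

linear fit: slope 0.9903, intercept -0.0012 MBq
max |relative error|: 1.16%
```

i.e. the fully corrected chain recovers tube activities to ~1% with an
essentially unit slope. The kidney script shows why the corrections
matter — the cortex activity is 34% low uncorrected, 32% after scatter,
24% after scatter+attenuation, and 0.6% off with the partial-volume stage
added:

```
             corrections measured_MBq      rel_err
                    none     1.878474 -0.341029198
                 scatter     1.929350 -0.323181858
     scatter+attenuation     2.164144 -0.240815955
 scatter+attenuation+pve     2.866832  0.005687681
```

In-memory, a single acquisition is:

```r
library(gdspect)
cfg <- simulation_config(seed = 1)
tim <- acquisition_timing()
cal <- nema_calibration(cfg, pipeline_params(), tim)
ras <- rasterize_phantom(phantom_tube(7.46))
w   <- simulate_windows(ras$activity, ras$ct, cfg)
run_pipeline(w, ras$ct, cal, tim)
#> <quant_result> A = 7.385 MBq (rel. unc. 0.102), R = 28696 cps, VOI 0.531 mL
#>   corrections: scatter + attenuation + pve
```

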