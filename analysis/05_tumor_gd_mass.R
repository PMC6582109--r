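#!/usr/bin/env Rscript

## Step 5 — tumour Gd mass through the In-Gd coefficient.
##
## A heterogeneous tumour holding 2.55 MBq is imaged two days after a
## preparation whose proportions give alpha_calc(t0) = 0.91 ug/MBq. The
## tumour VOI comes from the SPECT image itself (blur, 8% local
## threshold, dilate 2) because the activity border does not follow the
## anatomy. The Gd mass is computed twice: with the calculated
## coefficient, and with a coefficient fitted on paired activity/mass
## samples containing two metabolically shifted outliers — reproducing
## the observation that the calculated coefficient tracks the reference
## better when clearance alters the fitted one.

suppressPackageStartupMessages(library(gdspect))
dir.create("results", showWarnings = FALSE)

cfg <- simulation_config(seed = 5)
par <- pipeline_params()
tim <- acquisition_timing()
cal <- nema_calibration(cfg, par, tim)

th <- tim$t_half_s
t_prep <- -2 * 86400          # preparation two days before imaging (t0 = 0)
alpha_calc <- alpha_from_preparation(m_gd_prep_ug = 0.91 * 40,
                                     a_prep_MBq = 40,
                                     preparation_time = t_prep)

a_img_true <- 2.55
ras <- rasterize_phantom(phantom_tumor(a_img_true))
## the tumour's true Gd load follows the preparation proportions
gd_true <- gd_mass(a_img_true, alpha_calc, t_img = 0, t_half_s = th)

w <- simulate_windows(ras$activity, ras$ct, cfg)
corr <- correct_windows(w, ras$ct, par)
mask <- tumor_voi(corr$stages$attenuation, par$voi)
final <- mgm_correct(corr$stages$attenuation, mask, NULL, par$psf)
rate <- voi_count_rate(final, mask)
a_meas <- activity_from_rate(rate$R_cps, cal, tim)
unc <- uncertainty_quadrature(rate$sd_rel)

cat(sprintf("true activity %.3f MBq; measured %.3f MBq (%+.2f%%)\n",
            a_img_true, a_meas, 100 * (a_meas / a_img_true - 1)))
cat(sprintf("SPECT-derived VOI: %.3f mL (%s)\n", mask_volume_mL(mask),
            mask$provenance))

## fitted coefficient from paired samples; two samples suffer a different
## Gd / In-111 clearance and are excluded by an explicit index list, the
## judgment-based default (exclude = "auto" also drops both, and with so
## few points at 2% spread it prunes borderline ones as well)
set.seed(cfg$seed)
a_samples <- seq(1, 5, length.out = 8)
m_samples <- alpha_calc$value * a_samples * (1 + rnorm(8, sd = 0.02))
m_samples[c(3, 6)] <- m_samples[c(3, 6)] * c(0.45, 0.35)
fit <- fit_alpha(a_samples, m_samples, exclude = c(3, 6),
                 reference_time = t_prep)

m_from_calc <- gd_mass(a_meas, alpha_calc, t_img = 0, t_half_s = th)
m_from_fit <- gd_mass(a_meas, fit, t_img = 0, t_half_s = th)

tab <- data.frame(
  coefficient = c("calculated", "fitted"),
  alpha_ug_per_MBq_at_t0 = c(alpha_calc$value, fit$value),
  gd_measured_ug = c(m_from_calc, m_from_fit),
  gd_reference_ug = gd_true,
  rel_diff = c(m_from_calc, m_from_fit) / gd_true - 1,
  rel_uncertainty = unc)
write.csv(tab, "results/tumor_gd_mass.csv", row.names = FALSE)
print(tab, row.names = FALSE)
cat(sprintf("\nexcluded sample indices in the fit: %s\n",
            paste(fit$fit_details$excluded, collapse = ", ")))
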