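#!/usr/bin/env Rscript

## Step 1 — define the study phantoms and their ground truth.
##
## Builds the digital phantoms used throughout the analysis (the four-tube
## in vitro set, the NEMA calibration cylinder, a kidney with a hot cortex
## and a heterogeneous tumour), writes their specifications as YAML, and
## rasterizes one example acquisition to volumetric images so the ground
## truth can be inspected.

suppressPackageStartupMessages(library(gdspect))

out <- "results/phantoms"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

tube_activities <- c(7.46, 4.20, 2.16, 1.23)  # MBq at imaging time
specs <- c(
  setNames(lapply(tube_activities, phantom_tube),
           sprintf("tube_%0.2fMBq", tube_activities)),
  list(calibration = phantom_calibration(),
       kidney = phantom_kidney(3.0),
       tumor = phantom_tumor(2.55)))

truth <- do.call(rbind, lapply(names(specs), function(nm) {
  ras <- rasterize_phantom(specs[[nm]])
  write_phantom_spec(specs[[nm]], file.path(out, paste0(nm, ".yaml")))
  data.frame(phantom = nm,
             n_shapes = length(specs[[nm]]$shapes),
             total_activity_MBq = ras$total_activity_MBq,
             hot_volume_mL = sum(vapply(
               seq_along(ras$truth_masks), function(i) {
                 if (specs[[nm]]$shapes[[i]]$activity_MBq_per_mL > 0)
                   mask_volume_mL(ras$truth_masks[[i]]) else 0
               }, numeric(1))))
}))
write.csv(truth, "results/phantom_ground_truth.csv", row.names = FALSE)
cat("phantom ground truth:\n")
print(truth, row.names = FALSE)

## one example acquisition written as images (window images + CT + truth)
ras <- rasterize_phantom(specs$tube_7.46MBq)
w <- simulate_windows(ras$activity, ras$ct, simulation_config(seed = 1))
write_image(ras$ct, file.path(out, "tube_7.46MBq_ct.nii.gz"))
write_image(w$peak1_img, file.path(out, "tube_7.46MBq_peak171.nii.gz"),
            window = "peak171")
write_image(w$scatter_img, file.path(out, "tube_7.46MBq_scatter209.nii.gz"),
            window = "scatter209")
write_image(w$peak2_img, file.path(out, "tube_7.46MBq_peak245.nii.gz"),
            window = "peak245")
jsonlite::write_json(
  list(phantom = "tube_7.46MBq", seed = 1,
       true_total_MBq = ras$total_activity_MBq,
       truth_mask_voxels = sum(ras$truth_masks[[1]]$values)),
  file.path(out, "tube_7.46MBq_truth.json"), auto_unbox = TRUE, digits = NA)
cat("\nwrote example acquisition (0.6 mm SPECT windows, 0.4 mm CT) under",
    out, "\n")
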