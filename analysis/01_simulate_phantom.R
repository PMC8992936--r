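#!/usr/bin/env Rscript
# Build the synthetic head-and-neck phantom CT and its sCT surrogate, and
# check the voxelized bone volume against the closed-form solid volumes.
library(posequiv)

dir.create("results", showWarnings = FALSE)
seed <- 1L

spec <- phantom_spec(seed = seed)
ph <- make_phantom(spec)
sct <- make_sct_surrogate(ph$volume, blur_sigma_mm = 1.5,
                          bone_contrast_scale = 0.8, noise_sd_hu = 20,
                          seed = seed)

write_volume(ph$volume, "results/phantom_ct.nii.gz", datatype = "int16")
write_volume(sct, "results/phantom_sct.nii.gz")

frac <- mean(ph$volume$data >= 200 & ph$volume$data <= 1700)
analytic <- phantom_bone_volume(spec) /
  prod(dim(ph$volume$data) * ph$volume$spacing)

tab <- data.frame(
  quantity = c("grid", "spacing_mm", "bone_voxel_fraction",
               "bone_analytic_fraction", "relative_error"),
  value = c(paste(dim(ph$volume$data), collapse = "x"),
            paste(ph$volume$spacing, collapse = "x"),
            signif(frac, 5), signif(analytic, 5),
            signif(abs(frac - analytic) / analytic, 3)))
write.csv(tab, "results/phantom_summary.csv", row.names = FALSE)

cat(sprintf(paste0(
  "Phantom: %s voxels at %s mm; bone occupies %.3f%% of the grid, vs\n",
  "%.3f%% from the closed-form solid volumes (relative error %.2f%%).\n",
  "sCT surrogate written with 1.5 mm blur, 0.8 bone contrast, 20 HU noise.\n"),
  paste(dim(ph$volume$data), collapse = "x"),
  paste(ph$volume$spacing, collapse = "x"),
  100 * frac, 100 * analytic, 100 * abs(frac - analytic) / analytic))
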