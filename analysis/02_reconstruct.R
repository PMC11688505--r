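#!/usr/bin/env Rscript
# Reconstruct the low-dose scan with the two filters (Ram-Lak attenuation,
# Hilbert electron density) and score the noisy FBP against the noiseless
# ground truth. Establishes the baseline the denoisers must beat.
# Requires 01_simulate.R to have run.

library(gbpcct)

inp <- file.path("results", "01_simulation")
out <- file.path("results", "02_reconstruction")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sino <- read_sinogram_pair(file.path(inp, "sino_low_dose"))
gt_att <- read_tomogram(file.path(inp, "ground_truth_attenuation.tif"))
gt_ed <- read_tomogram(file.path(inp, "ground_truth_electron_density.tif"))

fbp_att <- reconstruct_attenuation(sino)
fbp_ed <- reconstruct_electron_density(sino, phase_sensitivity = 24)
write_tomogram(fbp_att, file.path(out, "fbp_attenuation.tif"))
write_tomogram(fbp_ed, file.path(out, "fbp_electron_density.tif"))

cat("noisy FBP vs noiseless ground truth:\n\nattenuation:\n")
rep_att <- assess_stack(fbp_att, gt_att)
print(rep_att)
write_iqa_report(rep_att, file.path(out, "iqa_fbp_attenuation.csv"))

cat("\nelectron density:\n")
rep_ed <- assess_stack(fbp_ed, gt_ed)
print(rep_ed)
write_iqa_report(rep_ed, file.path(out, "iqa_fbp_electron_density.csv"))
cat(sprintf("\noutputs under %s\n", out))
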