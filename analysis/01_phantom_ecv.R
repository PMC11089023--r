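#!/usr/bin/env Rscript
# Phantom study of the ECV imaging stage.
#
# Builds paired-phase CT phantoms with known ground-truth extracellular
# volume, pushes them through the ECV pipeline (delta-HU, blood-pool
# normalisation, hematocrit correction, VOI extraction), and quantifies
# (a) exactness of recovery without noise, (b) degradation with HU noise,
# and (c) sensitivity to voxel misregistration between the phases.

suppressPackageStartupMessages(library(ecvrisk))
dir.create("results", showWarnings = FALSE)

recover <- function(ph, pvp = NULL) {
  pair <- if (is.null(pvp)) ph$pair else phase_volume_pair(ph$pair$unenhanced, pvp)
  delta <- compute_delta_hu(pair)
  da <- blood_pool_delta(delta, ph$aorta_mask)
  mean_ecv_in_voi(compute_ecv_map(delta, da, ph$spec$hematocrit), ph$tumor_mask)
}

rows <- list()

# Noiseless recovery is exact
ph0 <- generate_phantom(phantom_spec(noise_sd = 0))
rows[[1]] <- data.frame(condition = "noiseless", noise_sd = 0, shift_vox = 0,
                        truth = ph0$truth$ecv_tumor, recovered = recover(ph0))

# Noise sweep (PVP noise in HU)
for (sd in c(2, 5, 10)) {
  ph <- generate_phantom(phantom_spec(noise_sd = sd, seed = 100 + sd))
  rows[[length(rows) + 1]] <- data.frame(
    condition = "noisy", noise_sd = sd, shift_vox = 0,
    truth = ph$truth$ecv_tumor, recovered = recover(ph))
}

# Misregistration sweep: shift the PVP phase, keep the masks fixed
for (sh in 1:3) {
  pvp <- apply_misregistration(ph0$pair$pvp, c(sh, 0, 0),
                               fill = ph0$spec$background_hu)
  rows[[length(rows) + 1]] <- data.frame(
    condition = "misregistered", noise_sd = 0, shift_vox = sh,
    truth = ph0$truth$ecv_tumor, recovered = recover(ph0, pvp))
}

tab <- do.call(rbind, rows)
tab$abs_error <- abs(tab$recovered - tab$truth)
write.csv(tab, "results/phantom_ecv.csv", row.names = FALSE)

cat("Phantom ECV recovery (ground truth", ph0$truth$ecv_tumor, "%):\n")
print(tab, row.names = FALSE, digits = 4)
cat("\nNoiseless recovery is exact; misregistration of even 1 voxel biases",
    "the VOI mean, which is why the pipeline assumes registered inputs.\n")

# Reader-agreement demonstration on two perturbed segmentations
m1 <- ph0$tumor_mask
m2 <- apply_misregistration(m1, c(1, 0, 0), fill = 0L)
d <- dice(m1, m2)
cat(sprintf("\nDice of 1-voxel-shifted re-segmentation: %.3f (%s)\n",
            d, agreement_thresholds(d)))
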