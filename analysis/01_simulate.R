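#!/usr/bin/env Rscript
# Step 1: simulate the study cohort.
#
# Generates a 31-sample synthetic cohort of spent-culture-medium Raman
# spectra (15 pregnant / 16 non-pregnant, 900-band amplitude doubled in the
# pregnant group) together with session reference spectra (toluene for
# wavenumber calibration, distilled water for background subtraction), and
# writes everything under results/cohort/.

suppressPackageStartupMessages(library(ramanivf))

cfg <- sim_config(seed = 20170930)
sim <- generate_cohort(cfg)
refs <- generate_references(cfg)

dir.create("results/cohort", recursive = TRUE, showWarnings = FALSE)
manifest <- write_synthetic_cohort(sim, "results/cohort")
write_spectrum(refs$toluene, "results/cohort/toluene.csv")
write_spectrum(refs$water, "results/cohort/water.csv")

cat("Simulated cohort:\n")
print(sim$cohort)
cat("manifest:", manifest, "\n")
cat("ground truth: results/cohort/ground_truth.json\n")
cat(sprintf("planted effect: pregnant 900-band amplitude x%g (area ratio of group means is exact)\n",
            cfg$effect_size))
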