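#!/usr/bin/env Rscript
# Step 2: preprocess the cohort.
#
# Reads the simulated manifest and applies the preprocessing chain —
# cosmic-ray despiking, toluene-based wavenumber calibration, water
# background subtraction, iterative third-order polynomial fluorescence
# correction, max-intensity normalization — and writes the processed
# spectra plus a JSON processing report under results/preprocessed/.

suppressPackageStartupMessages(library(ramanivf))

cohort <- assemble_cohort("results/cohort/manifest.csv")
toluene <- read_spectrum("results/cohort/toluene.csv")
water <- read_spectrum("results/cohort/water.csv")

pp <- run_chain(cohort, toluene, water)

dir.create("results/preprocessed", recursive = TRUE, showWarnings = FALSE)
write_cohort(pp, "results/preprocessed")
report <- list(
  n_input = n_samples(cohort),
  n_processed = n_samples(pp),
  failures = attr(pp, "failures"),
  steps = pp$spectra[[1]]$log
)
jsonlite::write_json(report, "results/preprocessed/report.json",
                     auto_unbox = TRUE, pretty = TRUE)

cat("Preprocessed", n_samples(pp), "of", n_samples(cohort), "spectra\n")
cat("chain:", paste(report$steps, collapse = " -> "), "\n")
if (length(report$failures)) {
  cat("failed samples:\n")
  for (id in names(report$failures))
    cat("  ", id, ":", report$failures[[id]], "\n")
} else cat("no failures\n")
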