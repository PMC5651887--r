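#!/usr/bin/env Rscript
# Step 5: PCA-QDA classification with leave-one-out cross-validation.
#
# PCA on the 890-950 cm-1 region of the preprocessed spectra, QDA on the
# first two principal components, LOOCV held-out predictions, ROC analysis
# with a Youden-optimal threshold on both the band-area-ratio score and the
# QDA posterior, and a confusion table; writes results/classification.json.

suppressPackageStartupMessages(library(ramanivf))

pp <- assemble_cohort("results/preprocessed/manifest.csv")
ft <- utils::read.csv("results/features.csv", stringsAsFactors = FALSE)

cv <- loocv(pp, features = ft)
print(cv)

roc_ratio <- roc_analysis(ft$r900_940, ft$label)
cat("\nROC on the 900/940 band-area ratio:\n")
print(roc_ratio)
roc_post <- roc_analysis(cv$per_sample$posterior_pregnant, cv$per_sample$label)
cat("ROC on the LOOCV QDA posterior:\n")
print(roc_post)

report <- list(
  confusion = as.list(cv$confusion),
  sensitivity_pct = 100 * cv$sensitivity,
  specificity_pct = 100 * cv$specificity,
  accuracy_pct = 100 * cv$accuracy,
  per_sample = cv$per_sample,
  roc_band_ratio = roc_ratio[c("auc", "optimal_threshold",
                               "optimal_sensitivity", "optimal_specificity",
                               "flipped")],
  roc_qda_posterior = roc_post[c("auc", "optimal_threshold",
                                 "optimal_sensitivity",
                                 "optimal_specificity", "flipped")]
)
jsonlite::write_json(report, "results/classification.json",
                     auto_unbox = TRUE, pretty = TRUE, digits = NA,
                     dataframe = "rows")
cat("\nwrote results/classification.json\n")
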