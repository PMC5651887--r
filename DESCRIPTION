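Package: ramanivf
Title: Raman Spectral Analysis of Spent Embryo Culture Media
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for Raman spectroscopic assessment of spent embryo
    culture media as a non-invasive marker of embryo reproductive potential.
    Provides cosmic-ray despiking, toluene-based wavenumber calibration,
    water-background subtraction, iterative third-order polynomial
    fluorescence correction and max-intensity normalization; Gaussian band
    component analysis over the 815-1065 and 1140-1500 cm-1 regions with
    band-area-ratio features (900/940 cm-1); Mann-Whitney U feature
    screening; and PCA followed by quadratic discriminant analysis on the
    890-950 cm-1 region with leave-one-out cross-validation, ROC analysis
    and Youden-optimal thresholding. A synthetic-spectrum cohort generator
    with recorded ground truth makes every stage testable without access to
    the original clinical spectra.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
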