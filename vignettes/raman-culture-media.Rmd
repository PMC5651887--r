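---
title: "Methods: Raman band-ratio analysis of spent embryo culture media"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Raman band-ratio analysis of spent embryo culture media}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramanivf)
```

## The problem

During in-vitro fertilization, embryos develop in individual droplets of
culture medium. What an embryo consumes from and secretes into that medium
is a metabolic fingerprint of its viability, and Raman spectroscopy can
read that fingerprint non-invasively from the spent droplet: water is a
weak Raman scatterer, so dissolved metabolites dominate the signal. The
pipeline in this package implements a complete analysis of such spectra
for a two-group cohort design (clinical pregnancy achieved or not after
single-embryo transfer, 15 and 16 samples respectively):

1. **Preprocessing** — cosmic-ray despiking, wavenumber calibration
   against a toluene standard, subtraction of a water background spectrum,
   iterative third-order polynomial fluorescence correction, and
   normalization to maximum intensity.
2. **Band component analysis** — bounded nonlinear least-squares
   decomposition of the 815–1065 and 1140–1500 cm⁻¹ regions into Gaussian
   line profiles, yielding band areas and the 900/940 cm⁻¹ band-area
   ratio as the candidate viability marker.
3. **Screening** — two-sided Mann–Whitney U tests of every band feature
   between groups.
4. **Classification** — PCA on the 890–950 cm⁻¹ channels, QDA on the
   first two principal components, leave-one-out cross-validation, ROC
   analysis with a Youden-optimal threshold, and confusion metrics with
   pregnant as the positive class.

No public dataset of such spectra exists, so the package ships a
first-class synthetic cohort generator with recorded ground truth; every
stage of the pipeline is validated against that ground truth.

## The synthetic measurement model

`generate_spectrum()` draws one spectrum as

$$ I(\nu) \;=\; \sum_j A_j e^{-(\nu-c_j)^2/2\sigma_j^2}
   \;+\; B(\nu) \;+\; W(\nu) \;+\; \varepsilon(\nu) \;+\; \text{spikes}, $$

with Gaussian bands $(c_j, \sigma_j, A_j)$, a cubic fluorescence baseline
$B$, a broad water contribution $W$, i.i.d. Gaussian detector noise
$\varepsilon$, and Poisson-count single-channel cosmic-ray spikes. The
defaults define the simulated study conditions:

* **Axis**: 600–1800 cm⁻¹ at 1 cm⁻¹ steps (1201 channels), the
  fingerprint region of a dispersive 785 nm instrument.
* **Band library**: ten bands spanning 815–1500 cm⁻¹ with widths
  6–15 cm⁻¹, including the 900 and 940 cm⁻¹ bands and a strong
  ~1003 cm⁻¹ band (the phenylalanine ring-breathing line that dominates
  protein-supplemented media and provides the normalization maximum). The
  library is an explicit stand-in: the composition of real media is not
  modeled, only the generic structure — overlapping Gaussian bands of
  plausible width and relative height.
* **Group effect**: the 900-band amplitude is multiplied by
  `effect_size` (default 2) in the pregnant group *deterministically*,
  before any noise, so the ratio of group means of true 900-band areas
  equals `effect_size` exactly and the planted effect is a sharp oracle.
* **Noise**: `noise_sd = 0.01`, i.e. 1% of the strongest band amplitude.
* **Spikes**: Poisson mean 1 per spectrum, single channel, 10–50× the
  local signal — removable without touching band shapes.
* **Water**: two very broad Gaussians (σ = 300 and 120 cm⁻¹, amplitudes
  0.10/0.15), reflecting that water contributes only a weak, smooth
  background in this region.
* **Per-sample variability**: band centers jitter by N(0, 0.5 cm⁻¹) and
  the baseline is scaled by a common factor N(1, 0.1). Amplitudes do
  **not** jitter, so the planted area-ratio effect stays exact; width
  jitter is likewise excluded because area = $A\sigma\sqrt{2\pi}$ would
  otherwise blur the oracle.
* **References**: the toluene spectrum carries narrow (σ = 2.5 cm⁻¹)
  bands at the canonical reference shifts 521.0, 785.8, 1003.6, 1030.6
  and 1210.0 cm⁻¹; an optional linear pixel-map distortion
  (observed = gain·true + offset) mislabels the axes for calibration
  round-trip tests.

What the generator does **not** emulate: instrument line-shape mixing
(Voigt profiles), wavelength-dependent detector response, correlated
(pink) noise, sample-to-sample water-path differences, or any real
biochemical difference between media. Passing tests therefore demonstrate
that the pipeline recovers what its own measurement model plants — a
necessary correctness property — not that the 900/940 ratio separates
real cohorts.

## Preprocessing choices

**Despiking.** A cosmic spike is a single-channel event, so it is
detected on the second difference of the intensity: channels whose
modified z-score $0.6745\,|d_2 - \mathrm{med}(d_2)|/\mathrm{MAD}(d_2)$
exceeds 8 are candidates. Candidates are confirmed as single-channel
events (their $|d_2|$ must exceed three times the curvature two channels
away, which leaves smooth band apexes alone even in noise-free spectra)
and removed *sequentially*: the worst offender is replaced by the median
of its 5-point neighborhood and the statistic recomputed, so the
shoulders of a removed spike are not dragged into the flag set. All
unflagged channels are returned bit-identical — a property the tests
assert literally.

**Wavenumber calibration.** Toluene apexes are located by quadratic
interpolation around local maxima *on the log intensity* (exact for a
Gaussian line), matched to the nearest canonical shift within ±15 cm⁻¹,
and a linear map (quadratic optional) from observed to reference shift is
least-squares fitted and applied. Linear is the default because a
dispersive grating spectrograph is locally linear over this span and a
two-parameter map is identifiable from two matched peaks; the map must be
monotone over the data range or calibration fails loudly.

**Water subtraction.** Default is plain subtraction (`unit`), treating
sample and background as acquired under identical exposure. Because
exposure matching cannot be guaranteed in practice, an `lsq` mode
subtracts $\alpha\,W$ with $\alpha \ge 0$ fitted over a configurable
signal-poor window.

**Fluorescence baseline.** Iterative modified polynomial fitting: fit a
cubic, clip the working spectrum to the fit, refit, until the baseline
changes by less than `tol = 1e-6` in relative Euclidean norm or 100
iterations. On band-free polynomial input the first fit is exact (the
tests require ≤ 1e-6 relative residual). On noisy spectra the clipping
decrements shrink geometrically and the iteration cap is routinely
reached first; the best iterate is returned with a `nonconv` flag and is
accurate to well below the noise level. On spectra whose true baseline is
*zero* the clipped cubic leaves a small (~1% of peak) oscillation — an
inherent property of the estimator, visible in the end-to-end clean-band
test, which asserts a realistic 2% RMS bound rather than an idealized
one.

**Normalization** divides by the maximum intensity (exactly 1 at the
maximum afterwards), and is applied last, after re-gridding the
calibrated cohort onto its common axis.

## Band fitting choices

Seeding is automatic by default: candidate centers sit at local minima of
a Savitzky–Golay second derivative whose window matches the initial band
width (8 cm⁻¹) — at 1 cm⁻¹ steps a grid-scale derivative would be pure
noise — with candidates closer than one band width merged. The fit is
bounded Levenberg–Marquardt (analytic Jacobian): centers within
±10 cm⁻¹ of their seeds, widths in [2, 40] cm⁻¹, amplitudes ≥ 0. Runs
that hit the iteration cap with a stalled objective (relative RSS
improvement < 1e-6 per step) are accepted as converged, since the
remaining drift is orders of magnitude below the area errors of
interest; fits that fail outright are flagged and their samples excluded
from the feature table with a logged reason. Areas use the closed form
$A\sigma\sqrt{2\pi}$, which the tests check against adaptive quadrature
to 0.1%. Band identity is nominal: the fitted band nearest 900 (within
±10 cm⁻¹) is "the 900 band", and the ratio is a ratio of areas, not
heights.

## Screening choices

`mann_whitney()` computes U by rank summation with midranks; the
two-sided p-value is exact for combined n ≤ 12 without ties and otherwise
a tie- and continuity-corrected normal approximation. The significance
level is 0.05 with no multiple-testing correction by default — the
analysis is a single-marker confirmation design centered on the 900/940
ratio — with a Benjamini–Hochberg option for exploratory use. Exactness
is verified against complete enumeration of rank assignments for every
no-tie instance with combined n ≤ 10.

## Classification choices

**PCA is refit inside every LOOCV fold**, and the held-out spectrum is
projected onto loadings estimated without it. Refitting is the only
leakage-free reading of leave-one-out validation; the tests corrupt the
held-out label and assert bit-identical held-out scores.

**QDA regularization**: each 2×2 class covariance gets
$+\lambda\,(\mathrm{tr}\Sigma/2)\,I$ with $\lambda = 10^{-6}$, enough to
guarantee positive definiteness at class sizes as small as 3 without
measurably moving the boundary.

**QDA priors are equal by default.** With empirical priors, removing a
sample for its LOOCV fold lowers its own class's prior; when the scores
carry little information the posterior tracks the prior, and the held-out
prediction is systematically pushed *away* from the true class. On
permuted labels this biases mean balanced accuracy to ≈ 45% instead of
50% for a 15/16 cohort — an anti-conservative artifact of the validation
scheme, not of the data. Equal priors restore the permutation-null
property (the acceptance tests verify mean balanced accuracy within three
standard errors of 50% over 200 permutations); empirical priors remain
available via `priors = "empirical"`.

**Ties** in the posterior predict non-pregnant, the conservative
direction for a transfer decision.

**ROC** thresholds are midpoints between consecutive distinct scores
plus outer sentinels; AUC is the trapezoid rule, which the tests pin to
the Mann–Whitney identity $\mathrm{AUC} = U/(n_1 n_2)$ at 1e-12. The
operating threshold maximizes Youden's J with ties broken toward the
lower threshold. Two score sources are reported: the 900/940 band-area
ratio (per-sample, model-free, so LOOCV-safe by construction) and the
held-out QDA posterior. If the marker orientation is reversed (AUC <
0.5) the score is flipped automatically and the flip is flagged.

## Validation problem sizes

The simulation studies behind the acceptance tests use two
configurations: the full default cohort (31 spectra, 600–1800 cm⁻¹) for
single-cohort end-to-end checks and permutation nulls, and a reduced-axis
configuration (700–1100 cm⁻¹, 401 channels, four bands, three toluene
reference lines) for replicate studies — 200 screening replicates per
effect size and 100 classification cohorts — chosen so the replicated
pipelines still exercise every stage (calibration, water, baseline,
despiking, fitting) over the regions that matter for the 900/940 marker.
Under these conditions the observed operating characteristics are: null
rejection rate of the ratio compatible with the nominal 5%, power ≈ 100%
at a doubled 900-band amplitude, LOOCV sensitivity and specificity above
80% in well over 90% of separable cohorts, and permutation-null balanced
accuracy statistically indistinguishable from 50%.

## Known limitations

* The band library and effect mechanism are stand-ins; nothing here
  validates the biological claim that the 900/940 ratio marks embryo
  viability.
* The despike confirmation rule assumes spikes are strictly
  single-channel; two-channel cosmic events are removed in two passes but
  wider ones may survive.
* The modified-polynomial baseline leaves a ~1% oscillation on spectra
  whose true baseline is negligible, which propagates into band-area
  errors of a few percent at the weakest bands.
* JCAMP-DX support covers single-spectrum AFFN `(X++(Y..Y))` and
  `(XY..XY)` tables only — no compressed (DIF/DUP/SQZ) forms, no
  multi-block files.
* With 15/16 samples per group, QDA estimates 2×2 covariances from ≤ 15
  points; the pipeline is honest about this (regularization, LOOCV) but
  small-sample optimism in the ROC threshold itself is not corrected
  beyond the use of held-out scores.
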