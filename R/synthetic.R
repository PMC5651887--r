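#' Default Gaussian band library for simulated culture-medium spectra
#'
#' Ten bands spanning 815-1500 cm^-1, including the 900 and 940 cm^-1 bands
#' whose area ratio carries the planted group effect. Centers, widths and
#' amplitudes are plausible stand-ins for a protein-supplemented culture
#' medium (e.g. the strong ~1003 cm^-1 phenylalanine ring-breathing band),
#' not claims about the real formulation.
#'
#' @return A data frame with columns `center`, `sigma`, `amplitude`.
#' @export
default_band_library <- function() {
  data.frame(
    center    = c(830, 855, 900, 940, 1003, 1045, 1160, 1250, 1320, 1450),
    sigma     = c( 10,  12,   8,   9,    6,   10,   12,   14,   12,   15),
    amplitude = c(0.25, 0.30, 0.35, 0.40, 1.00, 0.30, 0.25, 0.35, 0.30, 0.60)
  )
}

#' Default water background profile
#'
#' Two very broad (sigma > 100 cm^-1), low-amplitude Gaussians standing in
#' for the weak water contribution under the fingerprint region.
#'
#' @return A data frame with columns `center`, `sigma`, `amplitude`.
#' @export
default_water_profile <- function() {
  data.frame(center = c(800, 1640), sigma = c(300, 120),
             amplitude = c(0.10, 0.15))
}

#' Simulation configuration for synthetic Raman cohorts
#'
#' Defines the measurement model used by the generator: Gaussian bands on a
#' cubic fluorescence baseline plus a broad water background, additive
#' Gaussian detector noise and Poisson-count single-channel cosmic-ray
#' spikes. The group difference is a deterministic multiplicative scaling of
#' the 900 cm^-1 band amplitude in the pregnant group, so the ratio of
#' group-mean true 900-band areas equals `effect_size` exactly.
#'
#' @param axis_range Simulated shift range in cm^-1, default `c(600, 1800)`.
#' @param n_points Grid size (>= 200), default 1201 (1 cm^-1 step).
#' @param band_library Data frame (`center`, `sigma`, `amplitude`) of bands
#'   common to all samples; must include bands at 900 and 940 cm^-1.
#' @param baseline_coeffs Four coefficients `c0..c3` of the cubic
#'   fluorescence baseline, evaluated in the scaled coordinate
#'   `u = (shift - min) / (max - min)` so magnitudes are axis-independent.
#' @param water_profile Data frame of broad Gaussians (`center`, `sigma`,
#'   `amplitude`) added to every spectrum; `NULL` disables it.
#' @param noise_sd Additive Gaussian noise SD (a.u.), default 0.01
#'   (1\% of the strongest band amplitude).
#' @param spike_rate Expected cosmic-ray spikes per spectrum (Poisson mean).
#' @param effect_size Multiplicative shift of the 900-band amplitude in the
#'   pregnant group, default 2.
#' @param n_pregnant,n_nonpregnant Group sizes, default 15 and 16.
#' @param center_jitter_sd Per-sample SD of band-center jitter (cm^-1);
#'   areas are unaffected since area depends only on amplitude and width.
#' @param baseline_jitter_sd Per-sample SD of a common multiplicative
#'   baseline scale factor.
#' @param toluene_shifts Canonical toluene reference band positions (cm^-1)
#'   used for wavenumber calibration.
#' @param toluene_sigma,toluene_amplitude Width and height of simulated
#'   toluene reference bands.
#' @param seed RNG seed making cohort generation reproducible.
#' @return A validated object of class `sim_config`.
#' @export
sim_config <- function(axis_range = c(600, 1800),
                       n_points = 1201,
                       band_library = default_band_library(),
                       baseline_coeffs = c(2.0, 1.5, -1.0, 0.5),
                       water_profile = default_water_profile(),
                       noise_sd = 0.01,
                       spike_rate = 1,
                       effect_size = 2,
                       n_pregnant = 15,
                       n_nonpregnant = 16,
                       center_jitter_sd = 0.5,
                       baseline_jitter_sd = 0.1,
                       toluene_shifts = c(521.0, 785.8, 1003.6, 1030.6, 1210.0),
                       toluene_sigma = 2.5,
                       toluene_amplitude = 1,
                       seed = 1L) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  fail <- function(field, msg)
    stop("invalid sim_config field '", field, "': ", msg, call. = FALSE)
  if (length(cfg$axis_range) != 2 || diff(cfg$axis_range) <= 0)
    fail("axis_range", "must be (min, max) with min < max")
  if (cfg$n_points < 200) fail("n_points", "must be >= 200")
  bl <- cfg$band_library
  if (!all(c("center", "sigma", "amplitude") %in% names(bl)))
    fail("band_library", "needs columns center, sigma, amplitude")
  if (any(bl$sigma <= 0)) fail("band_library", "sigma must be > 0")
  if (any(bl$amplitude < 0)) fail("band_library", "amplitude must be >= 0")
  if (any(bl$center < cfg$axis_range[1] | bl$center > cfg$axis_range[2]))
    fail("band_library", "band centers must lie within axis_range")
  if (length(cfg$baseline_coeffs) != 4)
    fail("baseline_coeffs", "need exactly 4 cubic coefficients")
  if (cfg$noise_sd < 0) fail("noise_sd", "must be >= 0")
  if (cfg$spike_rate < 0) fail("spike_rate", "must be >= 0")
  if (cfg$effect_size <= 0) fail("effect_size", "must be > 0")
  if (cfg$n_pregnant < 1) fail("n_pregnant", "must be >= 1")
  if (cfg$n_nonpregnant < 1) fail("n_nonpregnant", "must be >= 1")
  invisible(cfg)
}

sim_axis <- function(cfg) {
  seq(cfg$axis_range[1], cfg$axis_range[2], length.out = cfg$n_points)
}

#' Sum of Gaussian profiles
#'
#' Evaluates `sum_j A_j * exp(-(x - c_j)^2 / (2 sigma_j^2))`; the
#' closed-form area of each component is `A * sigma * sqrt(2*pi)`.
#'
#' @param x Evaluation grid.
#' @param center,sigma,amplitude Component parameter vectors (recycled
#'   together).
#' @return Numeric vector of summed intensities.
#' @export
gaussian_mix <- function(x, center, sigma, amplitude) {
  if (!length(center)) return(numeric(length(x)))
  g <- exp(-(outer(x, center, "-"))^2 / rep(2 * sigma^2, each = length(x)))
  as.numeric(g %*% amplitude)
}

#' Closed-form area of a Gaussian band
#' @param amplitude,sigma Band amplitude and width.
#' @return `amplitude * sigma * sqrt(2*pi)`.
#' @export
gaussian_area <- function(amplitude, sigma) amplitude * sigma * sqrt(2 * pi)

eval_baseline <- function(x, coeffs, axis_range) {
  u <- (x - axis_range[1]) / diff(axis_range)
  coeffs[1] + coeffs[2] * u + coeffs[3] * u^2 + coeffs[4] * u^3
}

#' Generate one synthetic spectrum with recorded ground truth
#'
#' Draws from the measurement model of [sim_config()]:
#' `intensity = bands + cubic baseline + water + N(0, noise_sd) + spikes`.
#' Uses the session RNG stream; call [set.seed()] (or use
#' [generate_cohort()]) for reproducibility. Every stochastic draw is
#' recorded in the returned ground truth.
#'
#' @param config A `sim_config`.
#' @param label `"pregnant"` or `"nonpregnant"`; pregnant samples have the
#'   900-band amplitude multiplied by `config$effect_size`.
#' @param sample_id Sample identifier.
#' @return A list with elements `spectrum` (`raman_spectrum`) and `truth`
#'   (realized band table, baseline coefficients, spike channels/heights,
#'   label).
#' @export
generate_spectrum <- function(config, label = c("nonpregnant", "pregnant"),
                              sample_id = "sim") {
  validate_sim_config(config)
  label <- match.arg(label)
  x <- sim_axis(config)
  bands <- config$band_library
  # deterministic group effect on the band nearest 900 (before any noise)
  i900 <- which.min(abs(bands$center - 900))
  if (label == "pregnant")
    bands$amplitude[i900] <- bands$amplitude[i900] * config$effect_size
  if (config$center_jitter_sd > 0)
    bands$center <- bands$center +
      stats::rnorm(nrow(bands), 0, config$center_jitter_sd)
  bscale <- max(0.2, 1 + stats::rnorm(1, 0, config$baseline_jitter_sd))
  bcoef <- config$baseline_coeffs * bscale
  y <- gaussian_mix(x, bands$center, bands$sigma, bands$amplitude) +
    eval_baseline(x, bcoef, config$axis_range)
  if (!is.null(config$water_profile))
    y <- y + gaussian_mix(x, config$water_profile$center,
                          config$water_profile$sigma,
                          config$water_profile$amplitude)
  if (config$noise_sd > 0)
    y <- y + stats::rnorm(length(x), 0, config$noise_sd)
  n_spike <- stats::rpois(1, config$spike_rate)
  spike_ch <- integer(0); spike_h <- numeric(0)
  if (n_spike > 0) {
    spike_ch <- sample.int(length(x), min(n_spike, length(x)))
    spike_h <- stats::runif(length(spike_ch), 10, 50) *
      pmax(abs(y[spike_ch]), 0.1)
    y[spike_ch] <- y[spike_ch] + spike_h
  }
  list(
    spectrum = raman_spectrum(x, y, sample_id, "simulated"),
    truth = list(sample_id = sample_id, label = label, bands = bands,
                 baseline_coeffs = bcoef,
                 spike_channels = spike_ch, spike_heights = spike_h)
  )
}

#' Generate a labeled synthetic cohort
#'
#' Produces `n_pregnant + n_nonpregnant` spectra (defaults 15/16, the study
#' design this generator emulates) under `config`, deterministically from
#' `config$seed`.
#'
#' @param config A `sim_config`.
#' @return A list with elements `cohort` (`raman_cohort`) and `truth` (one
#'   ground-truth record per sample).
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  labels <- c(rep("pregnant", config$n_pregnant),
              rep("nonpregnant", config$n_nonpregnant))
  ids <- sprintf("S%02d", seq_along(labels))
  out <- mapply(function(lab, id) generate_spectrum(config, lab, id),
                labels, ids, SIMPLIFY = FALSE)
  spectra <- lapply(out, `[[`, "spectrum")
  names(spectra) <- ids
  truth <- lapply(out, `[[`, "truth")
  names(truth) <- ids
  cohort <- raman_cohort(spectra, stats::setNames(labels, ids), sim_axis(config))
  list(cohort = cohort, truth = truth)
}

#' Generate toluene and water reference spectra
#'
#' The toluene spectrum carries narrow bands at the canonical reference
#' shifts in `config$toluene_shifts` (those inside the axis range); the
#' water spectrum is the configured water profile. Both get additive noise
#' at `config$noise_sd`. An optional linear axis distortion
#' `observed = gain * true + offset` mislabels both reference axes the way
#' a miscalibrated spectrograph would, for testing the calibration fit.
#'
#' @param config A `sim_config`.
#' @param distortion Length-2 numeric `c(gain, offset)`, default `c(1, 0)`
#'   (identity pixel map).
#' @return List with `toluene` and `water` (`raman_spectrum` objects) and
#'   the `distortion` used.
#' @export
generate_references <- function(config, distortion = c(1, 0)) {
  validate_sim_config(config)
  x <- sim_axis(config)
  refs <- config$toluene_shifts
  obs_pos <- distortion[1] * refs + distortion[2]
  keep <- obs_pos > min(x) + 10 & obs_pos < max(x) - 10
  ytol <- gaussian_mix(x, obs_pos[keep],
                       rep(config$toluene_sigma, sum(keep)),
                       rep(config$toluene_amplitude, sum(keep)))
  ywat <- if (is.null(config$water_profile)) numeric(length(x)) else
    gaussian_mix(x, config$water_profile$center, config$water_profile$sigma,
                 config$water_profile$amplitude)
  if (config$noise_sd > 0) {
    ytol <- ytol + stats::rnorm(length(x), 0, config$noise_sd)
    ywat <- ywat + stats::rnorm(length(x), 0, config$noise_sd)
  }
  list(toluene = raman_spectrum(x, ytol, "toluene", "simulated"),
       water = raman_spectrum(x, ywat, "water", "simulated"),
       distortion = distortion)
}

#' Write a synthetic cohort with ground truth to a directory
#'
#' Per-sample CSVs plus `manifest.csv` via [write_cohort()], and the
#' ground-truth records as `ground_truth.json`.
#'
#' @param sim Result of [generate_cohort()].
#' @param dir Destination directory.
#' @return The manifest path, invisibly.
#' @export
write_synthetic_cohort <- function(sim, dir) {
  mp <- write_cohort(sim$cohort, dir)
  jsonlite::write_json(sim$truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(mp)
}
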