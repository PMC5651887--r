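test_that("despike removes an injected spike and touches nothing else", {
  set.seed(21)
  x <- seq(600, 1800, by = 1)
  y <- gaussian_mix(x, c(900, 1003), c(8, 6), c(0.5, 1)) +
    rnorm(length(x), 0, 0.01)
  clean <- raman_spectrum(x, y, "clean")

  # clean spectrum: no-op
  out0 <- despike(clean)
  expect_identical(out0$intensity, clean$intensity)
  expect_length(attr(out0, "replaced"), 0)

  # one channel at 50x its local value
  i <- which(x == 1100)
  spiked <- clean
  spiked$intensity[i] <- 50 * max(abs(clean$intensity[i]), 0.05)
  out <- despike(spiked)
  expect_equal(attr(out, "replaced"), i)
  expect_lt(abs(out$intensity[i] - clean$intensity[i]), 3 * 0.01)
  expect_identical(out$intensity[-i], clean$intensity[-i])
})

test_that("despike degenerate inputs: constant spectrum and short spectrum", {
  s <- raman_spectrum(1:100, rep(2, 100), "const")
  expect_identical(despike(s)$intensity, s$intensity)
  short <- raman_spectrum(1:4, c(1, 2, 1, 2), "short")
  expect_warning(out <- despike(short), "skipped")
  expect_identical(out$intensity, short$intensity)
})

test_that("calibration is near-identity on undistorted toluene", {
  cfg <- sim_config(noise_sd = 0)
  refs <- generate_references(cfg)
  s <- clean_band_spectrum(900, 8, 1)
  res <- calibrate(s, refs$toluene)
  expect_lt(abs(res$map$coefficients[1]), 1e-3)
  expect_lt(abs(res$map$coefficients[2] - 1), 1e-3)
  expect_lt(res$map$residual_rms, 0.1)
  expect_gte(nrow(res$map$pairs), 2)
})

test_that("calibration inverts a linear axis distortion within 0.2 cm-1", {
  cfg <- sim_config(noise_sd = 0.005)
  set.seed(8)
  refs <- generate_references(cfg, distortion = c(1.01, 3))
  s <- clean_band_spectrum(900, 8, 1)   # same (distorted) axis labels
  res <- calibrate(s, refs$toluene)
  true_axis <- (s$shift - 3) / 1.01
  keep <- true_axis >= 620 & true_axis <= 1400   # span of matched peaks
  expect_lt(max(abs(res$spectrum$shift[keep] - true_axis[keep])), 0.2)
})

test_that("calibration with fewer than two matched peaks is an error", {
  cfg <- sim_config(noise_sd = 0, axis_range = c(950, 1015), n_points = 260,
                    band_library = data.frame(center = 1003, sigma = 6,
                                              amplitude = 1))
  refs <- generate_references(cfg)   # only the 1003.6 band fits the range
  s <- raman_spectrum(seq(950, 1015, length.out = 260),
                      rep(1, 260), "flat")
  expect_error(calibrate(s, refs$toluene), "calibration error")
})

test_that("water subtraction inverts the additive model", {
  x <- seq(600, 1800, by = 1)
  signal <- gaussian_mix(x, 900, 8, 1)
  water <- gaussian_mix(x, c(800, 1640), c(300, 120), c(0.1, 0.15))
  s <- raman_spectrum(x, signal + water, "s")
  w <- raman_spectrum(x, water, "water")
  out <- subtract_water(s, w, "unit")
  expect_equal(out$intensity, signal, tolerance = 1e-12)

  # scaled water recovered by least squares over a signal-poor window
  set.seed(9)
  s2 <- raman_spectrum(x, signal + 0.7 * water + rnorm(length(x), 0, 0.005), "s2")
  out2 <- subtract_water(s2, w, "lsq", fit_window = c(1100, 1600))
  expect_lt(abs(attr(out2, "alpha") - 0.7), 0.02)

  # zero background is a no-op
  wz <- raman_spectrum(x, rep(0, length(x)), "w0")
  expect_equal(subtract_water(s, wz, "unit")$intensity, s$intensity)
})

test_that("baseline correction is exact on band-free cubic input", {
  x <- seq(600, 1800, by = 1)
  base <- 2 + 0.003 * x - 1e-6 * x^2 + 4e-10 * x^3
  s <- raman_spectrum(x, base, "cubic")
  res <- baseline_correct(s)
  expect_lt(max(abs(res$spectrum$intensity)), 1e-6 * max(abs(base)))
  expect_true(res$converged)

  z <- raman_spectrum(x, rep(0, length(x)), "zero")
  expect_lt(max(abs(baseline_correct(z)$spectrum$intensity)), 1e-12)
})

test_that("baseline correction separates a band from a cubic background", {
  x <- seq(600, 1800, by = 1)
  base <- 3 + 1.5 * (x - 600) / 1200 - ((x - 600) / 1200)^2
  band <- gaussian_mix(x, 1003, 6, 1)
  s <- raman_spectrum(x, base + band, "mix")
  res <- baseline_correct(s)
  i <- which(x == 1003)
  expect_lt(abs(res$spectrum$intensity[i] - band[i]) / band[i], 0.05)
  expect_lt(sqrt(mean((res$baseline - base)^2)) / mean(base), 0.02)
})

test_that("max normalization is exact, idempotent and scale invariant", {
  set.seed(10)
  x <- 1:500
  s <- raman_spectrum(x, runif(500, 0.1, 5), "n")
  n1 <- normalize_max(s)
  expect_identical(max(n1$intensity), 1)
  n2 <- normalize_max(n1)
  expect_equal(n2$intensity, n1$intensity)
  s7 <- s; s7$intensity <- 7 * s$intensity
  expect_equal(normalize_max(s7)$intensity, n1$intensity)
  neg <- raman_spectrum(x, rep(-1, 500), "neg")
  expect_error(normalize_max(neg), "normalization error")
})

test_that("the full chain reproduces a clean single band end to end", {
  cfg <- sim_config(
    band_library = data.frame(center = 900, sigma = 8, amplitude = 1),
    baseline_coeffs = rep(0, 4), water_profile = NULL, noise_sd = 0,
    spike_rate = 0, center_jitter_sd = 0, baseline_jitter_sd = 0,
    n_pregnant = 2, n_nonpregnant = 2
  )
  sim <- generate_cohort(cfg)
  refs <- generate_references(cfg)
  pp <- run_chain(sim$cohort, refs$toluene, refs$water)
  expect_length(attr(pp, "failures"), 0)
  for (s in pp$spectra) {
    expect_equal(max(s$intensity), 1)
    target <- exp(-(s$shift - 900)^2 / (2 * 8^2))
    # residual is dominated by the small oscillation the clipped polynomial
    # baseline leaves on a baseline-free spectrum (~1% of peak height)
    expect_lt(sqrt(mean((s$intensity - target)^2)), 0.02)
    expect_gt(stats::cor(s$intensity, target), 0.99)
    expect_lt(abs(s$shift[which.max(s$intensity)] - 900), 1)
  }
})

test_that("the chain preprocesses a realistic cohort and flags failures", {
  cfg <- quick_config(seed = 3)
  sim <- generate_cohort(cfg)
  refs <- generate_references(cfg)
  pp <- run_chain(sim$cohort, refs$toluene, refs$water)
  expect_length(attr(pp, "failures"), 0)
  expect_equal(n_samples(pp), 31)
  for (s in pp$spectra) expect_equal(max(s$intensity), 1)

  # empty cohort passes through vacuously
  empty <- sim$cohort
  empty$spectra <- list()
  empty$labels <- empty$labels[character(0)]
  out <- run_chain(empty, refs$toluene, refs$water)
  expect_equal(n_samples(out), 0)
})

test_that("chain recovers true band-area ratios within 10% median error", {
  cfg <- quick_config(seed = 12, spike_rate = 0.5)
  sim <- generate_cohort(cfg)
  refs <- generate_references(cfg)
  pp <- run_chain(sim$cohort, refs$toluene, refs$water)
  rel_err <- vapply(names(pp$spectra), function(id) {
    s <- pp$spectra[[id]]
    fit <- fit_bands(s, c(815, 1065),
                     seed_bands(s, c(815, 1065)))
    tr <- sim$truth[[id]]$bands
    true_ratio <- gaussian_area(tr$amplitude[tr$center > 890 & tr$center < 910],
                                tr$sigma[tr$center > 890 & tr$center < 910]) /
      gaussian_area(tr$amplitude[tr$center > 930 & tr$center < 950],
                    tr$sigma[tr$center > 930 & tr$center < 950])
    abs(band_ratio(fit) - true_ratio) / true_ratio
  }, numeric(1))
  expect_lt(median(rel_err), 0.1)
})
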