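#' Preprocessing configuration
#'
#' Free parameters of the preprocessing chain
#' (despike -> calibrate -> water subtraction -> baseline -> normalize).
#'
#' @param spike_z_threshold Modified z-score cutoff on the second difference
#'   above which a channel is treated as a cosmic-ray spike; default 8.
#' @param calib_order Polynomial order of the wavenumber calibration map
#'   (1 = linear, 2 = quadratic).
#' @param calib_ref_shifts Canonical toluene reference shifts (cm^-1).
#' @param calib_match_tol Max distance (cm^-1) between a detected toluene
#'   apex and a reference shift for a match; default 15.
#' @param water_scale_mode `"unit"` (plain subtraction) or `"lsq"`
#'   (least-squares scaled subtraction).
#' @param water_fit_window Optional `c(lo, hi)` window (cm^-1) over which
#'   the `lsq` scale is fitted; default the full axis.
#' @param baseline_order Polynomial order of the fluorescence baseline,
#'   default 3.
#' @param baseline_max_iter,baseline_tol Iteration cap and relative
#'   convergence tolerance of the iterative polynomial fit.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(spike_z_threshold = 8,
                              calib_order = 1,
                              calib_ref_shifts = c(521.0, 785.8, 1003.6,
                                                   1030.6, 1210.0),
                              calib_match_tol = 15,
                              water_scale_mode = c("unit", "lsq"),
                              water_fit_window = NULL,
                              baseline_order = 3,
                              baseline_max_iter = 100,
                              baseline_tol = 1e-6) {
  water_scale_mode <- match.arg(water_scale_mode)
  if (spike_z_threshold <= 0) stop("spike_z_threshold must be > 0", call. = FALSE)
  if (!calib_order %in% 1:2) stop("calib_order must be 1 or 2", call. = FALSE)
  if (baseline_order < 1) stop("baseline_order must be >= 1", call. = FALSE)
  if (baseline_tol <= 0) stop("baseline_tol must be > 0", call. = FALSE)
  structure(as.list(environment()), class = "preprocess_config")
}

#' Remove cosmic-ray spikes
#'
#' Detects spikes as channels whose modified z-score
#' `0.6745 * |d2 - median(d2)| / MAD(d2)` of the second difference exceeds
#' `z_threshold`, and removes them sequentially: at each pass the
#' worst-offending channel is replaced by the median of its 5-point
#' neighborhood (excluding already-flagged channels) and the statistic is
#' recomputed, so the shoulders of a removed spike are not themselves
#' flagged. All unflagged channels are returned bit-identical.
#'
#' @param s A `raman_spectrum`.
#' @param z_threshold Cutoff, default 8.
#' @param max_spikes Safety cap on sequential removals, default 50.
#' @return Despiked `raman_spectrum`; replaced channel indices are in
#'   `attr(, "replaced")` and in the processing log.
#' @export
despike <- function(s, z_threshold = 8, max_spikes = 50) {
  validate_spectrum(s)
  n <- length(s$intensity)
  if (n < 5L) {
    warning("spectrum '", s$sample_id,
            "' shorter than the despike window; skipped", call. = FALSE)
    out <- sp_log(s, "despike(skipped)")
    attr(out, "replaced") <- integer(0)
    return(out)
  }
  y <- s$intensity
  flagged <- integer(0)
  for (pass in seq_len(max_spikes)) {
    d2 <- diff(y, differences = 2)            # aligned to channels 2..n-1
    med <- stats::median(d2)
    scale <- stats::mad(d2, constant = 1)
    if (scale <= 0) scale <- mean(abs(d2 - med))
    if (scale <= 0) break                      # constant spectrum
    z <- 0.6745 * abs(d2 - med) / scale
    cand <- order(z, decreasing = TRUE)
    cand <- cand[z[cand] > z_threshold]
    hit <- 0L
    for (i in cand) {
      # single-channel confirmation: a cosmic spike perturbs d2 only at
      # i-1..i+1, so it must dominate the curvature two channels away;
      # smooth band apexes have comparable |d2| there and are left alone
      nb <- abs(d2[c(i - 2L, i + 2L)[c(i - 2L, i + 2L) %in% seq_along(d2)]] - med)
      if (!length(nb) || abs(d2[i] - med) > 3 * max(nb)) { hit <- i; break }
    }
    if (hit == 0L) break
    ch <- hit + 1L                             # spectrum channel index
    win <- max(1L, ch - 2L):min(n, ch + 2L)
    win <- setdiff(win, c(flagged, ch))
    y[ch] <- stats::median(y[win])
    flagged <- c(flagged, ch)
  }
  out <- s
  out$intensity <- y
  out <- sp_log(out, sprintf("despike(z=%g,replaced=%d)",
                             z_threshold, length(flagged)))
  attr(out, "replaced") <- sort(flagged)
  out
}

find_peak_apexes <- function(s, min_height = NULL) {
  y <- s$intensity; x <- s$shift; n <- length(y)
  if (is.null(min_height))
    min_height <- stats::median(y) + 0.2 * (max(y) - stats::median(y))
  idx <- which(y[2:(n - 1)] >= y[1:(n - 2)] & y[2:(n - 1)] > y[3:n]) + 1L
  idx <- idx[y[idx] >= min_height]
  if (!length(idx)) return(numeric(0))
  vapply(idx, function(i) {
    a <- y[i - 1]; b <- y[i]; c <- y[i + 1]
    # log-domain parabola is exact for a Gaussian line shape
    if (min(a, b, c) > 0) { a <- log(a); b <- log(b); c <- log(c) }
    den <- a - 2 * b + c
    delta <- if (abs(den) < .Machine$double.eps) 0 else 0.5 * (a - c) / den
    delta <- max(-0.5, min(0.5, delta))
    x[i] + delta * (x[i + 1] - x[i - 1]) / 2
  }, numeric(1))
}

#' Calibrate the wavenumber axis against a toluene reference
#'
#' Toluene band apexes are located by quadratic interpolation around local
#' maxima and matched to the nearest canonical reference shift within
#' `calib_match_tol`; a polynomial map (order `calib_order`) from observed
#' to reference shift is least-squares fitted and applied to the sample's
#' axis.
#'
#' @param s A `raman_spectrum` to calibrate.
#' @param toluene Toluene reference `raman_spectrum` from the same session.
#' @param config A `preprocess_config`.
#' @return List with `spectrum` (calibrated) and `map` (a
#'   `calibration_map`: coefficients, residual RMS in cm^-1, matched pairs).
#' @export
calibrate <- function(s, toluene, config = preprocess_config()) {
  validate_spectrum(s); validate_spectrum(toluene)
  apexes <- find_peak_apexes(toluene)
  refs <- config$calib_ref_shifts
  obs <- ref <- numeric(0)
  for (r in refs) {
    if (!length(apexes)) break
    j <- which.min(abs(apexes - r))
    if (abs(apexes[j] - r) <= config$calib_match_tol) {
      obs <- c(obs, apexes[j]); ref <- c(ref, r)
    }
  }
  if (length(obs) < config$calib_order + 1 || length(obs) < 2)
    stop("calibration error: only ", length(obs),
         " toluene reference peak(s) matched (need >= ",
         max(2, config$calib_order + 1), ")", call. = FALSE)
  fit <- stats::lm(ref ~ stats::poly(obs, config$calib_order, raw = TRUE))
  coefs <- unname(stats::coef(fit))
  apply_map <- function(x) {
    out <- coefs[1]
    for (k in seq_len(config$calib_order)) out <- out + coefs[k + 1] * x^k
    out
  }
  new_axis <- apply_map(s$shift)
  if (any(diff(new_axis) <= 0))
    stop("calibration error: fitted map is non-monotone over the data range",
         call. = FALSE)
  rms <- sqrt(mean(stats::residuals(fit)^2))
  map <- structure(list(coefficients = coefs, residual_rms = rms,
                        pairs = data.frame(observed = obs, reference = ref),
                        order = config$calib_order, fun = apply_map),
                   class = "calibration_map")
  out <- s
  out$shift <- new_axis
  out <- sp_log(out, sprintf("calibrate(order=%d,rms=%.3g)",
                             config$calib_order, rms))
  list(spectrum = out, map = map)
}

#' Subtract the water background
#'
#' `mode = "unit"` subtracts the water spectrum as measured;
#' `mode = "lsq"` subtracts `alpha * water` with `alpha >= 0` chosen by
#' least squares over `fit_window` (useful when acquisition times differ).
#' The water spectrum is resampled onto the sample's axis first.
#'
#' @param s A `raman_spectrum`.
#' @param water Water background `raman_spectrum` covering `s`'s axis.
#' @param mode `"unit"` or `"lsq"`.
#' @param fit_window Optional `c(lo, hi)` signal-poor window for the `lsq`
#'   fit; default the full axis.
#' @return Background-subtracted `raman_spectrum`; the scale used is logged
#'   and stored in `attr(, "alpha")`.
#' @export
subtract_water <- function(s, water, mode = c("unit", "lsq"),
                           fit_window = NULL) {
  mode <- match.arg(mode)
  validate_spectrum(s)
  w <- resample_spectrum(water, s$shift)
  alpha <- 1
  if (mode == "lsq") {
    idx <- seq_along(s$shift)
    if (!is.null(fit_window))
      idx <- which(s$shift >= fit_window[1] & s$shift <= fit_window[2])
    if (!length(idx)) stop("empty water fit window", call. = FALSE)
    denom <- sum(w$intensity[idx]^2)
    alpha <- if (denom > 0)
      max(0, sum(s$intensity[idx] * w$intensity[idx]) / denom) else 0
  }
  out <- s
  out$intensity <- s$intensity - alpha * w$intensity
  out <- sp_log(out, sprintf("water(mode=%s,alpha=%.4g)", mode, alpha))
  attr(out, "alpha") <- alpha
  out
}

#' Iterative polynomial fluorescence baseline correction
#'
#' Modified polynomial fitting (Lieber-style): fit a polynomial of order
#' `order` to the spectrum, clip the working spectrum to the fit wherever it
#' exceeds it (so peaks are progressively excluded), and refit until the
#' baseline changes by less than `tol` (relative) or `max_iter` is reached.
#' The final polynomial is subtracted.
#'
#' @param s A `raman_spectrum`.
#' @param order Polynomial order, default 3.
#' @param max_iter Iteration cap, default 100.
#' @param tol Relative convergence tolerance on the baseline (Euclidean
#'   norm), default 1e-6.
#' @return List with `spectrum` (corrected), `baseline` (numeric vector),
#'   `converged`, `iterations`. On noisy spectra the clipping decrements
#'   shrink geometrically, so the iteration cap is often reached before the
#'   tolerance; the best iterate is returned with `converged = FALSE` (also
#'   tagged `nonconv` in the processing log) and is accurate to well below
#'   the noise level.
#' @export
baseline_correct <- function(s, order = 3, max_iter = 100, tol = 1e-6) {
  validate_spectrum(s)
  n <- length(s$shift)
  if (n <= order + 1)
    stop("spectrum '", s$sample_id, "': too few points for order-", order,
         " baseline", call. = FALSE)
  xs <- 2 * (s$shift - min(s$shift)) / diff(range(s$shift)) - 1
  X <- outer(xs, 0:order, `^`)
  qrX <- qr(X)
  y0 <- s$intensity
  yk <- y0
  fit_prev <- NULL
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    beta <- qr.coef(qrX, yk)
    fit <- as.numeric(X %*% beta)
    # relative change of the baseline in Euclidean norm
    if (!is.null(fit_prev) &&
        sqrt(sum((fit - fit_prev)^2)) <=
        tol * max(sqrt(sum(fit_prev^2)), .Machine$double.eps)) {
      converged <- TRUE
      fit_prev <- fit
      break
    }
    fit_prev <- fit
    yk <- pmin(yk, fit)
  }
  if (is.null(fit_prev)) fit_prev <- rep(0, n)
  out <- s
  out$intensity <- y0 - fit_prev
  out <- sp_log(out, sprintf("baseline(order=%d,iter=%d%s)", order, iter,
                             if (converged) "" else ",nonconv"))
  list(spectrum = out, baseline = fit_prev, converged = converged,
       iterations = iter)
}

#' Normalize a spectrum to its maximum intensity
#'
#' @param s A `raman_spectrum` with positive maximum intensity.
#' @return Spectrum divided by its maximum (max of output is exactly 1).
#' @export
normalize_max <- function(s) {
  validate_spectrum(s)
  m <- max(s$intensity)
  if (m <= 0)
    stop("normalization error for '", s$sample_id,
         "': non-positive maximum intensity (", signif(m, 4),
         "); baseline correction may have failed", call. = FALSE)
  out <- s
  out$intensity <- s$intensity / m
  sp_log(out, sprintf("normalize(max=%.4g)", m))
}

#' Run the full preprocessing chain on a cohort
#'
#' Applies, per sample: despike -> wavenumber calibration (toluene) ->
#' water-background subtraction -> iterative third-order polynomial
#' fluorescence correction -> max-intensity normalization. After
#' calibration the cohort is re-gridded onto a uniform common axis spanning
#' the intersection of the calibrated ranges (original step), so downstream
#' region slicing stays valid; normalization is applied last so every
#' output has maximum exactly 1.
#'
#' @param cohort A `raman_cohort`.
#' @param toluene Toluene reference spectrum, or a named list of them (one
#'   per sample ID) when each session had its own reference.
#' @param water Water background spectrum, or a named list per sample.
#' @param config A `preprocess_config`.
#' @return The preprocessed `raman_cohort`. Samples for which any stage
#'   failed are dropped and reported in `attr(, "failures")` (named list of
#'   condition messages).
#' @export
run_chain <- function(cohort, toluene, water, config = preprocess_config()) {
  ids <- names(cohort$spectra)
  if (!length(ids)) return(cohort)
  pick <- function(ref, id)
    if (inherits(ref, "raman_spectrum")) ref else ref[[id]]
  failures <- list()
  processed <- list()
  for (id in ids) {
    res <- tryCatch({
      s <- despike(cohort$spectra[[id]], config$spike_z_threshold)
      tol_s <- pick(toluene, id)
      cal <- calibrate(s, tol_s, config)
      s <- cal$spectrum
      wat <- pick(water, id)
      wat_cal <- wat
      wat_cal$shift <- cal$map$fun(wat$shift)
      s <- subtract_water(s, wat_cal, config$water_scale_mode,
                          config$water_fit_window)
      bl <- baseline_correct(s, config$baseline_order,
                             config$baseline_max_iter, config$baseline_tol)
      bl$spectrum
    }, error = function(e) e)
    if (inherits(res, "error")) failures[[id]] <- conditionMessage(res)
    else processed[[id]] <- res
  }
  if (!length(processed)) {
    empty <- cohort
    empty$spectra <- list()
    empty$labels <- cohort$labels[character(0)]
    attr(empty, "failures") <- failures
    return(empty)
  }
  step <- stats::median(diff(cohort$common_axis))
  lo <- max(vapply(processed, function(s) min(s$shift), 0))
  hi <- min(vapply(processed, function(s) max(s$shift), 0))
  axes_same <- all(vapply(processed, function(s)
    length(s$shift) == length(processed[[1]]$shift) &&
      max(abs(s$shift - processed[[1]]$shift)) < 1e-9, logical(1)))
  common <- if (axes_same) processed[[1]]$shift else seq(lo, hi, by = step)
  final <- lapply(processed, function(s)
    normalize_max(resample_spectrum(s, common)))
  out <- raman_cohort(final, cohort$labels[names(final)], common)
  attr(out, "failures") <- failures
  out
}
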