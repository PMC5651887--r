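#' Seed initial Gaussian band candidates in a region
#'
#' Automatic mode places candidate centers at local minima of the smoothed
#' (Savitzky-Golay) second derivative — where band curvature is most
#' negative — keeping the `n_bands` strongest; manual mode takes centers
#' from `centers`. Initial widths are 8 cm^-1 and initial amplitudes the
#' local intensity.
#'
#' @param s A preprocessed `raman_spectrum`.
#' @param region `c(lo, hi)` in cm^-1, inside the spectrum range.
#' @param n_bands `"auto"` or an integer count to keep.
#' @param centers Optional numeric vector of fixed initial centers
#'   (manual mode).
#' @param sigma0 Initial width (cm^-1), default 8.
#' @param min_rel_height Auto mode drops candidates whose local intensity is
#'   below this fraction of the region maximum; default 0.02.
#' @return Data frame of seeds (`center`, `sigma`, `amplitude`).
#' @export
seed_bands <- function(s, region, n_bands = "auto", centers = NULL,
                       sigma0 = 8, min_rel_height = 0.02) {
  validate_spectrum(s)
  if (region[1] >= region[2] || region[1] < min(s$shift) ||
      region[2] > max(s$shift))
    stop("region [", region[1], ", ", region[2],
         "] invalid or outside spectrum range", call. = FALSE)
  idx <- which(s$shift >= region[1] & s$shift <= region[2])
  x <- s$shift[idx]; y <- s$intensity[idx]
  if (!is.null(centers)) {
    amp <- pmax(stats::approx(x, y, xout = centers, rule = 2)$y, 1e-6)
    return(data.frame(center = centers, sigma = sigma0, amplitude = amp))
  }
  m <- length(y)
  # second derivative over a window comparable to a band width, so noise
  # curvature at the grid scale does not spawn spurious candidates
  step <- stats::median(diff(x))
  w <- min(2L * floor(sigma0 / step) + 1L, if (m %% 2L == 1L) m else m - 1L)
  w <- max(w, 5L)
  if (m < w) stop("fitting error: region too short for auto seeding",
                  call. = FALSE)
  d2 <- signal::sgolayfilt(y, p = 3, n = w, m = 2)
  cand <- which(d2[2:(m - 1)] < 0 &
                d2[2:(m - 1)] <= d2[1:(m - 2)] &
                d2[2:(m - 1)] <= d2[3:m]) + 1L
  cand <- cand[y[cand] > min_rel_height * max(y)]
  # merge candidates closer than half a band width, keeping the strongest
  if (length(cand) > 1L) {
    o <- cand[order(-d2[cand])]
    kept <- integer(0)
    for (i in o)
      if (!length(kept) || min(abs(x[kept] - x[i])) >= sigma0)
        kept <- c(kept, i)
    cand <- sort(kept)
  }
  if (!length(cand))
    stop("fitting error: no band candidates found in region [",
         region[1], ", ", region[2],
         "]; supply manual centers", call. = FALSE)
  strength <- -d2[cand]
  if (is.numeric(n_bands)) {
    keep <- order(strength, decreasing = TRUE)[seq_len(min(n_bands, length(cand)))]
    cand <- sort(cand[keep])
  }
  data.frame(center = x[cand], sigma = sigma0,
             amplitude = pmax(y[cand], 1e-6))
}

gauss_model <- function(x, par) {
  k <- length(par) / 3
  p <- matrix(par, ncol = 3, byrow = TRUE)   # center, sigma, amplitude
  gaussian_mix(x, p[, 1], p[, 2], p[, 3])
}

# analytic Jacobian of the residual y - model w.r.t. (c, sigma, A) per band
gauss_jac <- function(x, par) {
  p <- matrix(par, ncol = 3, byrow = TRUE)
  k <- nrow(p)
  J <- matrix(0, length(x), 3 * k)
  for (j in seq_len(k)) {
    d <- x - p[j, 1]; s <- p[j, 2]; A <- p[j, 3]
    g <- exp(-d^2 / (2 * s^2))
    J[, 3 * j - 2] <- -A * g * d / s^2
    J[, 3 * j - 1] <- -A * g * d^2 / s^3
    J[, 3 * j]     <- -g
  }
  J
}

#' Fit Gaussian band components in a region
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt via
#' \pkg{minpack.lm}) of a sum of Gaussians to the region. Centers are
#' constrained to `center_window` around their seeds, widths to
#' `sigma_bounds`, amplitudes to be non-negative. Band areas use the closed
#' form `A * sigma * sqrt(2*pi)`.
#'
#' @param s A preprocessed `raman_spectrum`.
#' @param region `c(lo, hi)` in cm^-1.
#' @param seeds Seed data frame from [seed_bands()].
#' @param center_window Allowed center excursion from seed (cm^-1),
#'   default 10.
#' @param sigma_bounds `c(min, max)` width bounds (cm^-1), default
#'   `c(2, 40)`.
#' @return An object of class `band_fit`: `bands` (center, sigma,
#'   amplitude, area, standard errors), `residual_rms`, `converged`,
#'   `region`, `sample_id`.
#' @export
fit_bands <- function(s, region, seeds, center_window = 10,
                      sigma_bounds = c(2, 40)) {
  validate_spectrum(s)
  if (!nrow(seeds)) stop("fit_bands: no seeds supplied", call. = FALSE)
  idx <- which(s$shift >= region[1] & s$shift <= region[2])
  if (length(idx) <= 3 * nrow(seeds))
    stop("fit_bands: region has too few points (", length(idx),
         ") for ", nrow(seeds), " bands", call. = FALSE)
  x <- s$shift[idx]; y <- s$intensity[idx]
  par0 <- as.numeric(t(as.matrix(seeds[, c("center", "sigma", "amplitude")])))
  k <- nrow(seeds)
  lower <- as.numeric(t(cbind(seeds$center - center_window,
                              rep(sigma_bounds[1], k), rep(0, k))))
  upper <- as.numeric(t(cbind(seeds$center + center_window,
                              rep(sigma_bounds[2], k), rep(Inf, k))))
  par0 <- pmin(pmax(par0, lower), upper)
  fit <- minpack.lm::nls.lm(
    par = par0,
    lower = lower, upper = upper,
    fn = function(p) y - gauss_model(x, p),
    jac = function(p) gauss_jac(x, p),
    control = minpack.lm::nls.lm.control(maxiter = 1000, maxfev = 1e6)
  )
  # info 1-4: a Levenberg-Marquardt stopping rule fired; at the iteration
  # cap, a stalled objective (relative improvement below 1e-6 per step,
  # negligible for band areas) still counts as converged
  converged <- fit$info %in% 1:4 ||
    (length(fit$rsstrace) >= 2 &&
     abs(diff(utils::tail(fit$rsstrace, 2))) <=
       1e-6 * max(utils::tail(fit$rsstrace, 1), .Machine$double.eps))
  p <- matrix(fit$par, ncol = 3, byrow = TRUE)
  res <- y - gauss_model(x, fit$par)
  rms <- sqrt(mean(res^2))
  npar <- length(par0)
  se <- rep(NA_real_, npar)
  if (length(res) > npar) {
    s2 <- sum(res^2) / (length(res) - npar)
    cv <- tryCatch(solve(fit$hessian) * 2 * s2, error = function(e) NULL)
    if (!is.null(cv)) {
      d <- diag(cv)
      se <- ifelse(d > 0, sqrt(d), NA_real_)
    }
  }
  sem <- matrix(se, ncol = 3, byrow = TRUE)
  ord <- order(p[, 1])
  bands <- data.frame(center = p[ord, 1], sigma = p[ord, 2],
                      amplitude = p[ord, 3],
                      area = gaussian_area(p[ord, 3], p[ord, 2]),
                      se_center = sem[ord, 1], se_sigma = sem[ord, 2],
                      se_amplitude = sem[ord, 3])
  structure(list(sample_id = s$sample_id, region = region, bands = bands,
                 residual_rms = rms, converged = converged,
                 info = fit$info),
            class = "band_fit")
}

#' @export
print.band_fit <- function(x, ...) {
  cat(sprintf("<band_fit> %s, region %.0f-%.0f cm-1: %d bands, residual RMS %.3g%s\n",
              x$sample_id, x$region[1], x$region[2], nrow(x$bands),
              x$residual_rms, if (x$converged) "" else " (NOT converged)"))
  print(x$bands, digits = 4)
  invisible(x)
}

#' Band-area ratio between two nominal centers
#'
#' Takes the fitted band nearest each nominal center (within `tol`) and
#' returns the ratio of their closed-form areas.
#'
#' @param fit A `band_fit` (or list of them, searched jointly).
#' @param num_center,den_center Nominal centers (cm^-1), defaults 900/940.
#' @param tol Center-matching tolerance (cm^-1), default 10.
#' @return The ratio, or `NA` with a `"reason"` attribute when either band
#'   is missing or the denominator area is not positive.
#' @export
band_ratio <- function(fit, num_center = 900, den_center = 940, tol = 10) {
  bands <- if (inherits(fit, "band_fit")) fit$bands else
    do.call(rbind, lapply(fit, `[[`, "bands"))
  pick <- function(nominal) {
    j <- which.min(abs(bands$center - nominal))
    if (!length(j) || abs(bands$center[j] - nominal) > tol) return(NULL)
    bands[j, ]
  }
  num <- pick(num_center); den <- pick(den_center)
  if (is.null(num) || is.null(den)) {
    out <- NA_real_
    attr(out, "reason") <- sprintf("no fitted band within %g cm-1 of %g",
                                   tol, if (is.null(num)) num_center else den_center)
    return(out)
  }
  if (den$area <= 0) {
    out <- NA_real_
    attr(out, "reason") <- "zero denominator area"
    return(out)
  }
  num$area / den$area
}

#' Build a per-sample feature table of band areas and ratios
#'
#' Each sample's fitted bands (possibly over several regions) are matched
#' to `nominal_centers` (nearest fitted center within `tol`), giving
#' `area_<center>` columns; `ratios` adds named area-ratio columns.
#' Samples with a non-converged fit or any missing feature are excluded and
#' listed in `attr(, "excluded")`.
#'
#' @param fits Named list (by sample ID); each element is a `band_fit` or a
#'   list of `band_fit`s (one per region).
#' @param labels Named character vector of sample labels.
#' @param nominal_centers Numeric vector of nominal band centers; defaults
#'   to the default band library centers that fall inside the fitted
#'   regions.
#' @param ratios Named list of `c(numerator, denominator)` nominal centers;
#'   default `list(r900_940 = c(900, 940))`.
#' @param tol Center-matching tolerance (cm^-1), default 10.
#' @return Data frame (`sample_id`, `label`, `area_*`, ratio columns).
#' @export
build_features <- function(fits, labels, nominal_centers = NULL,
                           ratios = list(r900_940 = c(900, 940)), tol = 10) {
  as_list <- lapply(fits, function(f)
    if (inherits(f, "band_fit")) list(f) else f)
  if (is.null(nominal_centers)) {
    regions <- do.call(rbind, lapply(as_list[[1]], `[[`, "region"))
    lib <- default_band_library()$center
    nominal_centers <- lib[vapply(lib, function(cc)
      any(cc >= regions[, 1] & cc <= regions[, 2]), logical(1))]
  }
  for (rn in names(ratios)) {
    rc <- ratios[[rn]]
    if (!all(vapply(rc, function(cc)
      any(abs(nominal_centers - cc) <= tol), logical(1))))
      stop("configuration error: ratio '", rn,
           "' refers to centers outside the nominal center set", call. = FALSE)
  }
  rows <- list(); excluded <- list()
  for (id in names(as_list)) {
    fl <- as_list[[id]]
    if (!all(vapply(fl, `[[`, logical(1), "converged"))) {
      excluded[[id]] <- "non-converged band fit"
      next
    }
    bands <- do.call(rbind, lapply(fl, `[[`, "bands"))
    areas <- vapply(nominal_centers, function(cc) {
      j <- which.min(abs(bands$center - cc))
      if (abs(bands$center[j] - cc) > tol) NA_real_ else bands$area[j]
    }, numeric(1))
    rvals <- vapply(names(ratios), function(rn)
      as.numeric(band_ratio(fl, ratios[[rn]][1], ratios[[rn]][2], tol)),
      numeric(1))
    vals <- c(areas, rvals)
    if (anyNA(vals)) {
      excluded[[id]] <- "missing band feature"
      next
    }
    row <- data.frame(sample_id = id, label = unname(labels[id]))
    row[paste0("area_", nominal_centers)] <- as.list(areas)
    row[names(ratios)] <- as.list(rvals)
    rows[[id]] <- row
  }
  if (!length(rows))
    stop("pipeline error: no samples with complete band features", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}
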