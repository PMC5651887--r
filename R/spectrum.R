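#' Construct a Raman spectrum
#'
#' A `raman_spectrum` holds one sample's Raman shift axis (cm^-1), the
#' measured intensity (arbitrary units) and an ordered processing log of the
#' steps already applied to it.
#'
#' @param shift Numeric vector of Raman shifts in cm^-1, strictly increasing.
#' @param intensity Numeric vector of intensities, same length as `shift`.
#' @param sample_id Character scalar identifying the sample.
#' @param log Character vector of processing-step tags already applied.
#' @return An object of class `raman_spectrum`.
#' @export
raman_spectrum <- function(shift, intensity, sample_id = "sample",
                           log = character()) {
  s <- structure(
    list(sample_id = as.character(sample_id)[1],
         shift = as.numeric(shift),
         intensity = as.numeric(intensity),
         log = as.character(log)),
    class = "raman_spectrum"
  )
  validate_spectrum(s)
  s
}

validate_spectrum <- function(s) {
  if (length(s$shift) != length(s$intensity))
    stop("spectrum '", s$sample_id, "': shift and intensity lengths differ (",
         length(s$shift), " vs ", length(s$intensity), ")", call. = FALSE)
  if (length(s$shift) < 2L)
    stop("spectrum '", s$sample_id, "': fewer than 2 points", call. = FALSE)
  if (anyNA(s$shift) || any(!is.finite(s$shift)))
    stop("spectrum '", s$sample_id, "': non-finite shift values", call. = FALSE)
  if (anyNA(s$intensity) || any(!is.finite(s$intensity)))
    stop("spectrum '", s$sample_id, "': non-finite intensities", call. = FALSE)
  if (any(diff(s$shift) <= 0))
    stop("spectrum '", s$sample_id, "': shift axis not strictly increasing",
         call. = FALSE)
  invisible(s)
}

sp_log <- function(s, tag) {
  s$log <- c(s$log, tag)
  s
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum> %s: %d points, %.1f-%.1f cm-1\n",
              x$sample_id, length(x$shift), min(x$shift), max(x$shift)))
  if (length(x$log))
    cat("  processing:", paste(x$log, collapse = " -> "), "\n")
  invisible(x)
}

#' Resample a spectrum onto a new shift axis
#'
#' Linear interpolation onto `axis`; values at grid points shared with the
#' original axis are preserved exactly. The target axis must lie within the
#' spectrum's range.
#'
#' @param s A `raman_spectrum`.
#' @param axis Numeric vector, strictly increasing, within `range(s$shift)`.
#' @return A resampled `raman_spectrum`.
#' @export
resample_spectrum <- function(s, axis) {
  validate_spectrum(s)
  axis <- as.numeric(axis)
  if (min(axis) < min(s$shift) - 1e-9 || max(axis) > max(s$shift) + 1e-9)
    stop("spectrum '", s$sample_id, "': target axis ",
         min(axis), "-", max(axis), " outside measured range ",
         min(s$shift), "-", max(s$shift), call. = FALSE)
  if (isTRUE(all.equal(axis, s$shift, tolerance = 0))) return(s)
  y <- stats::approx(s$shift, s$intensity, xout = axis, rule = 1)$y
  raman_spectrum(axis, y, s$sample_id, c(s$log, "resample"))
}

#' Construct a labeled cohort of spectra
#'
#' @param spectra Named list of `raman_spectrum` objects (names = sample IDs).
#' @param labels Named character vector mapping sample ID to `"pregnant"` or
#'   `"nonpregnant"`.
#' @param common_axis Shared shift grid; all spectra must sit on it.
#' @return An object of class `raman_cohort`.
#' @export
raman_cohort <- function(spectra, labels, common_axis) {
  ids <- vapply(spectra, function(s) s$sample_id, character(1))
  names(spectra) <- ids
  if (!all(ids %in% names(labels)))
    stop("missing label for sample(s): ",
         paste(setdiff(ids, names(labels)), collapse = ", "), call. = FALSE)
  labels <- labels[ids]
  bad <- !labels %in% c("pregnant", "nonpregnant")
  if (any(bad))
    stop("unknown label '", labels[bad][1], "' for sample '",
         ids[bad][1], "'", call. = FALSE)
  for (s in spectra) {
    if (length(s$shift) != length(common_axis) ||
        max(abs(s$shift - common_axis)) > 1e-9)
      stop("sample '", s$sample_id, "' is not on the common axis", call. = FALSE)
  }
  structure(list(spectra = spectra, labels = labels,
                 common_axis = as.numeric(common_axis)),
            class = "raman_cohort")
}

#' @export
print.raman_cohort <- function(x, ...) {
  cat(sprintf("<raman_cohort> %d spectra (%d pregnant / %d nonpregnant), axis %.1f-%.1f cm-1 (%d channels)\n",
              length(x$spectra), sum(x$labels == "pregnant"),
              sum(x$labels == "nonpregnant"),
              min(x$common_axis), max(x$common_axis), length(x$common_axis)))
  invisible(x)
}

#' Number of samples in a cohort
#' @param cohort A `raman_cohort`.
#' @return Integer sample count.
#' @export
n_samples <- function(cohort) length(cohort$spectra)
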