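#' Read a spectrum from disk
#'
#' Supported formats: two-column CSV (`wavenumber_cm1,intensity`, one header
#' line, dot decimal separator) and JCAMP-DX with an `##XYDATA=(X++(Y..Y))`
#' or `##XYPOINTS=(XY..XY)` table. Non-monotone axes are sorted with a
#' logged warning; duplicated shift values are averaged.
#'
#' @param path File path.
#' @param format `"csv"`, `"jcamp"`, or `"auto"` (by file extension:
#'   `.dx`/`.jdx`/`.jcm` are JCAMP, anything else CSV).
#' @param sample_id Optional sample ID; defaults to the file name.
#' @return A `raman_spectrum`.
#' @export
read_spectrum <- function(path, format = c("auto", "csv", "jcamp"),
                          sample_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("spectrum file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("dx", "jdx", "jcm", "jcamp")) "jcamp" else "csv"
  }
  if (is.null(sample_id))
    sample_id <- tools::file_path_sans_ext(basename(path))
  xy <- switch(format,
               csv = read_xy_csv(path),
               jcamp = read_xy_jcamp(path))
  log <- character()
  x <- xy$x; y <- xy$y
  if (length(x) < 2L)
    stop("format error in ", path, ": fewer than 2 data points", call. = FALSE)
  if (is.unsorted(x, strictly = TRUE)) {
    o <- order(x)
    x <- x[o]; y <- y[o]
    warning("shift axis in ", path, " was not increasing; sorted on read",
            call. = FALSE)
    log <- c(log, "sorted-on-read")
    if (anyDuplicated(x)) {
      y <- as.numeric(tapply(y, x, mean))
      x <- sort(unique(x))
      log <- c(log, "duplicates-averaged")
    }
  }
  raman_spectrum(x, y, sample_id, log)
}

read_xy_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop("format error in ", path, ": need a header line plus >= 2 data rows",
         call. = FALSE)
  body <- lines[-1]
  parts <- strsplit(body, ",", fixed = TRUE)
  n_fld <- lengths(parts)
  if (any(n_fld < 2L))
    stop("format error in ", path, " at line ",
         which(n_fld < 2L)[1] + 1L, ": expected 2 comma-separated fields",
         call. = FALSE)
  x <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
  y <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  bad <- which(is.na(x) | is.na(y))
  if (length(bad))
    stop("format error in ", path, " at line ", bad[1] + 1L,
         ": non-numeric value", call. = FALSE)
  list(x = x, y = y)
}

#' Write a spectrum to disk
#'
#' CSV files carry the header `wavenumber_cm1,intensity`; JCAMP-DX files use
#' an AFFN `(X++(Y..Y))` table on uniform axes and `(XY..XY)` pairs
#' otherwise. Values are written with enough digits for a round-trip within
#' 1e-9 (CSV) / 1e-6 relative (JCAMP).
#'
#' @param s A `raman_spectrum`.
#' @param path Destination path.
#' @param format `"csv"`, `"jcamp"`, or `"auto"` (by extension).
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path, format = c("auto", "csv", "jcamp")) {
  format <- match.arg(format)
  validate_spectrum(s)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("dx", "jdx", "jcm", "jcamp")) "jcamp" else "csv"
  }
  if (format == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("wavenumber_cm1,intensity", con)
    writeLines(sprintf("%.12g,%.12g", s$shift, s$intensity), con)
  } else {
    write_xy_jcamp(s, path)
  }
  invisible(path)
}

write_xy_jcamp <- function(s, path) {
  n <- length(s$shift)
  dx <- diff(s$shift)
  uniform <- max(dx) - min(dx) < 1e-9 * max(abs(s$shift))
  hdr <- c(
    sprintf("##TITLE=%s", s$sample_id),
    "##JCAMP-DX=4.24",
    "##DATA TYPE=RAMAN SPECTRUM",
    "##XUNITS=1/CM",
    "##YUNITS=ARBITRARY UNITS",
    "##XFACTOR=1",
    "##YFACTOR=1",
    sprintf("##FIRSTX=%.10g", s$shift[1]),
    sprintf("##LASTX=%.10g", s$shift[n]),
    sprintf("##NPOINTS=%d", n)
  )
  if (uniform) {
    rows <- split(seq_len(n), ceiling(seq_len(n) / 6))
    tab <- vapply(rows, function(i) {
      paste(c(sprintf("%.10g", s$shift[i[1]]),
              sprintf("%.9g", s$intensity[i])), collapse = " ")
    }, character(1))
    body <- c("##XYDATA=(X++(Y..Y))", tab)
  } else {
    body <- c("##XYPOINTS=(XY..XY)",
              sprintf("%.10g, %.9g", s$shift, s$intensity))
  }
  writeLines(c(hdr, body, "##END="), path)
}

read_xy_jcamp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  get_field <- function(key) {
    i <- grep(paste0("^##", key, "="), lines)
    if (!length(i)) return(NA_real_)
    as.numeric(sub(paste0("^##", key, "="), "", lines[i[1]]))
  }
  xf <- get_field("XFACTOR"); if (is.na(xf)) xf <- 1
  yf <- get_field("YFACTOR"); if (is.na(yf)) yf <- 1
  i_xy <- grep("^##XYDATA=", lines)
  i_pts <- grep("^##XYPOINTS=", lines)
  i_end <- grep("^##END", lines)
  stop_at <- if (length(i_end)) i_end[1] - 1L else length(lines)
  if (length(i_xy)) {
    firstx <- get_field("FIRSTX"); lastx <- get_field("LASTX")
    npt <- get_field("NPOINTS")
    if (anyNA(c(firstx, lastx, npt)))
      stop("format error in ", path,
           ": XYDATA requires FIRSTX, LASTX and NPOINTS", call. = FALSE)
    deltax <- (lastx - firstx) / (npt - 1)
    body <- lines[(i_xy[1] + 1L):stop_at]
    x <- numeric(0); y <- numeric(0)
    for (k in seq_along(body)) {
      tok <- strsplit(trimws(body[k]), "[[:space:]]+")[[1]]
      if (!length(tok)) next
      v <- suppressWarnings(as.numeric(tok))
      if (anyNA(v))
        stop("format error in ", path, " at line ", i_xy[1] + k,
             ": non-numeric value", call. = FALSE)
      x <- c(x, v[1] + deltax * (seq_len(length(v) - 1L) - 1L))
      y <- c(y, v[-1])
    }
    list(x = x * xf, y = y * yf)
  } else if (length(i_pts)) {
    body <- lines[(i_pts[1] + 1L):stop_at]
    parts <- strsplit(trimws(body), "[,;[:space:]]+")
    v <- suppressWarnings(lapply(parts, as.numeric))
    bad <- which(vapply(v, anyNA, logical(1)))
    if (length(bad))
      stop("format error in ", path, " at line ", i_pts[1] + bad[1],
           ": non-numeric value", call. = FALSE)
    x <- vapply(v, `[`, 0, 1L); y <- vapply(v, `[`, 0, 2L)
    list(x = x * xf, y = y * yf)
  } else {
    stop("format error in ", path, ": no XYDATA/XYPOINTS table", call. = FALSE)
  }
}

#' Assemble a labeled cohort from a manifest
#'
#' The manifest is a CSV with columns `sample_id,path,label`
#' (label in \{pregnant, nonpregnant\}); spectrum paths are resolved relative
#' to the manifest's directory. Spectra are placed on a shared axis: if all
#' input grids are identical that grid is kept, otherwise every spectrum is
#' linearly resampled onto a uniform grid (step `step` cm^-1) spanning the
#' intersection of the individual ranges.
#'
#' @param manifest_path Path to the manifest CSV.
#' @param step Grid step (cm^-1) of the common axis when resampling, default 1.
#' @return A `raman_cohort`.
#' @export
assemble_cohort <- function(manifest_path, step = 1) {
  if (!file.exists(manifest_path))
    stop("manifest not found: ", manifest_path, call. = FALSE)
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("sample_id", "path", "label")
  if (!all(need %in% names(man)))
    stop("manifest must have columns sample_id, path, label", call. = FALSE)
  if (!nrow(man)) stop("manifest is empty", call. = FALSE)
  bad <- !man$label %in% c("pregnant", "nonpregnant")
  if (any(bad))
    stop("assembly error for sample '", man$sample_id[bad][1],
         "': unknown label '", man$label[bad][1], "'", call. = FALSE)
  base <- dirname(normalizePath(manifest_path))
  spectra <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, man$path[i])
    if (!file.exists(p))
      stop("assembly error for sample '", man$sample_id[i],
           "': file not found: ", man$path[i], call. = FALSE)
    spectra[[i]] <- read_spectrum(p, sample_id = man$sample_id[i])
  }
  names(spectra) <- man$sample_id
  labels <- stats::setNames(man$label, man$sample_id)

  axes <- lapply(spectra, `[[`, "shift")
  same <- all(vapply(axes, function(a)
    length(a) == length(axes[[1]]) && max(abs(a - axes[[1]])) < 1e-9,
    logical(1)))
  if (same) {
    common <- axes[[1]]
  } else {
    lo <- max(vapply(axes, min, 0))
    hi <- min(vapply(axes, max, 0))
    if (hi - lo < step) {
      i_lo <- which.max(vapply(axes, min, 0))
      stop("assembly error for sample '", man$sample_id[i_lo],
           "': empty intersection of shift ranges", call. = FALSE)
    }
    common <- seq(lo, hi, by = step)
    spectra <- lapply(spectra, resample_spectrum, axis = common)
  }
  raman_cohort(spectra, labels, common)
}

#' Write a cohort to a directory
#'
#' Writes one `<sample_id>.csv` per spectrum plus `manifest.csv`
#' (`sample_id,path,label`).
#'
#' @param cohort A `raman_cohort`.
#' @param dir Destination directory (created if missing).
#' @return Path to the manifest, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- names(cohort$spectra)
  paths <- paste0(ids, ".csv")
  for (i in seq_along(ids))
    write_spectrum(cohort$spectra[[i]], file.path(dir, paths[i]), "csv")
  man <- data.frame(sample_id = ids, path = paths,
                    label = unname(cohort$labels[ids]))
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(man, mp, row.names = FALSE, quote = FALSE)
  invisible(mp)
}
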