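#' Mann-Whitney U test between two groups
#'
#' U is computed by rank summation with midranks for ties. The two-sided
#' p-value is exact (by complete enumeration of rank assignments, as in
#' [stats::wilcox.test()]) when `n1 + n2 <= 12` and there are no ties, and
#' otherwise uses the normal approximation with tie and continuity
#' corrections; `mode` forces either route.
#'
#' @param x,y Numeric value vectors for the two groups.
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @param feature Optional feature name carried into the result.
#' @return An object of class `mw_test`: `feature`, `U` (for `x`), `p`,
#'   `median_x`, `median_y`, `n1`, `n2`, `method` (`"exact"` or
#'   `"normal-approx"`), `degenerate` (all values tied).
#' @export
mann_whitney <- function(x, y, mode = c("auto", "exact", "normal"),
                         feature = NA_character_) {
  mode <- match.arg(mode)
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("both groups need >= 1 value", call. = FALSE)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  degenerate <- length(unique(c(x, y))) == 1L
  if (mode == "exact" && ties)
    stop("exact Mann-Whitney p-value is unavailable with ties", call. = FALSE)
  use_exact <- !ties && (mode == "exact" || (mode == "auto" && n1 + n2 <= 12))
  if (degenerate) {
    p <- 1
    method <- "normal-approx"
  } else if (use_exact) {
    p <- if (U > n1 * n2 / 2)
      stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE) else
      stats::pwilcox(U, n1, n2)
    p <- min(2 * p, 1)
    method <- "exact"
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
    if (is.na(p)) { p <- 1 }
    method <- "normal-approx"
  }
  structure(list(feature = feature, U = U, p = p,
                 median_x = stats::median(x), median_y = stats::median(y),
                 n1 = n1, n2 = n2, method = method, degenerate = degenerate),
            class = "mw_test")
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U test%s: U = %g (n1=%d, n2=%d), p = %.4g [%s]%s\n",
              if (is.na(x$feature)) "" else paste0(" [", x$feature, "]"),
              x$U, x$n1, x$n2, x$p, x$method,
              if (x$degenerate) " (degenerate: all values tied)" else ""))
  invisible(x)
}

#' Screen band features between pregnant and non-pregnant groups
#'
#' Runs a two-sided Mann-Whitney U test per feature column of a feature
#' table (every numeric column except `sample_id`/`label`) and flags
#' features with p below `alpha`. No multiple-testing correction is applied
#' by default, matching the single-ratio headline analysis this pipeline
#' mirrors; `adjust = "BH"` switches on Benjamini-Hochberg adjusted flags.
#'
#' @param table Feature table from [build_features()].
#' @param alpha Significance level, default 0.05.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A data frame of class `screen_report` with one row per feature
#'   (`feature`, `U`, `p`, `p_adj`, `significant`, medians, group sizes,
#'   `n_dropped` missing rows per feature, `method`).
#' @export
screen_features <- function(table, alpha = 0.05,
                            adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(all(c("sample_id", "label") %in% names(table)))
  feats <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                   c("sample_id", "label"))
  if (!length(feats)) stop("no numeric feature columns", call. = FALSE)
  g1 <- table$label == "pregnant"
  if (sum(g1) < 2 || sum(!g1) < 2)
    stop("need >= 2 samples per group", call. = FALSE)
  rows <- lapply(feats, function(f) {
    v <- table[[f]]
    ok <- !is.na(v)
    t <- mann_whitney(v[ok & g1], v[ok & !g1], feature = f)
    data.frame(feature = f, U = t$U, p = t$p,
               median_pregnant = t$median_x,
               median_nonpregnant = t$median_y,
               n_pregnant = t$n1, n_nonpregnant = t$n2,
               n_dropped = sum(!ok), method = t$method)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- if (adjust == "BH") stats::p.adjust(out$p, "BH") else out$p
  out$significant <- out$p_adj < alpha
  rownames(out) <- NULL
  class(out) <- c("screen_report", "data.frame")
  attr(out, "alpha") <- alpha
  out
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("Feature screen (Mann-Whitney U, alpha = %g):\n",
              attr(x, "alpha")))
  print.data.frame(x, digits = 4)
  sig <- x$feature[x$significant]
  cat(if (length(sig))
    paste0("significant: ", paste(sig, collapse = ", "), "\n")
    else "no significant features\n")
  invisible(x)
}
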