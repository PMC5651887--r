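#' Extract the channel matrix of a spectral region
#'
#' Slices every spectrum of a preprocessed cohort to the channels with
#' `lo <= shift < hi` (half-open) on the common axis.
#'
#' @param cohort A preprocessed `raman_cohort` on a common axis covering
#'   the region.
#' @param lo,hi Region bounds in cm^-1, defaults 890 and 950.
#' @return Numeric matrix (samples x channels), rows in cohort order, with
#'   channel shifts as column names.
#' @export
region_matrix <- function(cohort, lo = 890, hi = 950) {
  idx <- which(cohort$common_axis >= lo & cohort$common_axis < hi)
  if (lo >= hi || !length(idx))
    stop("region [", lo, ", ", hi, ") is empty on the common axis",
         call. = FALSE)
  if (lo < min(cohort$common_axis) || hi > max(cohort$common_axis) +
      stats::median(diff(cohort$common_axis)))
    stop("region [", lo, ", ", hi, ") outside the common axis range",
         call. = FALSE)
  m <- t(vapply(cohort$spectra, function(s) s$intensity[idx],
                numeric(length(idx))))
  dimnames(m) <- list(names(cohort$spectra),
                      sprintf("%.6g", cohort$common_axis[idx]))
  m
}

#' Principal component analysis of a channel matrix
#'
#' Mean-centered (no variance scaling) PCA by singular value decomposition.
#' Loadings follow the sign convention that each loading's
#' largest-magnitude element is positive.
#'
#' @param m Samples x channels matrix.
#' @param k Number of components to keep, default 2.
#' @return List of class `pca_model`: `mean`, `loadings` (channels x k),
#'   `var_fraction` (length k), `scores` (samples x k).
#' @export
pca_fit <- function(m, k = 2) {
  m <- as.matrix(m)
  if (nrow(m) < k + 1)
    stop("PCA needs at least k + 1 = ", k + 1, " samples", call. = FALSE)
  mu <- colMeans(m)
  mc <- sweep(m, 2, mu)
  sv <- svd(mc)
  rank <- sum(sv$d > max(sv$d[1], 1) * 1e-12)
  if (rank < k)
    stop("PCA rank deficiency: achieved rank ", rank, " < k = ", k,
         call. = FALSE)
  load <- sv$v[, seq_len(k), drop = FALSE]
  flip <- vapply(seq_len(k), function(j)
    sign(load[which.max(abs(load[, j])), j]), numeric(1))
  load <- sweep(load, 2, flip, `*`)
  scores <- mc %*% load
  varfrac <- sv$d^2 / sum(sv$d^2)
  structure(list(mean = mu, loadings = load,
                 var_fraction = varfrac[seq_len(k)], scores = scores),
            class = "pca_model")
}

#' Project new samples onto a fitted PCA model
#' @param model A `pca_model`.
#' @param m New samples x channels matrix (or a single row vector).
#' @return Scores matrix (samples x k).
#' @export
pca_project <- function(model, m) {
  m <- matrix(m, ncol = length(model$mean))
  sweep(m, 2, model$mean) %*% model$loadings
}

#' Fit quadratic discriminant analysis
#'
#' Gaussian class-conditional model with class-specific means and
#' covariances (denominator `n_c - 1`), and ridge regularization
#' `Sigma + lambda * (trace(Sigma)/d) * I` to keep the small per-class
#' covariances positive definite. Priors default to equal: under
#' leave-one-out cross-validation on a near-balanced cohort, empirical
#' priors systematically disfavor the held-out sample's own class and bias
#' the null balanced accuracy below 50\%; `priors = "empirical"` restores
#' sample-frequency priors.
#'
#' @param scores Samples x d score matrix (d = 2 for the pipeline).
#' @param labels Character vector (`"pregnant"`/`"nonpregnant"`) aligned
#'   with rows.
#' @param lambda Regularization strength, default 1e-6.
#' @param priors `"equal"` (default) or `"empirical"`.
#' @return List of class `qda_model`: per-class `means`, `covs`, `priors`,
#'   `lambda`.
#' @export
qda_fit <- function(scores, labels, lambda = 1e-6,
                    priors = c("equal", "empirical")) {
  priors <- match.arg(priors)
  scores <- as.matrix(scores)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need two classes", call. = FALSE)
  d <- ncol(scores)
  means <- list(); covs <- list(); pri <- numeric(0)
  for (cl in classes) {
    m <- scores[labels == cl, , drop = FALSE]
    if (nrow(m) < 3)
      stop("class '", cl, "' has ", nrow(m),
           " samples; need >= 3 for a nondegenerate covariance",
           call. = FALSE)
    S <- stats::cov(m)
    S <- S + lambda * (sum(diag(S)) / d) * diag(d)
    ok <- tryCatch({ chol(S); TRUE }, error = function(e) FALSE)
    if (!ok)
      stop("class '", cl, "' covariance not positive definite after ",
           "regularization", call. = FALSE)
    means[[cl]] <- colMeans(m)
    covs[[cl]] <- S
    pri[cl] <- nrow(m)
  }
  pri <- if (priors == "empirical") pri / sum(pri) else
    stats::setNames(rep(1 / length(classes), length(classes)), classes)
  structure(list(means = means, covs = covs, priors = pri,
                 lambda = lambda, classes = classes),
            class = "qda_model")
}

#' Class posterior probabilities under a QDA model
#' @param model A `qda_model`.
#' @param points Points x d matrix (or single point).
#' @return Matrix (points x classes) of posteriors, rows summing to 1.
#' @export
qda_posterior <- function(model, points) {
  points <- matrix(points, ncol = length(model$means[[1]]))
  logd <- vapply(model$classes, function(cl) {
    S <- model$covs[[cl]]; mu <- model$means[[cl]]
    ch <- chol(S)
    z <- forwardsolve(t(ch), t(sweep(points, 2, mu)))
    -0.5 * colSums(z^2) - sum(log(diag(ch))) -
      0.5 * ncol(points) * log(2 * pi) + log(model$priors[cl])
  }, numeric(nrow(points)))
  logd <- matrix(logd, nrow = nrow(points),
                 dimnames = list(NULL, model$classes))
  m <- apply(logd, 1, max)
  p <- exp(logd - m)
  p / rowSums(p)
}

#' Leave-one-out cross-validated PCA-QDA classification
#'
#' For each sample the PCA (on the `region` channel matrix) and the QDA on
#' its first `k` scores are refit on the remaining n - 1 samples — so no
#' information from the held-out sample leaks into the model — and the
#' held-out sample is projected and scored. Prediction is the class with
#' the larger posterior; a tie predicts nonpregnant. A per-sample
#' band-ratio score column is attached when `features` is supplied.
#'
#' @param cohort Preprocessed `raman_cohort`.
#' @param region `c(lo, hi)` in cm^-1, default `c(890, 950)`.
#' @param k Number of principal components, default 2.
#' @param lambda QDA regularization, default 1e-6.
#' @param features Optional feature table with `sample_id` and a ratio
#'   column named by `ratio_col`.
#' @param ratio_col Name of the band-ratio column, default `"r900_940"`.
#' @param labels Optional label override (same names as the cohort), used
#'   e.g. for permutation tests.
#' @param priors Prior mode passed to [qda_fit()], default `"equal"`.
#' @return List of class `cv_result`: `per_sample` data frame (sample_id,
#'   label, posterior_pregnant, prediction, band_ratio), `confusion`
#'   (TP/FN/TN/FP), `sensitivity`, `specificity`, `accuracy`,
#'   `balanced_accuracy`, `excluded` (failed folds).
#' @export
loocv <- function(cohort, region = c(890, 950), k = 2, lambda = 1e-6,
                  features = NULL, ratio_col = "r900_940", labels = NULL,
                  priors = c("equal", "empirical")) {
  priors <- match.arg(priors)
  m <- region_matrix(cohort, region[1], region[2])
  if (is.null(labels)) labels <- cohort$labels
  labels <- labels[rownames(m)]
  n <- nrow(m)
  post <- rep(NA_real_, n)
  excluded <- list()
  for (i in seq_len(n)) {
    res <- tryCatch({
      pca <- pca_fit(m[-i, , drop = FALSE], k)
      qda <- qda_fit(pca$scores, labels[-i], lambda, priors)
      sc <- pca_project(pca, m[i, ])
      qda_posterior(qda, sc)[1, "pregnant"]
    }, error = function(e) e)
    if (inherits(res, "error"))
      excluded[[rownames(m)[i]]] <- conditionMessage(res)
    else post[i] <- res
  }
  pred <- ifelse(post > 0.5, "pregnant", "nonpregnant")   # tie -> nonpregnant
  per <- data.frame(sample_id = rownames(m), label = unname(labels),
                    posterior_pregnant = post, prediction = pred)
  if (!is.null(features)) {
    ix <- match(per$sample_id, features$sample_id)
    per$band_ratio <- features[[ratio_col]][ix]
  }
  ok <- !is.na(per$posterior_pregnant)
  cm <- confusion_metrics(per$prediction[ok], per$label[ok])
  structure(c(list(per_sample = per, excluded = excluded), cm),
            class = "cv_result")
}

#' Confusion counts and metrics (pregnant = positive class)
#'
#' @param predictions,labels Aligned character vectors with values
#'   `"pregnant"`/`"nonpregnant"`.
#' @return List: `confusion` (TP, FN, TN, FP), `sensitivity`,
#'   `specificity`, `accuracy`, `balanced_accuracy` (proportions; use
#'   [format_pct()] for display rounding).
#' @export
confusion_metrics <- function(predictions, labels) {
  if (length(predictions) != length(labels))
    stop("predictions and labels differ in length", call. = FALSE)
  tp <- sum(predictions == "pregnant" & labels == "pregnant")
  fn <- sum(predictions == "nonpregnant" & labels == "pregnant")
  tn <- sum(predictions == "nonpregnant" & labels == "nonpregnant")
  fp <- sum(predictions == "pregnant" & labels == "nonpregnant")
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  list(confusion = c(TP = tp, FN = fn, TN = tn, FP = fp),
       sensitivity = sens, specificity = spec,
       accuracy = (tp + tn) / length(labels),
       balanced_accuracy = mean(c(sens, spec)))
}

#' Format a proportion as a display percentage
#'
#' Rounds to `digits` decimals and drops trailing zeros, so `14/15` prints
#' as `"93%"` at `digits = 0` and `10/16` as `"62.5%"` at `digits = 1`.
#'
#' @param x Proportion in `[0, 1]`.
#' @param digits Decimals to keep, default 1.
#' @return Character percentage.
#' @export
format_pct <- function(x, digits = 1) {
  v <- round(100 * x, digits)
  paste0(sub("\\.?0+$", "", formatC(v, format = "f", digits = digits)), "%")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("LOOCV PCA-QDA classification\n")
  cat(sprintf("  confusion: TP=%d FN=%d TN=%d FP=%d\n",
              x$confusion["TP"], x$confusion["FN"],
              x$confusion["TN"], x$confusion["FP"]))
  cat(sprintf("  sensitivity %s, specificity %s, accuracy %s\n",
              format_pct(x$sensitivity), format_pct(x$specificity),
              format_pct(x$accuracy)))
  if (length(x$excluded))
    cat("  excluded folds:", length(x$excluded), "\n")
  invisible(x)
}

#' ROC analysis with Youden-optimal threshold
#'
#' Candidate thresholds are midpoints between consecutive distinct sorted
#' scores plus outer sentinels; a sample is called positive (pregnant) when
#' its score exceeds the threshold. AUC is computed by the trapezoid rule.
#' If the positive group tends to score lower (AUC < 0.5) the score
#' orientation is flipped automatically and flagged. The optimal threshold
#' maximizes Youden's J = sensitivity + specificity - 1, ties broken toward
#' the lower threshold.
#'
#' @param scores Numeric scores (e.g. band-area ratios or QDA posteriors).
#' @param labels Aligned `"pregnant"`/`"nonpregnant"` labels.
#' @param auto_flip Flip orientation when AUC < 0.5, default TRUE.
#' @return List of class `roc_curve`: `thresholds`, `sensitivity`,
#'   `specificity` (per threshold), `auc`, `optimal_threshold`,
#'   `optimal_sensitivity`, `optimal_specificity`, `youden`, `flipped`,
#'   `degenerate`, `rule = "youden"`.
#' @export
roc_analysis <- function(scores, labels, auto_flip = TRUE) {
  if (length(scores) != length(labels))
    stop("scores and labels differ in length", call. = FALSE)
  if (anyNA(scores) || any(!is.finite(scores)))
    stop("scores must be finite", call. = FALSE)
  pos <- labels == "pregnant"
  if (!any(pos) || all(pos))
    stop("both labels must be present", call. = FALSE)
  flipped <- FALSE
  auc_of <- function(sc) {
    r <- rank(sc)
    (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(!pos))
  }
  if (auto_flip && auc_of(scores) < 0.5) {
    scores <- -scores
    flipped <- TRUE
  }
  su <- sort(unique(scores))
  degenerate <- length(su) == 1L
  thr <- if (degenerate) c(su - 1, su + 1) else
    c(su[1] - 1, (su[-1] + su[-length(su)]) / 2, su[length(su)] + 1)
  sens <- vapply(thr, function(t) mean(scores[pos] > t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[!pos] <= t), numeric(1))
  fpr <- 1 - spec
  o <- order(fpr, sens)
  auc <- if (degenerate) 0.5 else
    sum(diff(fpr[o]) * (sens[o][-1] + sens[o][-length(sens)]) / 2)
  auc <- abs(auc)
  j <- sens + spec - 1
  best <- which(j == max(j))[1]          # ties -> lower threshold
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc, optimal_threshold = thr[best],
                 optimal_sensitivity = sens[best],
                 optimal_specificity = spec[best],
                 youden = j[best], flipped = flipped,
                 degenerate = degenerate, rule = "youden"),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f; optimal threshold %.4f (Youden J = %.3f): sensitivity %s, specificity %s%s%s\n",
              x$auc, x$optimal_threshold, x$youden,
              format_pct(x$optimal_sensitivity),
              format_pct(x$optimal_specificity),
              if (x$flipped) " [orientation flipped: lower score = positive]" else "",
              if (x$degenerate) " [degenerate: single distinct score]" else ""))
  invisible(x)
}
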