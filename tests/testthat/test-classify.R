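make_cohort <- function(m, labels, axis) {
  ids <- sprintf("c%02d", seq_len(nrow(m)))
  spectra <- lapply(seq_len(nrow(m)), function(i)
    raman_spectrum(axis, m[i, ], ids[i]))
  names(spectra) <- ids
  raman_cohort(spectra, stats::setNames(labels, ids), axis)
}

test_that("region slicing is half-open on the stated 890-950 window", {
  axis <- seq(600, 1800, by = 1)
  m <- rbind(sin(axis / 40), sin(axis / 40))
  co <- make_cohort(m, c("pregnant", "nonpregnant", "pregnant", "nonpregnant")[1:2], axis)
  rm_ <- region_matrix(co, 890, 950)
  expect_equal(ncol(rm_), 60)
  expect_equal(as.numeric(colnames(rm_)[1]), 890)
  expect_equal(as.numeric(colnames(rm_)[60]), 949)
  expect_identical(rm_[1, ], rm_[2, ])
  expect_error(region_matrix(co, 900, 900), "empty")
  expect_error(region_matrix(co, 100, 200), "empty|outside")
})

test_that("PCA: rank-1 data, decorrelated scores, rank-2 reconstruction", {
  set.seed(30)
  base <- rnorm(40)
  coefs <- rnorm(12)
  m1 <- outer(coefs, base)             # samples exactly on a line
  p1 <- pca_fit(m1, k = 1)
  expect_equal(p1$var_fraction[1], 1, tolerance = 1e-10)
  # asking for more components than the data's rank is an error
  expect_error(pca_fit(m1, k = 2), "rank 1")

  m <- matrix(rnorm(25 * 40), 25, 40)
  p <- pca_fit(m, k = 3)
  cv <- stats::cov(p$scores)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-8 * max(diag(cv)))
  # sign convention: dominant loading element positive
  for (j in 1:3)
    expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)

  u <- matrix(rnorm(15 * 2), 15, 2)
  v <- matrix(rnorm(2 * 40), 2, 40)
  m2 <- u %*% v
  p2 <- pca_fit(m2, k = 2)
  rec <- sweep(p2$scores %*% t(p2$loadings), 2, p2$mean, `+`)
  expect_lt(max(abs(rec - m2)), 1e-8)

  expect_error(pca_fit(m1[, 1:2] * 0, k = 2), "rank")
})

test_that("PCA projection of training rows reproduces their scores", {
  set.seed(31)
  m <- matrix(rnorm(20 * 30), 20, 30)
  p <- pca_fit(m, 2)
  expect_equal(pca_project(p, m), unname(p$scores), ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("QDA posteriors are calibrated Gaussian posteriors", {
  set.seed(32)
  s1 <- matrix(rnorm(100, 0, 1), 50, 2)
  s2 <- matrix(rnorm(100, 8, 1), 50, 2)
  scores <- rbind(s1, s2)
  labels <- rep(c("nonpregnant", "pregnant"), each = 50)
  q <- qda_fit(scores, labels, lambda = 0)
  post <- qda_posterior(q, rbind(q$means$pregnant, q$means$nonpregnant, c(4, 4)))
  expect_equal(rowSums(post), rep(1, 3), tolerance = 1e-12)
  expect_gt(post[1, "pregnant"], 0.99)
  expect_gt(post[2, "nonpregnant"], 0.99)

  # cross-check densities against MASS::qda on the same data
  skip_if_not_installed("MASS")
  mq <- MASS::qda(scores, grouping = labels, prior = c(0.5, 0.5))
  pts <- matrix(rnorm(40, 4, 3), 20, 2)
  mp <- stats::predict(mq, pts)$posterior
  ours <- qda_posterior(q, pts)
  expect_equal(ours[, "pregnant"], unname(mp[, "pregnant"]),
               tolerance = 1e-6)
})

test_that("QDA with equal class covariances reduces to the linear boundary", {
  skip_if_not_installed("MASS")
  set.seed(34)
  cloud <- matrix(rnorm(60), 30, 2) %*% matrix(c(1, .4, .4, 1), 2)
  s1 <- cloud
  s2 <- sweep(cloud, 2, c(3, 1), `+`)   # identical covariance, shifted mean
  scores <- rbind(s1, s2)
  colnames(scores) <- c("PC1", "PC2")
  labels <- rep(c("nonpregnant", "pregnant"), each = 30)
  q <- qda_fit(scores, labels, lambda = 0)
  ml <- MASS::lda(scores, grouping = labels, prior = c(0.5, 0.5))
  grid <- as.matrix(expand.grid(PC1 = seq(-2, 5, by = 0.1),
                                PC2 = seq(-2, 3, by = 0.1)))
  ours <- ifelse(qda_posterior(q, grid)[, "pregnant"] > 0.5,
                 "pregnant", "nonpregnant")
  lin <- as.character(stats::predict(ml, grid)$class)
  expect_gt(mean(ours == lin), 0.995)
})

test_that("qda_fit enforces minimum class sizes and label presence", {
  s <- matrix(rnorm(10), 5, 2)
  expect_error(qda_fit(s, c("pregnant", "pregnant", rep("nonpregnant", 3))),
               "pregnant")
  expect_error(qda_fit(s, rep("pregnant", 5)), "two classes")
})

test_that("LOOCV separates a strong synthetic effect perfectly", {
  cfg <- quick_config(seed = 40, effect_size = 3, noise_sd = 0.005)
  sim <- generate_cohort(cfg)
  refs <- generate_references(cfg)
  pp <- run_chain(sim$cohort, refs$toluene, refs$water)
  cv <- loocv(pp)
  expect_equal(cv$sensitivity, 1)
  expect_equal(cv$specificity, 1)
  expect_equal(unname(cv$confusion["TP"] + cv$confusion["FN"]), 15)
  expect_equal(unname(cv$confusion["TN"] + cv$confusion["FP"]), 16)
})

test_that("LOOCV score of a sample ignores its own label (no leakage)", {
  cfg <- quick_config(seed = 41, n_pregnant = 5, n_nonpregnant = 6)
  sim <- generate_cohort(cfg)
  refs <- generate_references(cfg)
  pp <- run_chain(sim$cohort, refs$toluene, refs$water)
  base <- loocv(pp)
  for (i in seq_len(n_samples(pp))) {
    flipped <- pp$labels
    flipped[i] <- if (flipped[i] == "pregnant") "nonpregnant" else "pregnant"
    cv <- loocv(pp, labels = flipped)
    expect_equal(cv$per_sample$posterior_pregnant[i],
                 base$per_sample$posterior_pregnant[i], tolerance = 1e-12)
  }
})

test_that("LOOCV runs on the smallest legal cohort (5 per class)", {
  cfg <- quick_config(seed = 42, n_pregnant = 5, n_nonpregnant = 5)
  sim <- generate_cohort(cfg)
  refs <- generate_references(cfg)
  pp <- run_chain(sim$cohort, refs$toluene, refs$water)
  cv <- loocv(pp)
  expect_equal(nrow(cv$per_sample), 10)
  expect_length(cv$excluded, 0)
})

test_that("ROC handles separable, uninformative and tied-score inputs", {
  r <- roc_analysis(c(0.1, 0.2, 0.8, 0.9),
                    c("nonpregnant", "nonpregnant", "pregnant", "pregnant"))
  expect_equal(r$auc, 1)
  expect_equal(r$optimal_threshold, 0.5)
  expect_equal(r$optimal_sensitivity, 1)
  expect_equal(r$optimal_specificity, 1)

  r2 <- roc_analysis(rep(c(0.3, 0.7), 4),
                     rep(c("pregnant", "nonpregnant"), each = 4))
  expect_equal(r2$auc, 0.5)

  r3 <- roc_analysis(rep(1, 6), rep(c("pregnant", "nonpregnant"), 3))
  expect_true(r3$degenerate)
  expect_equal(r3$auc, 0.5)
})

test_that("trapezoid AUC equals the Mann-Whitney concordance on random data", {
  set.seed(43)
  for (i in 1:500) {
    n1 <- sample(3:20, 1); n2 <- sample(3:20, 1)
    scores <- c(rnorm(n1, 0.3), round(rnorm(n2), 1))  # ties included
    labels <- c(rep("pregnant", n1), rep("nonpregnant", n2))
    r <- roc_analysis(scores, labels, auto_flip = FALSE)
    expect_equal(r$auc, rank_auc(scores, labels), tolerance = 1e-12)
  }
  skip_if_not_installed("pROC")
  set.seed(44)
  sc <- rnorm(40); lb <- rep(c("pregnant", "nonpregnant"), 20)
  r <- roc_analysis(sc, lb, auto_flip = FALSE)
  pr <- pROC::roc(response = lb, predictor = sc, levels = c("nonpregnant", "pregnant"),
                  direction = "<", quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
})

test_that("orientation auto-flip reports lower-score-positive markers", {
  set.seed(45)
  sc <- c(rnorm(20, 0), rnorm(20, 2))
  lb <- c(rep("pregnant", 20), rep("nonpregnant", 20))
  r <- roc_analysis(sc, lb)
  expect_true(r$flipped)
  expect_gt(r$auc, 0.5)
})

test_that("confusion metrics reproduce the per-group prediction tallies", {
  labels <- c(rep("pregnant", 15), rep("nonpregnant", 16))
  pred <- c(rep("pregnant", 14), "nonpregnant",
            rep("nonpregnant", 10), rep("pregnant", 6))
  cm <- confusion_metrics(pred, labels)
  expect_equal(unname(cm$confusion), c(14, 1, 10, 6))
  expect_equal(cm$sensitivity, 14 / 15)
  expect_equal(cm$specificity, 10 / 16)
  expect_equal(format_pct(cm$sensitivity, 0), "93%")
  expect_equal(format_pct(cm$specificity, 1), "62.5%")

  all_right <- confusion_metrics(labels, labels)
  expect_equal(all_right$sensitivity, 1)
  expect_equal(all_right$specificity, 1)
  all_pos <- confusion_metrics(rep("pregnant", 31), labels)
  expect_equal(all_pos$sensitivity, 1)
  expect_equal(all_pos$specificity, 0)
  expect_error(confusion_metrics(pred[1:3], labels), "length")
})
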