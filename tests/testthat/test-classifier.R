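random_table <- function(n_per_donor = 8, n_ch = 30, seed = 1,
                         lipid_effect = 0) {
  set.seed(seed)
  feats <- NULL; label <- donor <- id <- character()
  shape <- abs(sin(seq_len(n_ch) / 3)) + 0.5
  for (d in c("d1", "d2", "d3")) {
    for (i in seq_len(n_per_donor)) {
      ph <- sample(c("M0", "M1", "M2"), 1)
      x <- shape + rnorm(n_ch, 0, 0.05) +
        lipid_effect * (ph == "M1") * (seq_len(n_ch) > n_ch / 2)
      feats <- rbind(feats, x / mean(x))
      label <- c(label, ph); donor <- c(donor, d)
      id <- c(id, paste0(d, "_", i))
    }
  }
  structure(list(features = feats, label = label, donor = donor, id = id,
                 axis = tiny_axis(n_ch), mode = "per_image"),
            class = "feature_table")
}

test_that("mean normalization yields unit mean and rejects bad input", {
  expect_equal(mean_normalize(c(1, 2, 3)), c(0.5, 1.0, 1.5))
  x <- mean_normalize(runif(50, 1, 9))
  expect_equal(mean(x), 1, tolerance = 1e-12)
  expect_equal(mean_normalize(x), x)  # idempotent
  expect_error(mean_normalize(c(-2, 1)), "positive mean")
})

test_that("feature tables average normalized spectra per image", {
  bench <- generate_benchmark_set(small_scene_config(seed = 13L))
  pp <- preprocess_set(bench$images)
  ft <- build_feature_table(pp)
  expect_equal(nrow(ft$features), length(pp$images))
  expect_equal(unname(rowMeans(ft$features)),
               rep(1, nrow(ft$features)), tolerance = 1e-12)
  expect_equal(length(unique(ft$donor)), 3)
  fts <- build_feature_table(pp, "per_spectrum")
  # row count reconciles with the preprocessing report
  expect_equal(nrow(fts$features), sum(pp$report$n_retained))
  # an image of duplicated spectra averages to the normalized spectrum
  im <- pp$images[[1]]
  im$spectra <- im$spectra[c(2, 2), ]
  pp1 <- structure(list(images = list(a = im), axis = pp$axis,
                        report = pp$report[1, ]),
                   class = "preprocessed_set")
  f1 <- build_feature_table(pp1)
  expect_equal(drop(f1$features), mean_normalize(im$spectra[1, ]),
               ignore_attr = TRUE)
})

test_that("PCA-LDA separates separable clouds and is duplication-invariant", {
  tab <- random_table(seed = 5, lipid_effect = 0.4)
  fit <- fit_pca_lda(tab, 2, "M1_vs_rest")
  pred <- predict(fit, tab)
  expect_equal(pred$class, ifelse(tab$label == "M1", "M1", "rest"))
  dup <- tab
  dup$features <- rbind(tab$features, tab$features)
  dup$label <- c(tab$label, tab$label)
  dup$donor <- c(tab$donor, tab$donor)
  dup$id <- c(tab$id, paste0(tab$id, "_copy"))
  fit2 <- fit_pca_lda(dup, 2, "M1_vs_rest")
  # invariant up to the pooled-covariance normalization: same direction,
  # same boundary, hence identical classes and perfectly correlated scores
  expect_equal(predict(fit2, tab)$class, pred$class)
  expect_equal(stats::cor(predict(fit2, tab)$score, pred$score), 1,
               tolerance = 1e-9)
})

test_that("full-rank PCA-LDA equals LDA on the raw features", {
  set.seed(9)
  X <- matrix(rnorm(12 * 4), 12, 4)
  y <- rep(c("M1", "M0"), each = 6)
  X[y == "M1", 1] <- X[y == "M1", 1] + 1.5
  tab <- structure(list(features = X, label = y,
                        donor = rep("d", 12), id = as.character(1:12),
                        axis = NULL, mode = "per_image"),
                   class = "feature_table")
  fit <- fit_pca_lda(tab, 4, "M1_vs_rest")
  direct <- MASS::lda(X, grouping = factor(y, c("M0", "M1")),
                      prior = c(0.5, 0.5))
  expect_equal(predict(fit, tab)$class,
               ifelse(predict(direct, X)$class == "M1", "M1", "rest"))
  # decision scores are proportional to the raw-feature discriminant
  raw_ld <- drop(scale(X, center = TRUE, scale = FALSE) %*% direct$scaling)
  expect_equal(abs(cor(predict(fit, tab)$score, raw_ld)), 1,
               tolerance = 1e-9)
})

test_that("back-projected spectral scores equal the PCA-score path", {
  tab <- random_table(seed = 7, lipid_effect = 0.2)
  fit <- fit_pca_lda(tab, 2, "M1_vs_rest")
  Xc <- sweep(tab$features, 2, fit$center)
  via_scores <- drop((Xc %*% fit$loadings) %*% fit$scaling) + fit$intercept
  via_spectral <- predict(fit, tab)$score
  expect_equal(via_scores, via_spectral, tolerance = 1e-9)
  # predictions agree with MASS's own posterior rule
  mass_cls <- predict(fit$lda, Xc %*% fit$loadings)$class
  expect_equal(predict(fit, tab)$class, as.character(mass_cls))
})

test_that("classification metrics follow the confusion-matrix arithmetic", {
  truth <- c(rep("M1", 10), rep("rest", 10))
  pred <- c(rep("M1", 9), "rest", rep("rest", 8), "M1", "M1")
  scores <- c(rnorm(10, 2), rnorm(10))
  m <- classification_metrics(truth, pred, scores, "M1")
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$balanced_accuracy, 0.85)
  perfect <- classification_metrics(truth, truth,
                                    ifelse(truth == "M1", 1, -1), "M1")
  expect_equal(unlist(perfect[c("sensitivity", "specificity",
                                "balanced_accuracy", "accuracy", "auc")]),
               c(sensitivity = 1, specificity = 1, balanced_accuracy = 1,
                 accuracy = 1, auc = 1))
  # constant scores: every pair ties at one half
  tied <- classification_metrics(truth, pred, rep(0, 20), "M1")
  expect_equal(tied$auc, 0.5)
  expect_error(classification_metrics(rep("M1", 3), rep("M1", 3),
                                      1:3, "M1"), "both classes")
})

test_that("rank AUC equals exhaustive pairwise comparison (and pROC)", {
  set.seed(10)
  for (i in 1:10) {
    n <- sample(10:50, 1)
    pos <- runif(n) < 0.5
    if (!any(pos)) pos[1] <- TRUE
    if (all(pos)) pos[1] <- FALSE
    scores <- round(rnorm(n), 1)  # rounding induces ties
    pairwise <- mean(outer(scores[pos], scores[!pos],
                           function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(ramanphen:::rank_auc(scores, pos), pairwise)
  }
  if (requireNamespace("pROC", quietly = TRUE)) {
    expect_equal(ramanphen:::rank_auc(scores, pos),
                 as.numeric(pROC::auc(pROC::roc(pos, scores,
                                                quiet = TRUE,
                                                direction = "<"))))
  }
})

test_that("leave-one-donor-out folds never leak donors and pool correctly", {
  tab <- random_table(seed = 11, lipid_effect = 0.4)
  cv <- lodo_cv(tab, 2, "M1_vs_rest")
  expect_equal(sort(unique(cv$predictions$donor)), c("d1", "d2", "d3"))
  expect_equal(nrow(cv$predictions), nrow(tab$features))
  expect_false(anyDuplicated(cv$predictions$id) > 0)
  for (d in unique(tab$donor)) {
    test_ids <- cv$predictions$id[cv$predictions$donor == d]
    expect_setequal(test_ids, tab$id[tab$donor == d])
  }
  # a class signature planted identically across donors is fully learnable
  expect_equal(cv$metrics$balanced_accuracy, 1.0)
  expect_equal(dim(cv$cosine), c(3, 3))
})

test_that("label permutation collapses CV accuracy to chance", {
  accs <- vapply(1:20, function(s) {
    tab <- random_table(seed = 100, lipid_effect = 0.4)
    set.seed(2000 + s)
    tab$label <- sample(tab$label)
    out <- tryCatch(lodo_cv(tab, 2, "M1_vs_rest")$metrics$balanced_accuracy,
                    error = function(e) NA_real_)  # single-class folds
    out
  }, 0)
  accs <- accs[!is.na(accs)]
  expect_gt(length(accs), 10)
  # binomial sd at ~8 positives per fold pooled over 24 rows
  expect_lt(abs(mean(accs) - 0.5), 3 * stats::sd(accs) / sqrt(length(accs)) +
              0.1)
})

test_that("the M0-vs-M2 task drops M1 rows and errors on single-class folds", {
  tab <- random_table(seed = 15)
  cv <- lodo_cv(tab, 2, "M0_vs_M2")
  expect_true(all(cv$predictions$truth %in% c("M0", "M2")))
  solo <- tab
  solo$label[solo$donor != "d1"] <- "M0"
  solo$label[solo$donor == "d1"] <- "M2"
  expect_error(lodo_cv(solo, 2, "M0_vs_M2"), "single-class")
})
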