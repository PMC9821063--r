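# PCA-LDA discrimination of macrophage phenotypes on mean-normalized
# spectra, with leave-one-donor-out cross-validation, pooled-test metrics
# and back-projected coefficient stability.

#' Mean-normalize a spectrum
#'
#' Divides by the mean intensity so the output has mean exactly 1.
#'
#' @param intensities Numeric vector with positive mean.
#' @return Normalized vector.
#' @export
mean_normalize <- function(intensities) {
  m <- mean(intensities)
  if (!is.finite(m) || m <= 0)
    stop("mean normalization requires a positive mean", call. = FALSE)
  intensities / m
}

#' Build the classification feature table
#'
#' In `per_image` mode every retained spectrum is mean-normalized and then
#' averaged within its image: one row (one average spectrum) per image. In
#' `per_spectrum` mode each retained mean-normalized spectrum is its own
#' row. Phenotype labels and donor ids are attached from the image
#' metadata.
#'
#' @param pp A `preprocessed_set`.
#' @param mode `"per_image"` (default) or `"per_spectrum"`.
#' @return Object of class `"feature_table"`: `features` (rows x channels),
#'   `label`, `donor`, `id`, `axis`, `mode`.
#' @export
build_feature_table <- function(pp, mode = c("per_image", "per_spectrum")) {
  stopifnot(inherits(pp, "preprocessed_set"))
  mode <- match.arg(mode)
  feats <- list(); labels <- character(); donors <- character(); ids <- character()
  for (im in pp$images) {
    if (!nrow(im$spectra))
      stop(sprintf("image '%s' has no retained spectra", im$cell_id),
           call. = FALSE)
    norm <- im$spectra / rowMeans(im$spectra)
    if (any(!is.finite(norm)))
      stop(sprintf("image '%s': spectrum with non-positive mean", im$cell_id),
           call. = FALSE)
    if (mode == "per_image") {
      feats[[im$cell_id]] <- colMeans(norm)
      labels <- c(labels, im$phenotype)
      donors <- c(donors, im$donor_id)
      ids <- c(ids, im$cell_id)
    } else {
      feats[[im$cell_id]] <- norm
      labels <- c(labels, rep(im$phenotype, nrow(norm)))
      donors <- c(donors, rep(im$donor_id, nrow(norm)))
      ids <- c(ids, sprintf("%s:%d", im$cell_id, seq_len(nrow(norm))))
    }
  }
  X <- if (mode == "per_image") do.call(rbind, feats) else do.call(rbind, feats)
  rownames(X) <- NULL
  structure(list(features = X, label = labels, donor = donors, id = ids,
                 axis = pp$axis, mode = mode), class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d rows (%s) x %d channels, %d donors [%s]\n",
              nrow(x$features), x$mode, ncol(x$features),
              length(unique(x$donor)),
              paste(sprintf("%s:%d", names(table(x$label)), table(x$label)),
                    collapse = " ")))
  invisible(x)
}

task_binary <- function(label, task) {
  if (task == "M1_vs_rest") {
    list(keep = rep(TRUE, length(label)), positive = "M1", negative = "rest",
         binary = ifelse(label == "M1", "M1", "rest"))
  } else {
    keep <- label %in% c("M0", "M2")
    list(keep = keep, positive = "M2", negative = "M0",
         binary = label[keep])
  }
}

subset_table <- function(table, rows) {
  structure(list(features = table$features[rows, , drop = FALSE],
                 label = table$label[rows], donor = table$donor[rows],
                 id = table$id[rows], axis = table$axis, mode = table$mode),
            class = "feature_table")
}

#' Fit a PCA-LDA discrimination model
#'
#' Centers the training features on their mean, projects onto the top
#' `n_components` principal directions (covariance PCA, no variance
#' scaling), and fits a two-class linear discriminant with equal priors on
#' the scores (via [MASS::lda()]). The discriminant is back-projected to
#' the spectral axis, giving a single coefficient per wavenumber; the
#' decision score is `(x - center) %*% coefficients + intercept`, positive
#' for the positive class (M1 in the `M1_vs_rest` task, M2 in `M0_vs_M2`).
#'
#' @param table A [build_feature_table()] result (training rows). For the
#'   `M0_vs_M2` task M1 rows are dropped automatically.
#' @param n_components Number of principal components (default 2).
#' @param task `"M1_vs_rest"` or `"M0_vs_M2"`.
#' @return Object of class `"pca_lda"`.
#' @export
fit_pca_lda <- function(table, n_components = 2L,
                        task = c("M1_vs_rest", "M0_vs_M2")) {
  stopifnot(inherits(table, "feature_table"))
  task <- match.arg(task)
  tb <- task_binary(table$label, task)
  X <- table$features[tb$keep, , drop = FALSE]
  y <- factor(tb$binary, levels = c(tb$negative, tb$positive))
  if (nlevels(droplevels(y)) < 2L)
    stop("training set contains a single class", call. = FALSE)
  if (n_components >= nrow(X))
    stop("n_components must be smaller than the number of training rows",
         call. = FALSE)
  center <- colMeans(X)
  Xc <- sweep(X, 2L, center)
  sv <- svd(Xc, nu = 0L, nv = n_components)
  loadings <- sv$v  # channels x k, orthonormal columns
  scores <- Xc %*% loadings
  fit <- MASS::lda(scores, grouping = y, prior = c(0.5, 0.5))
  w <- fit$scaling[, 1L]
  proj <- drop(scores %*% w)
  m_neg <- mean(proj[y == tb$negative]); m_pos <- mean(proj[y == tb$positive])
  if (m_pos < m_neg) {  # orient so the positive class scores higher
    w <- -w; proj <- -proj
    tmp <- m_neg; m_neg <- -m_pos; m_pos <- -tmp
  }
  intercept <- -(m_pos + m_neg) / 2  # equal-prior midpoint boundary
  structure(list(center = center, loadings = loadings, scaling = w,
                 intercept = intercept,
                 coefficients = drop(loadings %*% w),
                 positive = tb$positive, negative = tb$negative,
                 task = task, n_components = n_components,
                 axis = table$axis, lda = fit),
            class = "pca_lda")
}

#' @export
print.pca_lda <- function(x, ...) {
  cat(sprintf("<pca_lda> %s: %d PCs on %d channels, positive class '%s'\n",
              x$task, x$n_components, length(x$coefficients), x$positive))
  invisible(x)
}

#' @export
coef.pca_lda <- function(object, ...) {
  stats::setNames(object$coefficients, as.numeric(object$axis))
}

#' Predict phenotype classes and decision scores
#'
#' @param object A fitted [fit_pca_lda()] model.
#' @param newdata A `feature_table` or a features matrix on the training
#'   axis.
#' @param ... Unused.
#' @return Data frame with `score` (positive favors the positive class)
#'   and `class`.
#' @export
predict.pca_lda <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "feature_table")) newdata$features
       else as.matrix(newdata)
  score <- drop(sweep(X, 2L, object$center) %*% object$coefficients) +
    object$intercept
  data.frame(score = score,
             class = ifelse(score > 0, object$positive, object$negative),
             stringsAsFactors = FALSE)
}

# Mann-Whitney AUC via midranks; ties count one half.
rank_auc <- function(scores, is_positive) {
  n1 <- sum(is_positive); n0 <- sum(!is_positive)
  r <- rank(scores)
  (sum(r[is_positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Pooled classification metrics
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, balanced accuracy
#' (their mean), plain accuracy, and ROC AUC in the Mann-Whitney form (the
#' probability that a random positive's decision score exceeds a random
#' negative's, ties counting one half).
#'
#' @param truth,predicted Class label vectors.
#' @param scores Decision scores (higher favors the positive class).
#' @param positive_class The positive label.
#' @return Named list: sensitivity, specificity, balanced_accuracy,
#'   accuracy, auc.
#' @export
classification_metrics <- function(truth, predicted, scores, positive_class) {
  pos <- truth == positive_class
  if (!any(pos) || all(pos))
    stop("truth must contain both classes", call. = FALSE)
  pred_pos <- predicted == positive_class
  sens <- sum(pos & pred_pos) / sum(pos)
  spec <- sum(!pos & !pred_pos) / sum(!pos)
  list(sensitivity = sens, specificity = spec,
       balanced_accuracy = (sens + spec) / 2,
       accuracy = mean(truth == predicted),
       auc = rank_auc(scores, pos))
}

#' Leave-one-donor-out cross-validation
#'
#' One fold per donor: the model is fitted on the remaining donors' rows
#' (PCA recomputed within each fold from training data only) and applied
#' to the held-out donor. Metrics are computed once on the pooled test
#' predictions of all folds. Coefficient stability across folds is
#' reported as pairwise cosine similarities of the back-projected
#' coefficient vectors.
#'
#' @param table A [build_feature_table()] result.
#' @param n_components,task Passed to [fit_pca_lda()].
#' @return Object of class `"cv_report"`: `predictions` (pooled data frame
#'   with id, donor, truth, score, predicted), `metrics`, `coefficients`
#'   (fold x channel matrix), `cosine` (fold similarity matrix), `task`,
#'   `positive`.
#' @export
lodo_cv <- function(table, n_components = 2L,
                    task = c("M1_vs_rest", "M0_vs_M2")) {
  stopifnot(inherits(table, "feature_table"))
  task <- match.arg(task)
  tb <- task_binary(table$label, task)
  tab <- subset_table(table, tb$keep)
  donors <- sort(unique(tab$donor))
  if (length(donors) < 2L)
    stop("leave-one-donor-out CV needs at least 2 donors", call. = FALSE)
  preds <- list(); coefs <- list()
  for (d in donors) {
    train <- tab$donor != d
    bin_train <- task_binary(tab$label[train], task)$binary
    if (length(unique(bin_train)) < 2L)
      stop(sprintf("fold for donor '%s': training set is single-class", d),
           call. = FALSE)
    fit <- fit_pca_lda(subset_table(tab, train), n_components, task)
    test <- subset_table(tab, !train)
    pr <- predict(fit, test)
    preds[[d]] <- data.frame(id = test$id, donor = d,
                             truth = task_binary(test$label, task)$binary,
                             score = pr$score, predicted = pr$class,
                             stringsAsFactors = FALSE)
    coefs[[d]] <- fit$coefficients
  }
  pooled <- do.call(rbind, c(preds, make.row.names = FALSE))
  metrics <- classification_metrics(pooled$truth, pooled$predicted,
                                    pooled$score, tb$positive)
  C <- do.call(rbind, coefs)
  nrm <- sqrt(rowSums(C^2))
  cosine <- (C / nrm) %*% t(C / nrm)
  structure(list(predictions = pooled, metrics = metrics,
                 coefficients = C, cosine = cosine, task = task,
                 positive = tb$positive, axis = tab$axis,
                 n_components = n_components),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<cv_report> %s, %d folds, %d pooled test predictions\n",
              x$task, nrow(x$coefficients), nrow(x$predictions)))
  cat(sprintf("  balanced accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%, accuracy %.1f%%, ROC AUC %.1f%%\n",
              100 * m$balanced_accuracy, 100 * m$sensitivity,
              100 * m$specificity, 100 * m$accuracy, 100 * m$auc))
  off <- x$cosine[upper.tri(x$cosine)]
  if (length(off))
    cat(sprintf("  coefficient stability (pairwise cosine): %.3f..%.3f\n",
                min(off), max(off)))
  invisible(x)
}

#' @export
summary.cv_report <- function(object, ...) {
  print(object)
  folds <- unique(object$predictions$donor)
  for (d in folds) {
    p <- object$predictions[object$predictions$donor == d, ]
    cat(sprintf("  fold %s: %d test rows, %.1f%% correct\n", d, nrow(p),
                100 * mean(p$truth == p$predicted)))
  }
  invisible(object)
}
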