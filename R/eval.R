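#' Stratified k-fold assignment
#'
#' Deterministic given the seed; within each class, shuffled samples are
#' dealt round-robin so per-fold class counts differ by at most 1.
#'
#' @param labels Binary label vector (two distinct values).
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in 1..k, one per sample.
#' @examples
#' table(stratified_kfold(rep(0:1, each = 20), 10, seed = 1))
#' @export
stratified_kfold <- function(labels, k, seed) {
  n <- length(labels)
  if (k > n) stop("k exceeds the number of samples")
  if (length(unique(labels)) != 2) stop("labels must be binary")
  if (k > 2 * min(table(labels))) {
    stop("k too large for the smallest class (need k <= 2 * min class size)")
  }
  folds <- integer(n)
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' ROC AUC by the rank (Mann-Whitney) formulation
#'
#' `AUC = (sum of positive ranks - n1 (n1 + 1) / 2) / (n1 n0)` with mid-ranks,
#' so ties contribute 1/2.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels; the larger value is the positive class.
#' @return AUC in [0, 1].
#' @examples
#' roc_auc(c(0.9, 0.8, 0.3), c(1, 0, 1))  # 0.5
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels == max(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Reference classifier: nearest centroid
#'
#' Scores a sample by its projection onto the (variance-scaled) difference
#' of class centroids; equivalent to diagonal LDA up to monotone transform.
#'
#' @return A classifier object (list with `fit` and `score` functions)
#'   usable with [cv_auc()].
#' @export
classifier_nearest_centroid <- function() {
  list(
    name = "nearest_centroid",
    fit = function(x, y) {
      pos <- y == max(y)
      mu1 <- colMeans(x[pos, , drop = FALSE])
      mu0 <- colMeans(x[!pos, , drop = FALSE])
      s <- apply(x, 2, stats::sd)
      list(w = (mu1 - mu0) / (s^2 + 1e-8), mid = (mu1 + mu0) / 2)
    },
    score = function(model, x) {
      drop(sweep(x, 2, model$mid) %*% model$w)
    }
  )
}

#' Reference classifier: k-nearest neighbors
#'
#' Scores a sample by the fraction of its k nearest training samples
#' (Euclidean distance) that belong to the positive class.
#'
#' @param k Neighborhood size (default 5).
#' @return A classifier object for [cv_auc()].
#' @export
classifier_knn <- function(k = 5) {
  list(
    name = sprintf("knn%d", k),
    fit = function(x, y) list(x = x, y = as.integer(y == max(y)), k = min(k, nrow(x))),
    score = function(model, x) {
      apply(x, 1, function(row) {
        d <- sqrt(colSums((t(model$x) - row)^2))
        mean(model$y[order(d)[seq_len(model$k)]])
      })
    }
  )
}

#' Cross-validated ROC AUC
#'
#' Trains the classifier on k-1 folds and scores the held-out fold,
#' reporting the per-fold and mean AUC. A fold whose held-out samples are
#' single-class is skipped with a warning (cannot happen with stratified
#' folds unless a class count is below k).
#'
#' @param x Feature matrix (samples x features), e.g. normalized DE-circRNA
#'   expression.
#' @param labels Binary labels (tumor = positive).
#' @param classifier A classifier object ([classifier_nearest_centroid()],
#'   [classifier_knn()], or any list with fit(x, y) and score(model, x)).
#' @param k Number of folds (default 10).
#' @param seed Seed for the fold assignment.
#' @return List of class `cv_result`: fold_auc, mean_auc, folds, classifier.
#' @export
cv_auc <- function(x, labels, classifier = classifier_nearest_centroid(),
                   k = 10, seed = 1) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(labels))
  folds <- stratified_kfold(labels, k, seed)
  fold_auc <- rep(NA_real_, k)
  for (f in seq_len(k)) {
    test <- folds == f
    if (length(unique(labels[test])) < 2) {
      warning("fold ", f, " held out a single class; skipped")
      next
    }
    model <- classifier$fit(x[!test, , drop = FALSE], labels[!test])
    s <- classifier$score(model, x[test, , drop = FALSE])
    fold_auc[f] <- roc_auc(s, labels[test])
  }
  structure(list(fold_auc = fold_auc, mean_auc = mean(fold_auc, na.rm = TRUE),
                 folds = folds, classifier = classifier$name %||% "custom"),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold CV (%s): mean AUC = %.3f\n",
              length(x$fold_auc), x$classifier, x$mean_auc))
  invisible(x)
}
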