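#' Extract a feature matrix from an image dataset
#'
#' @param dataset An [image_dataset()].
#' @param mode `"pixels"` (flattened intensities) or `"pca"` (projection onto
#'   the top principal components of the centered pixel matrix).
#' @param n_components Number of PCA components (default 2, as used for 2-D
#'   visualization).
#' @return Numeric matrix with one row per sample, row order matching the
#'   dataset indices.
#' @export
extract_features <- function(dataset, mode = c("pixels", "pca"),
                             n_components = 2L) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "image_dataset"))
  N <- n_samples(dataset)
  if (N == 0L) stop_fmt("dataset is empty")
  d <- dim(dataset$images)
  X <- matrix(dataset$images, N, prod(d[-1]))
  if (mode == "pixels") return(X)
  if (n_components > min(N, ncol(X)))
    stop_fmt("n_components = %d exceeds min(N, pixels) = %d",
             n_components, min(N, ncol(X)))
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = n_components)
  unname(p$x[, seq_len(n_components), drop = FALSE])
}

#' KNN classification with a held-out split
#'
#' Seeded train/test split, majority vote among the `k` nearest Euclidean
#' neighbors, confusion matrix with rows = true classes.
#'
#' @param features Numeric feature matrix (rows = samples).
#' @param labels Class labels (factor, character or integer), length = rows.
#' @param k Number of neighbors (default 5).
#' @param test_fraction Held-out share in `(0, 1)` (default 0.25).
#' @param seed Integer seed for the split.
#' @return List with `confusion` (true x predicted table), `accuracy`, and
#'   `test_indices`.
#' @export
knn_evaluate <- function(features, labels, k = 5L, test_fraction = 0.25,
                         seed = 1L) {
  if (k < 1L) stop_fmt("k must be >= 1")
  if (test_fraction <= 0 || test_fraction >= 1)
    stop_fmt("test_fraction must be in (0, 1)")
  labels <- factor(labels)
  N <- length(labels)
  n_test <- round(N * test_fraction)
  test_idx <- with_seed(seed, sort(sample.int(N, n_test)))
  train_idx <- setdiff(seq_len(N), test_idx)
  if (k > length(train_idx))
    stop_fmt("k = %d exceeds training size %d", k, length(train_idx))
  pred <- knn_predict(features[train_idx, , drop = FALSE], labels[train_idx],
                      features[test_idx, , drop = FALSE], k)
  confusion <- table(true = labels[test_idx],
                     predicted = factor(pred, levels = levels(labels)))
  list(confusion = confusion,
       accuracy = mean(pred == labels[test_idx]),
       test_indices = test_idx)
}

#' Majority-vote KNN prediction
#'
#' @param train_x,train_y Training features and labels.
#' @param test_x Query features.
#' @param k Number of neighbors.
#' @return Factor of predicted labels for the query rows.
#' @export
knn_predict <- function(train_x, train_y, test_x, k = 5L) {
  train_y <- factor(train_y)
  # class::knn breaks distance ties at random; pin the RNG for determinism
  with_seed(0L, class::knn(train_x, test_x, train_y, k = k))
}

#' k-means clustering scored by majority-mapped accuracy
#'
#' Standard k-means with seeded initialization; each cluster is mapped to its
#' majority true class and accuracy is computed under that mapping (bounded
#' below by the largest class share, hence >= 1/K).
#'
#' @param features Numeric feature matrix.
#' @param labels True class labels.
#' @param k_clusters Number of clusters (default: number of classes).
#' @param seed Integer seed.
#' @param iter_max Maximum Lloyd iterations.
#' @return List with `confusion` (true x mapped class), `accuracy`,
#'   `cluster` assignments, `mapping` (cluster -> class), and
#'   `tot_withinss`.
#' @export
kmeans_evaluate <- function(features, labels, k_clusters = NULL, seed = 1L,
                            iter_max = 25L) {
  labels <- factor(labels)
  k_clusters <- k_clusters %||% nlevels(labels)
  N <- nrow(features)
  if (k_clusters < 1L || k_clusters > N)
    stop_fmt("k_clusters must be within 1..%d", N)
  km <- with_seed(seed, stats::kmeans(features, centers = k_clusters,
                                      iter.max = iter_max, nstart = 5L))
  mapping <- vapply(seq_len(k_clusters), function(cl) {
    members <- labels[km$cluster == cl]
    if (length(members) == 0L) levels(labels)[1L]
    else names(which.max(table(members)))
  }, "")
  pred <- factor(mapping[km$cluster], levels = levels(labels))
  list(confusion = table(true = labels, predicted = pred),
       accuracy = mean(pred == labels),
       cluster = km$cluster, mapping = mapping,
       tot_withinss = km$tot.withinss)
}
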