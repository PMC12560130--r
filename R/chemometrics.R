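#' Row-standardise a fingerprint matrix (remove the bulk-RI shift)
#'
#' Subtracts each row's own mean over the 24 shifts. Because ethanol and
#' dissolved solids raise the bulk refractive index and shift all 24
#' sensors nearly uniformly, removing the per-row mean strips the gross
#' RI effect while leaving the differential chemistry pattern intact.
#' Idempotent; invariant to adding any constant to a row.
#'
#' @param fm a `fingerprint_matrix` (or data.frame with `s01`..`s24`).
#' @return A `centered_matrix`: the input with shift columns centred per
#'   row and a `row_mean` column logging each subtracted mean (nm).
#' @export
row_standardize <- function(fm) {
  scols <- sensor_columns()
  vals <- as.matrix(fm[, scols])
  if (any(!is.finite(vals))) stop("rows with missing entries rejected")
  mu <- rowMeans(vals)
  out <- fm
  out[, scols] <- vals - mu
  if ("row_mean" %in% names(fm)) {
    out$row_mean <- fm$row_mean + mu   # idempotence keeps the full log
  } else {
    out$row_mean <- mu
  }
  class(out) <- unique(c("centered_matrix", class(fm)))
  out
}

#' Principal component analysis of a fingerprint matrix
#'
#' Column-mean-centred PCA on the covariance of the 24 shift columns
#' (no unit-variance scaling by default: the columns share units of
#' nm). Signs follow a deterministic convention: within each component
#' the largest-magnitude loading is positive.
#'
#' @param fm a `fingerprint_matrix` or `centered_matrix`.
#' @param n_components number of components returned.
#' @param scale. also scale columns to unit variance (correlation PCA).
#' @return List with `scores` (rows x k), `loadings` (24 x k),
#'   `variance_fraction` (length k) and the row `metadata`.
#' @export
run_pca <- function(fm, n_components = 3L, scale. = FALSE) {
  vals <- fingerprint_values(fm)
  if (nrow(vals) < 2) stop("PCA needs at least 2 rows")
  k <- min(n_components, ncol(vals), nrow(vals) - 1L)
  p <- stats::prcomp(vals, center = TRUE, scale. = scale., rank. = k)
  # deterministic sign: largest |loading| positive per component
  for (j in seq_len(ncol(p$rotation))) {
    i <- which.max(abs(p$rotation[, j]))
    if (p$rotation[i, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  meta_cols <- setdiff(names(fm), sensor_columns())
  list(scores = p$x[, seq_len(k), drop = FALSE],
       loadings = p$rotation[, seq_len(k), drop = FALSE],
       variance_fraction = (p$sdev^2 / sum(p$sdev^2))[seq_len(k)],
       metadata = if ("status" %in% names(fm))
         fm[fm$status == "ok", meta_cols, drop = FALSE]
       else fm[, meta_cols, drop = FALSE])
}

#' Stratified 50:50 train/validation split
#'
#' Rows are allocated per stratum so every stratum is represented
#' equally in training and validation; with an odd stratum the extra
#' row goes to training. Disjoint and exhaustive for every seed.
#'
#' @param fm a `fingerprint_matrix`.
#' @param stratify_on metadata column defining strata (e.g.
#'   `"sample_id"`).
#' @param fraction training fraction (default 0.5).
#' @param seed integer seed.
#' @return List with data.frames `train` and `validation`.
#' @export
stratified_split <- function(fm, stratify_on = "sample_id",
                             fraction = 0.5, seed = 1L) {
  strata <- fm[[stratify_on]]
  if (is.null(strata)) stop("no such column: ", stratify_on)
  counts <- table(strata)
  if (any(counts < 2))
    stop("singleton stratum: ", paste(names(counts)[counts < 2],
                                      collapse = ", "))
  train_idx <- withr::with_seed(as.integer(seed), {
    unlist(lapply(unique(strata), function(g) {
      rows <- which(strata == g)
      n_train <- ceiling(length(rows) * fraction)
      sample(rows, n_train)
    }), use.names = FALSE)
  })
  list(train = fm[sort(train_idx), , drop = FALSE],
       validation = fm[setdiff(seq_len(nrow(fm)), train_idx), ,
                       drop = FALSE])
}

# Pooled within-class covariance with optional shrinkage toward a
# scaled identity. gamma = NULL selects automatic shrinkage, applied
# when the smallest class has fewer than 3x dimensions rows.
pooled_covariance <- function(x, labels, gamma = NULL) {
  p <- ncol(x)
  classes <- unique(labels)
  S <- matrix(0, p, p)
  n_tot <- 0L
  min_n <- Inf
  for (g in classes) {
    xi <- x[labels == g, , drop = FALSE]
    min_n <- min(min_n, nrow(xi))
    if (nrow(xi) > 1) {
      S <- S + stats::cov(xi) * (nrow(xi) - 1)
      n_tot <- n_tot + nrow(xi) - 1L
    }
  }
  S <- S / max(n_tot, 1L)
  if (is.null(gamma)) gamma <- if (min_n < 3 * p) 0.1 else 0
  if (gamma > 0)
    S <- (1 - gamma) * S + gamma * mean(diag(S)) * diag(p)
  S
}

#' Linear discriminant classification with a held-out validation set
#'
#' Fits a linear discriminant model (Gaussian classes, pooled
#' within-class covariance) on the training rows and assigns each
#' validation row to the class with the highest discriminant score.
#' When classes have few rows relative to the 24 dimensions, the pooled
#' covariance is shrunk toward a scaled identity to keep it invertible.
#' Priors default to training-set proportions.
#'
#' @param train,validation data.frames with the `s01`..`s24` columns
#'   (e.g. from [stratified_split()]).
#' @param label_column metadata column holding the class labels.
#' @param prior `"proportional"` or `"uniform"`.
#' @param shrinkage shrinkage weight in [0,1], or `NULL` for automatic.
#' @return Object of class `classification_report`: list with
#'   `label_set`, `confusion` (counts, true labels in rows),
#'   `confusion_pct` (rows sum to 100), `accuracy` (fraction),
#'   `per_class_recall` and `predicted`.
#' @export
lda_classify <- function(train, validation, label_column = "class_label",
                         prior = c("proportional", "uniform"),
                         shrinkage = NULL) {
  prior <- match.arg(prior)
  y_tr <- as.character(train[[label_column]])
  y_va <- as.character(validation[[label_column]])
  labels <- sort(unique(y_tr))
  if (length(labels) < 2) stop("need at least 2 labels in training data")
  missing <- setdiff(unique(y_va), labels)
  if (length(missing))
    stop("label present in validation but absent in train: ",
         paste(missing, collapse = ", "))
  x_tr <- fingerprint_values(train)
  x_va <- fingerprint_values(validation)
  y_tr <- y_tr[if ("status" %in% names(train)) train$status == "ok" else TRUE]
  y_va <- y_va[if ("status" %in% names(validation))
    validation$status == "ok" else TRUE]

  S <- pooled_covariance(x_tr, y_tr, gamma = shrinkage)
  Sinv <- solve(S)
  pri <- if (prior == "uniform") stats::setNames(rep(1 / length(labels),
                                                     length(labels)), labels)
         else table(y_tr)[labels] / length(y_tr)
  scores <- vapply(labels, function(g) {
    mu <- colMeans(x_tr[y_tr == g, , drop = FALSE])
    drop(x_va %*% Sinv %*% mu) - 0.5 * drop(mu %*% Sinv %*% mu) +
      log(pri[[g]])
  }, numeric(nrow(x_va)))
  predicted <- labels[max.col(scores, ties.method = "first")]

  confusion <- table(factor(y_va, labels), factor(predicted, labels))
  names(dimnames(confusion)) <- c("true", "predicted")
  accuracy <- sum(diag(confusion)) / sum(confusion)
  recall <- diag(confusion) / pmax(rowSums(confusion), 1)
  pct <- sweep(confusion, 1, pmax(rowSums(confusion), 1), "/") * 100
  structure(list(label_set = labels, confusion = confusion,
                 confusion_pct = pct, accuracy = accuracy,
                 per_class_recall = recall, predicted = predicted),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> %d labels, validation accuracy %.1f%%\n",
              length(x$label_set), 100 * x$accuracy))
  print(x$confusion)
  invisible(x)
}

#' Two-way hierarchical clustering of fingerprints and sensors
#'
#' Agglomerative clustering (Euclidean distance, Ward linkage) of both
#' the rows (sample measurements) and the columns (sensor chemistries)
#' of a centred fingerprint matrix — the structure behind clustered
#' heat-map figures. Leaf order is made deterministic by reordering
#' each dendrogram against the data means.
#'
#' @param fm a `centered_matrix` (or any fingerprint matrix).
#' @param linkage linkage method passed to [stats::hclust()].
#' @return List with `row_tree`, `col_tree` (hclust objects) and
#'   `ordered` (the matrix re-ordered by both dendrograms).
#' @export
two_way_hca <- function(fm, linkage = "ward.D2") {
  vals <- fingerprint_values(fm)
  if (nrow(vals) < 3) stop("HCA needs at least 3 rows")
  row_tree <- stats::hclust(stats::dist(vals), method = linkage)
  row_tree <- stats::as.hclust(stats::reorder(stats::as.dendrogram(row_tree),
                                              rowMeans(vals)))
  col_tree <- stats::hclust(stats::dist(t(vals)), method = linkage)
  col_tree <- stats::as.hclust(stats::reorder(stats::as.dendrogram(col_tree),
                                              colMeans(vals)))
  list(row_tree = row_tree, col_tree = col_tree,
       ordered = vals[row_tree$order, col_tree$order, drop = FALSE])
}

#' Majority-class purity of a dendrogram cut
#'
#' Cuts the sample tree at `k` clusters and reports the fraction of
#' rows whose cluster's majority class matches their own label.
#'
#' @param row_tree an `hclust` over fingerprint rows.
#' @param labels class label per row (pre-cut order).
#' @param k number of clusters.
#' @return Purity fraction in [0, 1].
#' @export
cut_purity <- function(row_tree, labels, k) {
  cl <- stats::cutree(row_tree, k = k)
  correct <- 0L
  for (g in unique(cl)) {
    lab <- labels[cl == g]
    correct <- correct + max(table(lab))
  }
  correct / length(labels)
}
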