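#' Project spike snippets onto their first three principal components
#'
#' Snippets are mean-centered and projected onto the top three eigenvectors
#' of the snippet covariance (computed through the SVD, `stats::prcomp`).
#' Each component's sign is fixed so that its largest-magnitude loading is
#' positive, making the projection reproducible across runs.
#'
#' @param snippets a `snippet_set` or a numeric matrix
#'   (n_snippets x n_samples) of raw, volt-scale snippets.
#' @return numeric matrix n_snippets x 3 of projection scores, with the
#'   rotation in attribute `"rotation"`.
#' @export
project_pca <- function(snippets) {
  m <- if (inherits(snippets, "snippet_set")) snippets$snippets
       else as.matrix(snippets)
  if (nrow(m) < 4)
    stop("insufficient data: need at least 4 snippets for PCA")
  p <- stats::prcomp(m, center = TRUE, scale. = FALSE, rank. = 3)
  rot <- p$rotation
  for (j in seq_len(ncol(rot))) {
    k <- which.max(abs(rot[, j]))
    if (rot[k, j] < 0) {
      rot[, j] <- -rot[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  scores <- p$x[, 1:3, drop = FALSE]
  colnames(scores) <- paste0("PC", 1:3)
  attr(scores, "rotation") <- rot
  attr(scores, "sdev") <- p$sdev
  scores
}

#' Cluster snippet features with a Gaussian-mixture model
#'
#' Fits Gaussian mixtures by EM for 1 to `max_clusters` components and
#' selects the model by BIC (`mclust`). Snippets whose maximum posterior
#' responsibility falls below `min_responsibility` are left unassigned
#' (label -1) and later count as non-members for isolation distance.
#' The fit is deterministic (hierarchical-agglomeration initialization);
#' `seed` is accepted for interface stability.
#'
#' @param features n x 3 projection scores from [project_pca()].
#' @param max_clusters largest number of mixture components considered.
#' @param seed optional RNG seed.
#' @param min_responsibility posterior needed to assign a snippet.
#' @return integer vector of cluster labels (1-based; -1 = unassigned),
#'   with the selected number of components in attribute `"G"`.
#' @importFrom mclust Mclust mclustBIC
#' @export
cluster_features <- function(features, max_clusters = 8, seed = NULL,
                             min_responsibility = 0.5) {
  features <- as.matrix(features)
  fit <- with_seed(seed,
    mclust::Mclust(features, G = seq_len(max_clusters), verbose = FALSE))
  if (is.null(fit)) stop("clustering error: EM failed for all k")
  labels <- as.integer(fit$classification)
  zmax <- apply(fit$z, 1, max)
  labels[zmax < min_responsibility] <- -1L
  attr(labels, "G") <- fit$G
  attr(labels, "model") <- fit$modelName
  labels
}

#' Isolation distance of one cluster
#'
#' Cluster-quality metric: with n the cluster size, the squared Mahalanobis
#' distance — under the cluster's own mean and covariance — of the n-th
#' closest non-member point. Large values mean the cluster is well
#' separated from everything else; the conventional single-unit criterion
#' is a value above 20. Undefined (NA) when there are fewer non-members
#' than members.
#'
#' @param features n x d feature matrix.
#' @param labels per-point cluster labels (-1 = unassigned; unassigned
#'   points count as non-members).
#' @param cluster_id the cluster to score.
#' @return squared Mahalanobis distance (non-negative), or `NA` when
#'   undefined.
#' @export
isolation_distance <- function(features, labels, cluster_id) {
  features <- as.matrix(features)
  inside <- labels == cluster_id
  n <- sum(inside)
  if (n < 4) stop("insufficient data: cluster has fewer than 4 members")
  if (sum(!inside) < n) return(NA_real_)
  mu <- colMeans(features[inside, , drop = FALSE])
  sigma <- stats::cov(features[inside, , drop = FALSE])
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-12 * max(abs(ev))) {
    warning("singular cluster covariance; regularizing the diagonal")
    sigma <- sigma + diag(1e-9 * sum(diag(sigma)) / ncol(sigma),
                          ncol(sigma))
  }
  d2 <- stats::mahalanobis(features[!inside, , drop = FALSE], mu, sigma)
  sort(d2, partial = n)[n]
}

#' Sort a snippet set into putative single units
#'
#' The standard chain: PCA projection to three components, Gaussian-mixture
#' clustering, isolation distance per cluster, and acceptance of clusters
#' exceeding the quality threshold.
#'
#' @param snippets a `snippet_set`.
#' @param max_clusters maximum mixture components.
#' @param seed optional RNG seed.
#' @param threshold isolation-distance acceptance threshold (strict).
#' @return object of class `cluster_result`: list with `labels`,
#'   `features`, `isolation_distance` (named numeric, NA = undefined),
#'   `accepted` (integer ids), `times_ms`.
#' @export
sort_snippets <- function(snippets, max_clusters = 8, seed = NULL,
                          threshold = 20) {
  features <- project_pca(snippets)
  labels <- cluster_features(features, max_clusters, seed)
  ids <- sort(unique(labels[labels > 0]))
  iso <- vapply(ids, function(cid) {
    if (sum(labels == cid) < 4) return(NA_real_)
    isolation_distance(features, labels, cid)
  }, numeric(1))
  names(iso) <- ids
  res <- structure(list(labels = labels, features = features,
                        isolation_distance = iso, accepted = integer(0),
                        times_ms = if (inherits(snippets, "snippet_set"))
                          snippets$times_ms else NULL),
                   class = "cluster_result")
  res$accepted <- accept_units(res, threshold)
  res
}

#' Accept single-unit clusters by isolation distance
#'
#' Strict criterion: a cluster is accepted only if its isolation distance
#' is defined and greater than the threshold (20 by convention); clusters
#' with undefined distance are rejected.
#'
#' @param result a `cluster_result` (or any list with an
#'   `isolation_distance` named vector).
#' @param threshold acceptance threshold.
#' @return integer vector of accepted cluster ids.
#' @export
accept_units <- function(result, threshold = 20) {
  iso <- result$isolation_distance
  if (!length(iso)) return(integer(0))
  as.integer(names(iso)[!is.na(iso) & iso > threshold])
}

#' @export
print.cluster_result <- function(x, ...) {
  ids <- names(x$isolation_distance)
  cat(sprintf("cluster_result: %d snippets, %d cluster(s), %d unassigned\n",
              length(x$labels), length(ids), sum(x$labels == -1L)))
  for (id in ids)
    cat(sprintf("  cluster %s: n=%d, isolation distance %s%s\n", id,
                sum(x$labels == as.integer(id)),
                ifelse(is.na(x$isolation_distance[[id]]), "undefined",
                       sprintf("%.1f", x$isolation_distance[[id]])),
                ifelse(as.integer(id) %in% x$accepted, " [accepted]", "")))
  invisible(x)
}
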