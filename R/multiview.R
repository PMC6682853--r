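#' Multi-view late-integration clustering
#'
#' The four stages mirror the late-integration multi-view workflow: (1)
#' within each view, features are clustered hierarchically (Ward linkage on a
#' correlation-based dissimilarity); (2) each feature cluster is reduced to
#' its correlation medoid ("centroid feature"); (3) patients are clustered
#' per view (Ward on Euclidean distance over the standardized centroid
#' features); (4) the per-view patient partitions are integrated into the
#' final clusters by clustering the stacked binary membership encoding.
#'
#' @name multiview
NULL

# Average silhouette width for labels under a dissimilarity; the internal
# index used to pick k. Returns -Inf for degenerate labelings.
avg_silhouette <- function(labels, d) {
  if (length(unique(labels)) < 2) return(-Inf)
  mean(cluster::silhouette(as.integer(labels), d)[, "sil_width"])
}

# Cut a Ward tree at each candidate k and keep the silhouette-best cut.
best_cut <- function(hc, d, k_candidates) {
  sil <- vapply(k_candidates, function(k)
    avg_silhouette(stats::cutree(hc, k = k), d), numeric(1))
  k <- k_candidates[which.max(sil)]  # ties -> smallest k
  list(labels = stats::cutree(hc, k = k), k = k, silhouette = max(sil))
}

#' Cluster the features of one view
#'
#' Features are points in patient space; their dissimilarity is
#' `1 - |Pearson r|`, so strongly correlated features (either sign) are close.
#' Agglomeration uses Ward linkage; the number of clusters is chosen by
#' average silhouette width over `k_candidates`.
#'
#' @param view patients x features matrix (standardized columns).
#' @param k_candidates integer candidates for the number of feature clusters
#'   (default 2:10, truncated to at most `ncol(view) - 1`).
#' @return list: `labels` (named by feature), `k`, `silhouette`, `hc`.
#' @export
cluster_features <- function(view, k_candidates = 2:10) {
  p <- ncol(view)
  if (p < 2) stop("need at least 2 features to cluster")
  if (min(k_candidates) > p)
    stop("k_candidates exceed the number of features (", p, ")")
  k_candidates <- k_candidates[k_candidates <= p]
  d <- stats::as.dist(1 - abs(stats::cor(view)))
  hc <- stats::hclust(d, method = "ward.D2")
  if (identical(k_candidates, p) || (length(k_candidates) == 1 && k_candidates == p)) {
    labels <- stats::setNames(seq_len(p), colnames(view))
    return(list(labels = labels, k = p, silhouette = NA_real_, hc = hc))
  }
  res <- best_cut(hc, d, k_candidates[k_candidates < p])
  names(res$labels) <- colnames(view)
  c(res, list(hc = hc))
}

#' Select the centroid (correlation-medoid) feature of each feature cluster
#'
#' Within each feature cluster the centroid is the member maximizing the mean
#' absolute Pearson correlation with the other members; singletons represent
#' themselves. Ties are broken by column order.
#'
#' @param view patients x features matrix.
#' @param feature_clusters named integer vector (from [cluster_features()]).
#' @return list: `centroids` (character), `membership` (list of feature names
#'   per cluster).
#' @export
select_centroids <- function(view, feature_clusters) {
  stopifnot(all(names(feature_clusters) %in% colnames(view)))
  membership <- split(names(feature_clusters), feature_clusters)
  centroids <- vapply(membership, function(members) {
    if (length(members) == 1) return(members)
    r <- abs(stats::cor(view[, members, drop = FALSE]))
    score <- (rowSums(r) - 1) / (length(members) - 1)  # mean |r| with others
    members[which.max(score)]                          # ties -> first column
  }, character(1))
  # report in stable column order
  ord <- order(match(centroids, colnames(view)))
  list(centroids = unname(centroids[ord]), membership = membership[ord])
}

#' Cluster patients within one view using its centroid features
#'
#' Ward hierarchical clustering on Euclidean distance over the standardized
#' centroid features; k chosen by average silhouette width.
#'
#' @param view_centroids patients x centroid-features matrix (standardized).
#' @param k_candidates candidate cluster numbers (default 2:10, truncated to
#'   `nrow - 1`).
#' @return list: `labels` (named by patient), `k`, `silhouette`.
#' @export
cluster_patients_view <- function(view_centroids, k_candidates = 2:10) {
  n <- nrow(view_centroids)
  if (n < 2) stop("need at least 2 patients")
  if (ncol(view_centroids) < 1) stop("need at least 1 centroid feature")
  d <- stats::dist(view_centroids)
  if (max(d) < .Machine$double.eps^0.5) {
    warning("all patients identical in this view; single cluster returned")
    return(list(labels = stats::setNames(rep(1L, n), rownames(view_centroids)),
                k = 1L, silhouette = NA_real_))
  }
  hc <- stats::hclust(d, method = "ward.D2")
  kc <- k_candidates[k_candidates < n]
  if (length(kc) == 0) {
    # tiny subsets (e.g. LOOCV at n = 3): no admissible k below n; finest cut
    k <- min(n, min(k_candidates))
    return(list(labels = stats::setNames(stats::cutree(hc, k = k),
                                         rownames(view_centroids)),
                k = k, silhouette = NA_real_))
  }
  res <- best_cut(hc, d, kc)
  names(res$labels) <- rownames(view_centroids)
  res
}

# One-hot membership encoding: patients x k binary matrix. Label-free in the
# sense that permuting cluster ids only permutes columns, which Euclidean
# distances (and hence the integration) are invariant to.
membership_matrix <- function(labels) {
  lev <- sort(unique(labels))
  m <- outer(labels, lev, `==`) * 1
  rownames(m) <- names(labels)
  m
}

# Relabel clusters as 1..k by decreasing size (ties: first-appearing patient).
relabel_by_size <- function(labels) {
  tab <- table(labels)
  first <- vapply(names(tab), function(l) min(which(labels == l)), numeric(1))
  ord <- names(tab)[order(-tab, first)]
  out <- match(as.character(labels), ord)
  stats::setNames(as.integer(out), names(labels))
}

#' Integrate per-view patient partitions into the final clustering
#'
#' Each view's labels are encoded as a binary membership matrix; the matrices
#' are stacked column-wise and the patients re-clustered into `final_k`
#' groups. Default strategy: Ward on the stacked encoding. Alternative:
#' spectral partitioning of the patient co-association matrix (fraction of
#' views in which two patients share a cluster). Final labels are renumbered
#' by decreasing cluster size.
#'
#' @param per_view_labels list of per-view label vectors, all named by the
#'   same patients.
#' @param final_k number of final clusters (default 2).
#' @param method `"ward"` (default) or `"spectral"`.
#' @return list: `final_labels` (named integer), `per_view_labels`,
#'   `per_view_k`, `method`.
#' @export
integrate_views <- function(per_view_labels, final_k = 2L,
                            method = c("ward", "spectral")) {
  method <- match.arg(method)
  ids <- names(per_view_labels[[1]])
  for (l in per_view_labels)
    if (!setequal(names(l), ids))
      stop("views label different patient sets; cannot integrate")
  per_view_labels <- lapply(per_view_labels, function(l) l[ids])
  stacked <- do.call(cbind, lapply(per_view_labels, membership_matrix))
  if (final_k >= length(ids)) {
    final <- stats::setNames(seq_along(ids), ids)
  } else if (method == "ward") {
    hc <- stats::hclust(stats::dist(stacked), method = "ward.D2")
    final <- stats::cutree(hc, k = final_k)
  } else {
    # co-association: mean over views of "same cluster" indicators
    A <- Reduce(`+`, lapply(per_view_labels, function(l)
      outer(l, l, `==`) * 1)) / length(per_view_labels)
    dvec <- rowSums(A)
    L <- diag(1 / sqrt(dvec)) %*% A %*% diag(1 / sqrt(dvec))
    ev <- eigen(L, symmetric = TRUE)
    U <- ev$vectors[, seq_len(final_k), drop = FALSE]
    U <- U / pmax(sqrt(rowSums(U^2)), 1e-12)
    km <- stats::kmeans(U, centers = final_k, nstart = 20)
    final <- stats::setNames(km$cluster, ids)
  }
  final <- relabel_by_size(stats::setNames(as.integer(final), ids))
  list(final_labels = final,
       per_view_labels = per_view_labels,
       per_view_k = vapply(per_view_labels, function(l) length(unique(l)), integer(1)),
       method = method)
}

#' Run the full multi-view clustering on a feature table
#'
#' Convenience wrapper: split views, cluster features, select centroids,
#' cluster patients per view, integrate. Standardization happens inside
#' [split_views()], so rerunning on a patient subset (as LOOCV does) refits
#' the scaling on that subset only.
#'
#' @param ft a [build_feature_table()] result.
#' @param feature_k_candidates,patient_k_candidates candidate k ranges.
#' @param final_k number of final patient clusters (default 2).
#' @param method integration strategy, see [integrate_views()].
#' @return object of class `multiview_clustering`: the [integrate_views()] result
#'   plus `centroid_sets` (per view) and `feature_clusters`.
#' @export
multiview_cluster <- function(ft, feature_k_candidates = 2:10,
                         patient_k_candidates = 2:10, final_k = 2L,
                         method = c("ward", "spectral")) {
  method <- match.arg(method)
  views <- split_views(ft)
  feature_clusters <- list(); centroid_sets <- list(); per_view_labels <- list()
  for (v in names(views)) {
    fc <- cluster_features(views[[v]], feature_k_candidates)
    cs <- select_centroids(views[[v]], fc$labels)
    pv <- cluster_patients_view(views[[v]][, cs$centroids, drop = FALSE],
                                patient_k_candidates)
    feature_clusters[[v]] <- fc
    centroid_sets[[v]] <- cs
    per_view_labels[[v]] <- pv$labels
  }
  res <- integrate_views(per_view_labels, final_k = final_k, method = method)
  res$centroid_sets <- centroid_sets
  res$feature_clusters <- feature_clusters
  class(res) <- "multiview_clustering"
  res
}

#' @export
print.multiview_clustering <- function(x, ...) {
  cat(sprintf("multiview_clustering: %d patients -> %d final clusters (%s)\n",
              length(x$final_labels), length(unique(x$final_labels)), x$method))
  cat("  per-view k:", paste(x$per_view_k, collapse = ", "), "\n")
  cat("  final sizes:", paste(table(x$final_labels), collapse = "/"), "\n")
  invisible(x)
}
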