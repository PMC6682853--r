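#' Leave-one-out repetitions of the full multi-view clustering
#'
#' Repetition r removes patient r from the feature table and reruns the whole
#' pipeline — view standardization, feature clustering, centroid selection,
#' per-view patient clustering, integration — from scratch on the remaining
#' patients. Nothing is carried over between repetitions, so there is no
#' leakage of the left-out patient into scaling or selection.
#'
#' @param ft a [build_feature_table()] result with n >= 3 patients.
#' @param ... arguments forwarded to [multiview_cluster()].
#' @return list of length n; element r holds `left_out` (patient id) and
#'   `labels` (final labels over the other n-1 patients), or `error` if that
#'   repetition failed.
#' @export
loocv_clusterings <- function(ft, ...) {
  n <- nrow(ft)
  if (n < 3) stop("LOOCV needs at least 3 patients")
  layout <- attr(ft, "layout")
  lapply(seq_len(n), function(r) {
    sub <- unclass(ft)[-r, , drop = FALSE]
    sub <- structure(sub, layout = layout, class = "feature_table")
    res <- try(multiview_cluster(sub, ...), silent = TRUE)
    if (inherits(res, "try-error"))
      list(left_out = rownames(ft)[r], labels = NULL,
           error = attr(res, "condition")$message)
    else
      list(left_out = rownames(ft)[r], labels = res$final_labels)
  })
}

#' Consensus co-occurrence matrix from resampled partitions
#'
#' `M[i, j]` is the fraction of repetitions containing both patients i and j
#' in which they were assigned to the same cluster; the diagonal is 1. For
#' leave-one-out partitions every off-diagonal pair is co-present in exactly
#' n - 2 repetitions.
#'
#' @param partitions list as returned by [loocv_clusterings()] (elements with
#'   `labels = NULL` are skipped).
#' @param patient_ids character vector of all patient ids.
#' @return n x n symmetric matrix with unit diagonal, entries in \[0, 1\].
#' @export
consensus_matrix <- function(partitions, patient_ids) {
  n <- length(patient_ids)
  co <- present <- matrix(0, n, n, dimnames = list(patient_ids, patient_ids))
  for (p in partitions) {
    if (is.null(p$labels)) next
    ids <- names(p$labels)
    idx <- match(ids, patient_ids)
    if (anyNA(idx)) stop("partition labels patients outside patient_ids")
    present[idx, idx] <- present[idx, idx] + 1
    same <- outer(p$labels, p$labels, `==`) * 1
    co[idx, idx] <- co[idx, idx] + same
  }
  if (any(present[upper.tri(present)] == 0))
    stop("some patient pair is never co-present; consensus undefined")
  M <- co / present
  diag(M) <- 1
  M
}

#' Per-cluster mean consensus
#'
#' Mean of the off-diagonal consensus entries over within-cluster pairs, for
#' each final cluster. Singleton clusters have no within-cluster pair and
#' report NA.
#'
#' @param M consensus matrix from [consensus_matrix()].
#' @param final_labels named integer vector of final cluster assignments.
#' @return named numeric vector, one mean per cluster.
#' @export
cluster_consensus_means <- function(M, final_labels) {
  ids <- names(final_labels)
  stopifnot(all(ids %in% rownames(M)))
  vapply(split(ids, final_labels), function(members) {
    if (length(members) < 2) return(NA_real_)
    sub <- M[members, members]
    mean(sub[upper.tri(sub)])
  }, numeric(1))
}
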