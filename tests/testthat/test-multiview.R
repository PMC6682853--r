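# Builds a patients x features view with planted correlated feature groups:
# each group is one latent factor plus small independent noise.
planted_feature_view <- function(n = 60, groups = 5, per_group = 4,
                                 noise = 0.05, seed = 1) {
  set.seed(seed)
  cols <- list()
  for (g in seq_len(groups)) {
    f <- rnorm(n)
    for (j in seq_len(per_group))
      cols[[length(cols) + 1L]] <- f + rnorm(n, 0, noise)
  }
  x <- do.call(cbind, cols)
  colnames(x) <- sprintf("G%d_f%d", rep(seq_len(groups), each = per_group),
                         rep(seq_len(per_group), groups))
  rownames(x) <- sprintf("P%02d", seq_len(n))
  list(x = scale(x), truth = rep(seq_len(groups), each = per_group))
}

test_that("feature clustering recovers planted correlated groups", {
  pv <- planted_feature_view(noise = sqrt(1 / 0.95^2 - 1))  # within-r ~ 0.95
  fc <- cluster_features(pv$x)
  expect_identical(fc$k, 5L)
  expect_equal(adjusted_rand_index(fc$labels, pv$truth), 1)

  # two perfectly correlated blocks
  set.seed(2)
  f1 <- rnorm(40); f2 <- rnorm(40)
  x <- cbind(a1 = f1, a2 = 2 * f1 + 3, a3 = -f1, b1 = f2, b2 = f2 * 0.5)
  fc2 <- cluster_features(scale(x), k_candidates = 2:4)
  expect_identical(fc2$k, 2L)
  expect_equal(adjusted_rand_index(fc2$labels, c(1, 1, 1, 2, 2)), 1)

  expect_error(cluster_features(scale(x), k_candidates = 6:8), "exceed")

  # orthogonal features, k forced to n_features -> singletons
  set.seed(3)
  xo <- matrix(rnorm(200 * 6), 200, 6, dimnames = list(NULL, letters[1:6]))
  fo <- cluster_features(scale(xo), k_candidates = 6)
  expect_identical(sort(unname(fo$labels)), 1:6)
})

test_that("centroid selection picks the correlation medoid", {
  pv <- planted_feature_view(groups = 3, per_group = 5, noise = 0.3, seed = 4)
  fc <- cluster_features(pv$x, k_candidates = 3)
  cs <- select_centroids(pv$x, fc$labels)
  expect_length(cs$centroids, 3)
  # [DERIVED] brute-force mean-|r| over members of each cluster
  for (cl in unique(fc$labels)) {
    members <- names(fc$labels)[fc$labels == cl]
    r <- abs(cor(pv$x[, members, drop = FALSE]))
    score <- (rowSums(r) - 1) / (length(members) - 1)
    best <- members[which.max(score)]
    expect_true(best %in% cs$centroids)
  }

  # singleton cluster represents itself
  cs1 <- select_centroids(pv$x, setNames(1L, "G1_f2"))
  expect_identical(cs1$centroids, "G1_f2")

  # exact tie in a two-member cluster -> first by column order
  set.seed(5); f <- rnorm(30)
  x <- scale(cbind(u = f + rnorm(30, 0, .2), v = f + rnorm(30, 0, .2)))
  cs2 <- select_centroids(x, setNames(c(1L, 1L), c("u", "v")))
  expect_identical(cs2$centroids, "u")
})

test_that("per-view patient clustering separates planted patient groups", {
  set.seed(6)
  n_per <- 25
  x <- rbind(matrix(rnorm(n_per * 3, 0), n_per, 3),
             matrix(rnorm(n_per * 3, 6), n_per, 3))
  rownames(x) <- sprintf("P%02d", 1:(2 * n_per))
  pc <- cluster_patients_view(scale(x))
  expect_identical(pc$k, 2L)
  expect_equal(adjusted_rand_index(pc$labels, rep(1:2, each = n_per)), 1)

  # duplicated patients always co-assigned
  xd <- rbind(x, x[1:5, ] + 0)
  rownames(xd) <- sprintf("Q%02d", seq_len(nrow(xd)))
  pd <- cluster_patients_view(scale(xd), k_candidates = 2:6)
  expect_identical(unname(pd$labels[51:55]), unname(pd$labels[1:5]))

  expect_warning(cluster_patients_view(matrix(1, 5, 2,
                                              dimnames = list(letters[1:5], NULL))),
                 "identical")
})

test_that("planted 3-cluster views are recovered across seeds (sep 4 sd)", {
  aris <- vapply(1:20, function(s) {
    set.seed(s)
    centers <- c(0, 4, 8)
    x <- do.call(rbind, lapply(centers, function(m)
      matrix(rnorm(20 * 4, m), 20, 4)))
    rownames(x) <- sprintf("P%02d", seq_len(nrow(x)))
    pc <- cluster_patients_view(scale(x))
    adjusted_rand_index(pc$labels, rep(1:3, each = 20))
  }, numeric(1))
  expect_gte(mean(aris), 0.9)
})

test_that("late integration: unanimity, majority, degenerate final_k", {
  ids <- sprintf("P%02d", 1:30)
  split2 <- setNames(rep(1:2, each = 15), ids)
  views <- list(a = split2, b = split2, c = split2, d = split2)
  fin <- integrate_views(views)
  expect_equal(adjusted_rand_index(fin$final_labels, split2), 1)

  # [DERIVED] three agreeing views + one random: majority wins (50 seeds)
  agree <- vapply(1:50, function(s) {
    set.seed(s)
    noisy <- setNames(sample(1:3, 30, replace = TRUE), ids)
    f <- integrate_views(list(a = split2, b = split2, c = split2, d = noisy))
    adjusted_rand_index(f$final_labels, split2) == 1
  }, logical(1))
  expect_gte(mean(agree), 0.95)

  # final_k = n -> every patient its own cluster
  fin_n <- integrate_views(views, final_k = 30)
  expect_identical(sort(unname(fin_n$final_labels)), 1:30)

  expect_error(integrate_views(list(a = split2, b = split2[-1])), "different")
})

test_that("integration is invariant to per-view label permutation", {
  ids <- sprintf("P%02d", 1:24)
  set.seed(8)
  views <- lapply(1:4, function(v) setNames(sample(1:3, 24, TRUE), ids))
  names(views) <- letters[1:4]
  permuted <- lapply(views, function(l) setNames(c(3L, 1L, 2L)[l], names(l)))
  f1 <- integrate_views(views)
  f2 <- integrate_views(permuted)
  expect_identical(f1$final_labels, f2$final_labels)
})

test_that("patient order only permutes labels, not the partition", {
  cohort <- generate_cohort(cohort_config(n_patients = 20, seed = 9,
                                          grid_shape = c(14, 14, 8)))
  ft <- suppressWarnings(build_feature_table(cohort))
  cl1 <- suppressWarnings(multiview_cluster(ft))
  set.seed(1)
  perm <- sample(nrow(ft))
  ftp <- structure(unclass(ft)[perm, ], layout = attr(ft, "layout"),
                   class = "feature_table")
  cl2 <- suppressWarnings(multiview_cluster(ftp))
  ids <- rownames(ft)
  expect_equal(adjusted_rand_index(cl1$final_labels[ids],
                                   cl2$final_labels[ids]), 1)
})
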