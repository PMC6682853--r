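#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items,
#' used throughout the test-suite to score recovery of planted clusters.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return A number in \[-1, 1\]; 1 means identical partitions up to relabeling.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_i * sum_j / n2
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Column-standardize a matrix
#'
#' Centers and scales each column to mean 0, sd 1. Zero-variance columns are
#' set to 0 (centered but not scaled) with a warning, so downstream Euclidean
#' distances ignore them rather than propagating NaN.
#'
#' @param x numeric matrix.
#' @return matrix of the same shape.
#' @keywords internal
standardize_columns <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  zero <- sdv < .Machine$double.eps^0.5
  if (any(zero)) {
    warning(sprintf("%d zero-variance column(s) set to 0 after centering", sum(zero)))
    sdv[zero] <- 1
  }
  out <- sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
  out[, zero] <- 0
  out
}

# Deterministic per-patient child seed from one root seed; stable under changes
# of n_patients so patient i's maps do not change when the cohort grows.
child_seed <- function(root_seed, index) {
  as.integer((as.numeric(root_seed) * 48271 + as.numeric(index) * 7919) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
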