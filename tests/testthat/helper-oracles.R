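# Independent oracles used across the suite. These deliberately re-derive
# quantities from first principles (loops, closed forms, survdiff) and never
# call the package functions they are checking.

# Linear-interpolation quantile between order statistics (type-7 convention),
# written out by hand from sorted values.
oracle_quantile <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

# Population central moments by explicit summation.
oracle_moments <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  list(mean = mu, sd = sqrt(sum((x - mu)^2) / (n - 1)),
       skewness = m3 / m2^1.5, kurtosis = m4 / m2^2 - 3)
}

# Histogram mode by an explicit per-value bin loop (ties -> lowest bin).
oracle_mode <- function(x, n_bins = 100L) {
  lo <- min(x); hi <- max(x)
  w <- (hi - lo) / n_bins
  counts <- integer(n_bins)
  for (v in x) {
    b <- floor((v - lo) / w) + 1
    if (b > n_bins) b <- n_bins
    counts[b] <- counts[b] + 1
  }
  k <- which(counts == max(counts))[1]
  lo + (k - 0.5) * w
}

# Textbook log-rank: O-E and hypergeometric variance accumulated over the
# distinct event times, for a two-group comparison.
oracle_logrank <- function(in_group, time, event) {
  O <- E <- V <- 0
  for (t in sort(unique(time[event]))) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & in_group)
    d <- sum(event & time == t)
    d1 <- sum(event & time == t & in_group)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  list(z = (O - E) / sqrt(V), chisq = (O - E)^2 / V)
}

# Cox partial log-likelihood for one binary covariate, no ties; maximized by
# golden-section search (the grid/brute-force oracle for cox_ph_fit).
oracle_cox_binary <- function(x, time, event) {
  pll <- function(beta) {
    s <- 0
    for (i in which(event)) {
      risk <- time >= time[i]
      s <- s + beta * x[i] - log(sum(exp(beta * x[risk])))
    }
    s
  }
  stats::optimize(pll, c(-10, 10), maximum = TRUE, tol = 1e-9)$maximum
}

# Benjamini-Hochberg step-up, written out directly.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running_min <- 1
  for (i in seq(n, 1)) {
    running_min <- min(running_min, p[o[i]] * n / i)
    adj[o[i]] <- running_min
  }
  adj
}

# Small deterministic "cohort" built directly in code (no generator) for
# feature-table plumbing tests.
tiny_cohort <- function(n_patients = 3, grid = c(10, 10, 6), seed = 99) {
  set.seed(seed)
  patients <- lapply(seq_len(n_patients), function(i) {
    ce <- array(FALSE, grid); ce[3:5, 3:5, 2:4] <- TRUE
    flair <- array(FALSE, grid); flair[2:7, 2:7, 2:5] <- TRUE
    nawm <- array(FALSE, grid); nawm[8:10, 8:10, 1:3] <- TRUE
    maps <- setNames(lapply(1:5, function(m)
      array(rlnorm(prod(grid), 0.2 * i, 0.3), grid)),
      c("p", "q", "rCBV", "MTT", "rCBF"))
    list(id = sprintf("T%02d", i), true_cluster = 1L + (i %% 2L), maps = maps,
         masks = list(ce = ce, flair = flair, ne = flair & !ce, nawm = nawm))
  })
  structure(list(patients = patients, config = NULL), class = "synthetic_cohort")
}

expect_silent_warnless <- function(expr) suppressWarnings(suppressMessages(expr))
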