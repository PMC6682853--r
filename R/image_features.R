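#' Derive the non-enhancing tumor mask
#'
#' Boolean subtraction of the contrast-enhancing region from the
#' FLAIR-hyperintense region: a voxel is non-enhancing tumor iff it is
#' FLAIR-positive and not contrast-enhancing.
#'
#' @param flair,ce logical 3-D arrays on the same grid.
#' @return logical array, `flair & !ce`.
#' @export
derive_ne_mask <- function(flair, ce) {
  if (!identical(dim(flair), dim(ce)))
    stop("mask grids do not match: ", paste(dim(flair), collapse = "x"),
         " vs ", paste(dim(ce), collapse = "x"))
  flair & !ce
}

#' Normalize a parametric map to normal-appearing white matter
#'
#' Divides every voxel by the scalar mean of the map inside the NAWM mask,
#' turning arbitrary units into dimensionless ratios with NAWM ~ 1.
#'
#' @param map numeric 3-D array.
#' @param nawm logical mask on the same grid; must be non-empty with
#'   non-zero mean.
#' @return normalized array.
#' @export
normalize_map <- function(map, nawm) {
  if (!identical(dim(map), dim(nawm))) stop("map and NAWM mask grids differ")
  if (!any(nawm)) stop("NAWM mask is empty; cannot normalize")
  m <- mean(map[nawm])
  if (!is.finite(m) || m == 0) stop("NAWM mean is zero or non-finite")
  map / m
}

#' Dice similarity coefficient of two binary masks
#'
#' @param a,b logical arrays on the same grid; at least one non-empty.
#' @return `2|A n B| / (|A| + |B|)` in \[0, 1\].
#' @export
dice_coefficient <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask grids do not match")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) stop("both masks are empty; Dice undefined")
  2 * sum(a & b) / (na + nb)
}

histogram_stat_names <- function()
  c("Mean", "SD", "Median", "Mode", "Skewness", "Kurtosis",
    "Prc5", "Prc25", "Prc75", "Prc95")

#' Ten histogram statistics of a region's voxel values
#'
#' Mean, sample SD, median, histogram mode, skewness, excess kurtosis and the
#' 5th/25th/75th/95th percentiles of the raw voxel values. The mode is the
#' center of the most populated of `n_bins` equal-width bins spanning
#' \[min, max\] (ties broken toward the lowest bin); all other statistics are
#' computed on the raw values, not on binned counts. Percentiles use linear
#' interpolation between order statistics (`stats::quantile` type 7).
#' Skewness and kurtosis use population (biased) moment estimators; kurtosis
#' is excess kurtosis. A constant region gets SD 0 and skewness/kurtosis 0 by
#' convention, with a warning. Non-finite voxels are dropped (count messaged).
#'
#' @param values numeric vector of region voxel values (length >= 2 after
#'   removing non-finite entries).
#' @param n_bins number of histogram bins for the mode (default 100).
#' @return named numeric vector of the ten statistics.
#' @examples
#' compute_histogram_features(rlnorm(500))
#' @export
compute_histogram_features <- function(values, n_bins = 100L) {
  bad <- !is.finite(values)
  if (any(bad)) {
    message(sprintf("dropping %d non-finite voxel(s)", sum(bad)))
    values <- values[!bad]
  }
  if (length(values) < 2)
    stop("insufficient data: need >= 2 finite voxels, got ", length(values))
  n <- length(values)
  mu <- mean(values)
  sdv <- stats::sd(values)
  qs <- stats::quantile(values, c(0.05, 0.25, 0.5, 0.75, 0.95),
                        names = FALSE, type = 7)
  m2 <- mean((values - mu)^2)
  if (m2 < .Machine$double.eps) {
    warning("constant region: skewness and kurtosis set to 0")
    skew <- 0; kurt <- 0
    mode_c <- values[1]
  } else {
    skew <- mean((values - mu)^3) / m2^1.5
    kurt <- mean((values - mu)^4) / m2^2 - 3
    rng <- range(values)
    w <- (rng[2] - rng[1]) / n_bins
    bin <- pmin(floor((values - rng[1]) / w) + 1L, n_bins)
    counts <- tabulate(bin, nbins = n_bins)
    k <- which.max(counts)  # which.max takes the lowest bin on ties
    mode_c <- rng[1] + (k - 0.5) * w
  }
  c(Mean = mu, SD = sdv, Median = qs[3], Mode = mode_c, Skewness = skew,
    Kurtosis = kurt, Prc5 = qs[1], Prc25 = qs[2], Prc75 = qs[4], Prc95 = qs[5])
}

#' Canonical feature-column layout
#'
#' 100 features named `<Statistic>-<modality>-<region>` (e.g. `Mean-q-NE`),
#' ordered by view (CE-diffusion, NE-diffusion, CE-perfusion, NE-perfusion),
#' modality within view, then statistic.
#'
#' @return data.frame with columns `feature`, `statistic`, `modality`,
#'   `region`, `view`.
#' @export
feature_layout <- function() {
  rows <- list()
  for (v in view_names()) {
    region <- sub("-.*", "", v)
    mods <- if (grepl("diffusion", v)) diffusion_maps() else perfusion_maps()
    for (m in mods) for (s in histogram_stat_names())
      rows[[length(rows) + 1L]] <- data.frame(
        feature = paste(s, m, region, sep = "-"),
        statistic = s, modality = m, region = region, view = v)
  }
  do.call(rbind, rows)
}

#' Build the patients x 100 histogram feature table
#'
#' For each patient: every map is normalized to its NAWM mean, then the ten
#' histogram statistics are extracted from the CE and NE regions of each of
#' the five maps — 100 features, partitioned into the four views (20/20/30/30).
#'
#' @param cohort a `synthetic_cohort` (or any list with `patients`, each
#'   holding `maps`, `masks`, `id`).
#' @param n_bins histogram bins for the mode statistic.
#' @param on_failure what to do when a patient has an empty/degenerate region:
#'   `"error"` (default) aborts naming the patient, `"na"` keeps the patient
#'   with NA features for the failing region, `"drop"` removes the patient.
#' @return object of class `feature_table`: numeric matrix (patients x 100,
#'   rownames = patient ids) with attributes `layout` (see [feature_layout()])
#'   and `failed` (character vector of patients that failed, if any).
#' @export
build_feature_table <- function(cohort, n_bins = 100L,
                                on_failure = c("error", "na", "drop")) {
  on_failure <- match.arg(on_failure)
  layout <- feature_layout()
  pts <- cohort$patients
  out <- matrix(NA_real_, nrow = length(pts), ncol = nrow(layout),
                dimnames = list(vapply(pts, `[[`, "", "id"), layout$feature))
  failed <- character()
  for (i in seq_along(pts)) {
    p <- pts[[i]]
    missing_maps <- setdiff(map_names(), names(p$maps))
    if (length(missing_maps) > 0)
      stop(sprintf("patient %s: missing map(s) %s", p$id,
                   paste(missing_maps, collapse = ", ")))
    ne <- p$masks$ne %||% derive_ne_mask(p$masks$flair, p$masks$ce)
    res <- try({
      row <- stats::setNames(numeric(nrow(layout)), layout$feature)
      norm <- lapply(p$maps, normalize_map, nawm = p$masks$nawm)
      for (m in map_names()) {
        for (region in c("CE", "NE")) {
          mask <- if (region == "CE") p$masks$ce else ne
          feats <- compute_histogram_features(norm[[m]][mask], n_bins = n_bins)
          row[paste(names(feats), m, region, sep = "-")] <- feats
        }
      }
      row
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      if (on_failure == "error")
        stop(sprintf("feature extraction failed for patient %s: %s",
                     p$id, attr(res, "condition")$message))
      failed <- c(failed, p$id)
    } else {
      out[i, ] <- res
    }
  }
  if (on_failure == "drop" && length(failed) > 0)
    out <- out[!rownames(out) %in% failed, , drop = FALSE]
  structure(out, layout = layout, failed = failed, class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d patients x %d features (views: %s)\n",
              nrow(x), ncol(x),
              paste(table(attr(x, "layout")$view)[view_names()], collapse = "/")))
  invisible(x)
}

#' Split a feature table into its four standardized views
#'
#' @param ft a [build_feature_table()] result (rows with any NA are dropped
#'   with a warning — views must be complete for clustering).
#' @return named list of 4 matrices, each column-standardized (mean 0, sd 1).
#' @export
split_views <- function(ft) {
  layout <- attr(ft, "layout")
  x <- unclass(ft)
  keep <- stats::complete.cases(x)
  if (!all(keep)) {
    warning(sprintf("dropping %d patient(s) with missing features", sum(!keep)))
    x <- x[keep, , drop = FALSE]
  }
  out <- lapply(view_names(), function(v)
    standardize_columns(x[, layout$feature[layout$view == v], drop = FALSE]))
  names(out) <- view_names()
  out
}
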