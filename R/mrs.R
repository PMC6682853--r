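#' Tumor occupancy fraction of each CSI voxel
#'
#' Projects a high-resolution tumor mask onto the coarse CSI grid: for each
#' CSI voxel, the fraction of map-grid voxels inside its footprint that are
#' tumor-positive.
#'
#' @param tumor_mask logical 3-D array on the map grid.
#' @param grid a `csi_grid` (see [generate_csi_grid()]) whose `footprints`
#'   hold linear map-voxel indices per CSI voxel.
#' @return numeric vector of fractions, one per CSI voxel (column-major over
#'   the 8 x 8 grid).
#' @export
tumor_fraction_per_csi_voxel <- function(tumor_mask, grid) {
  vapply(grid$footprints, function(idx) {
    if (length(idx) == 0) stop("empty CSI footprint: fraction undefined")
    if (max(idx) > length(tumor_mask)) stop("footprint outside the map grid")
    mean(tumor_mask[idx])
  }, numeric(1))
}

#' Quality and occupancy filter for CSI voxels
#'
#' Retains, per metabolite, the CSI voxels whose tumor occupancy strictly
#' exceeds `occupancy_threshold` (a voxel at exactly 50% is excluded) and
#' whose quality SD does not exceed `sd_threshold` (a voxel at exactly 20% is
#' retained; the discard rule is SD strictly greater). Idempotent by
#' construction.
#'
#' @param grid a `csi_grid`.
#' @param fractions occupancy fractions from [tumor_fraction_per_csi_voxel()].
#' @param occupancy_threshold minimum tumor fraction, strict (default 0.5).
#' @param sd_threshold maximum quality SD percent, non-strict (default 20).
#' @return list of logical vectors `naa` and `cho` (length 64), TRUE where
#'   the voxel is retained for that metabolite.
#' @export
filter_csi_voxels <- function(grid, fractions, occupancy_threshold = 0.5,
                              sd_threshold = 20) {
  stopifnot(length(fractions) == length(grid$footprints))
  occ <- fractions > occupancy_threshold
  list(naa = occ & as.vector(grid$sd_naa) <= sd_threshold,
       cho = occ & as.vector(grid$sd_cho) <= sd_threshold)
}

#' Per-patient metabolite summaries over retained voxels
#'
#' Median NAA/Cr and Cho/Cr over the CSI voxels retained by
#' [filter_csi_voxels()] against the given tumor mask, per patient. Patients
#' with no retained voxel get NA (they drop out of the comparison, mirroring
#' the patients lost to the occupancy rule in practice).
#'
#' @param cohort a `synthetic_cohort` whose patients carry `csi` grids.
#' @param region `"ne"` (default) or `"ce"`: mask used for occupancy.
#' @param summary_fn summary over retained voxels (default [stats::median]).
#' @inheritParams filter_csi_voxels
#' @return data.frame: `id`, `naa_cr`, `cho_cr`, `n_voxels_naa`, `n_voxels_cho`.
#' @export
patient_metabolite_summary <- function(cohort, region = c("ne", "ce"),
                                       occupancy_threshold = 0.5,
                                       sd_threshold = 20,
                                       summary_fn = stats::median) {
  region <- match.arg(region)
  rows <- lapply(cohort$patients, function(p) {
    mask <- p$masks[[region]]
    fr <- tumor_fraction_per_csi_voxel(mask, p$csi)
    keep <- filter_csi_voxels(p$csi, fr, occupancy_threshold, sd_threshold)
    sm <- function(vals, k) if (any(k)) summary_fn(vals[k]) else NA_real_
    data.frame(id = p$id,
               naa_cr = sm(as.vector(p$csi$naa_cr), keep$naa),
               cho_cr = sm(as.vector(p$csi$cho_cr), keep$cho),
               n_voxels_naa = sum(keep$naa), n_voxels_cho = sum(keep$cho))
  })
  do.call(rbind, rows)
}

#' Compare metabolite levels between patient clusters
#'
#' Two-sided Wilcoxon rank-sum test per metabolite column, with
#' Benjamini-Hochberg adjustment across the whole family of comparisons.
#' Patients with NA summaries are dropped per metabolite; an all-tied
#' comparison reports p = 1 with a warning.
#'
#' @param summaries data.frame with `id` and one column per metabolite (e.g.
#'   from [patient_metabolite_summary()]).
#' @param cluster_labels named (by patient id) or aligned cluster vector with
#'   two levels.
#' @return data.frame: `metabolite`, `n1`, `n2`, `statistic`, `p`, `p_adj`.
#' @export
compare_metabolites <- function(summaries, cluster_labels) {
  if (!is.null(names(cluster_labels)))
    cluster_labels <- cluster_labels[summaries$id]
  cl <- factor(cluster_labels)
  if (nlevels(cl) != 2) stop("cluster_labels must have two levels")
  metabs <- setdiff(names(summaries),
                    c("id", grep("^n_voxels", names(summaries), value = TRUE)))
  rows <- lapply(metabs, function(m) {
    v <- summaries[[m]]
    ok <- !is.na(v)
    g1 <- v[ok & cl == levels(cl)[1]]; g2 <- v[ok & cl == levels(cl)[2]]
    if (length(g1) == 0 || length(g2) == 0)
      stop("both clusters must be represented for metabolite ", m)
    if (length(unique(c(g1, g2))) == 1) {
      warning("all values tied for ", m, "; p set to 1")
      w <- list(statistic = length(g1) * length(g2) / 2, p.value = 1)
    } else {
      w <- suppressWarnings(stats::wilcox.test(g1, g2, exact = FALSE))
    }
    data.frame(metabolite = m, n1 = length(g1), n2 = length(g2),
               statistic = unname(w$statistic), p = w$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}
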