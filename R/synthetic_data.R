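#' Configuration for a synthetic imaging cohort
#'
#' Defines the stochastic world the generator draws from: two latent imaging
#' phenotypes whose parametric-map distributions differ by view-specific
#' standardized effect sizes (concentrated in the non-enhancing views by
#' default), proportional-hazards survival with a favorable minority cluster,
#' independent right-censoring, Table-1-style covariate marginals, and a
#' coarse 8 x 8 CSI metabolite grid.
#'
#' Voxel intensities are log-normal per modality and region (positive,
#' right-skewed, as ratio images are). A patient's regional log-mean is the
#' modality-region baseline, plus half the cluster contrast (sign by cluster),
#' plus a patient-level random effect with sd `patient_sd`; the view effect
#' size is the cluster contrast expressed in units of `patient_sd`, i.e. the
#' standardized between-patient mean shift of the downstream features.
#'
#' @param n_patients cohort size (default 80).
#' @param cluster_proportions probabilities of clusters 1 and 2 (default
#'   `c(53, 27) / 80`); cluster counts are fixed deterministically as
#'   `round(n * p)` so the default cohort is exactly 53/27.
#' @param grid_shape integer 3-vector of voxel dimensions (default 24 x 24 x 12,
#'   a desk-scale stand-in for a clinical matrix).
#' @param effect_sizes named numeric: standardized between-cluster shift per
#'   view (`CE-diffusion`, `NE-diffusion`, `CE-perfusion`, `NE-perfusion`).
#' @param patient_sd sd of the patient-level log-mean random effect.
#' @param voxel_sdlog within-region log-sd of voxel intensities.
#' @param hr_cluster2 named numeric `c(os =, pfs =)`: hazard ratio of cluster 2
#'   (favorable) relative to cluster 1.
#' @param median_survival_cluster1 named numeric `c(os =, pfs =)` baseline
#'   median survival in days for cluster 1.
#' @param censoring_rate target probability that a record is censored.
#' @param ne_volume_factor linear scale applied to the FLAIR radius of
#'   cluster-2 patients (default 1.25, roughly doubling non-enhancing volume).
#' @param naa_shift_cluster2 additive shift on log NAA/Cr in tumor-dominant CSI
#'   voxels of cluster-2 patients (default -0.3: lower NAA/Cr, favorable).
#' @param seed root RNG seed; per-patient child seeds are derived from it.
#' @return an object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_patients = 80,
                          cluster_proportions = c(53, 27) / 80,
                          grid_shape = c(24L, 24L, 12L),
                          effect_sizes = c("CE-diffusion" = 1.5,
                                           "NE-diffusion" = 3.0,
                                           "CE-perfusion" = 1.5,
                                           "NE-perfusion" = 3.0),
                          patient_sd = 0.15,
                          voxel_sdlog = 0.3,
                          hr_cluster2 = c(os = 0.32, pfs = 0.33),
                          median_survival_cluster1 = c(os = 424, pfs = 248),
                          censoring_rate = 0.2,
                          ne_volume_factor = 1.25,
                          naa_shift_cluster2 = -0.3,
                          seed = 1L) {
  assert_that(n_patients >= 4, "n_patients must be >= 4")
  assert_that(length(cluster_proportions) == 2 && all(cluster_proportions > 0) &&
                abs(sum(cluster_proportions) - 1) < 1e-8,
              "cluster_proportions must be two positive numbers summing to 1")
  assert_that(length(grid_shape) == 3 && all(grid_shape[1:2] >= 8) &&
                grid_shape[3] >= 4,
              "grid_shape needs x and y >= 8 (CSI grid) and z >= 4")
  assert_that(all(is.finite(effect_sizes)) &&
                setequal(names(effect_sizes), view_names()),
              "effect_sizes must be finite and named by the four views")
  assert_that(all(hr_cluster2 > 0), "hazard ratios must be positive")
  assert_that(censoring_rate >= 0 && censoring_rate < 1,
              "censoring_rate must be in [0, 1)")
  structure(list(
    n_patients = as.integer(n_patients),
    cluster_proportions = cluster_proportions,
    map_names = map_names(),
    grid_shape = as.integer(grid_shape),
    effect_sizes = effect_sizes[view_names()],
    patient_sd = patient_sd,
    voxel_sdlog = voxel_sdlog,
    hr_cluster2 = hr_cluster2,
    median_survival_cluster1 = median_survival_cluster1,
    censoring_rate = censoring_rate,
    ne_volume_factor = ne_volume_factor,
    naa_shift_cluster2 = naa_shift_cluster2,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

map_names <- function() c("p", "q", "rCBV", "MTT", "rCBF")
diffusion_maps <- function() c("p", "q")
perfusion_maps <- function() c("rCBV", "MTT", "rCBF")
view_names <- function() c("CE-diffusion", "NE-diffusion", "CE-perfusion", "NE-perfusion")

view_of <- function(modality, region) {
  kind <- if (modality %in% diffusion_maps()) "diffusion" else "perfusion"
  paste0(region, "-", kind)
}

# Baseline log-means of the normalized (ratio-to-NAWM) intensity per
# modality and region; NAWM itself sits at log-mean 0 (ratio ~ 1).
baseline_meanlog <- function() {
  rbind(
    CE = c(p = 0.50, q = 0.20, rCBV = 0.80, MTT = 0.30, rCBF = 0.60),
    NE = c(p = 0.30, q = 0.10, rCBV = 0.20, MTT = 0.15, rCBF = 0.15)
  )
}

# Spherical mask on an integer grid.
sphere_mask <- function(grid_shape, center, radius) {
  g <- expand.grid(x = seq_len(grid_shape[1]), y = seq_len(grid_shape[2]),
                   z = seq_len(grid_shape[3]))
  d2 <- (g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2
  array(d2 <= radius^2, dim = grid_shape)
}

#' Generate masks, maps, covariates, survival and CSI for one patient
#'
#' Internal workhorse of [generate_cohort()]; exposed for tests.
#'
#' @param index patient index (drives the child seed).
#' @param true_cluster 1 or 2.
#' @param config a [cohort_config()].
#' @return a per-patient bundle (list).
#' @keywords internal
generate_patient <- function(index, true_cluster, config) {
  set.seed(child_seed(config$seed, index))
  g <- config$grid_shape

  # geometry: CE nucleus inside a FLAIR envelope; NAWM contralateral
  ce_center <- c(0.35, 0.5, 0.5) * g + stats::rnorm(3, 0, 0.4)
  r_ce <- max(2.2, 0.13 * min(g) * stats::rlnorm(1, 0, 0.12))
  r_flair <- r_ce + max(1.5, 0.10 * min(g) * stats::rlnorm(1, 0, 0.12))
  if (true_cluster == 2) r_flair <- r_flair * config$ne_volume_factor
  ce <- sphere_mask(g, ce_center, r_ce)
  flair <- sphere_mask(g, ce_center, r_flair)
  flair <- flair | ce                     # CE subset of FLAIR by construction
  nawm <- sphere_mask(g, c(0.82, 0.5, 0.5) * g, 0.10 * min(g) + 1.2) & !flair
  masks <- list(ce = ce, flair = flair, ne = flair & !ce, nawm = nawm)

  # cluster-conditional log-normal intensities; contrast rides on the
  # patient-level random effect scale so effect sizes are standardized
  base <- baseline_meanlog()
  sgn <- if (true_cluster == 1) +0.5 else -0.5
  maps <- list()
  for (m in map_names()) {
    vol <- array(NA_real_, dim = g)
    bg <- stats::rlnorm(prod(g), meanlog = -0.7, sdlog = 0.4)  # non-brain/other
    vol[] <- bg
    nawm_mean <- stats::rnorm(1, 0, 0.05)
    vol[masks$nawm] <- stats::rlnorm(sum(masks$nawm), nawm_mean, config$voxel_sdlog)
    for (region in c("CE", "NE")) {
      d <- config$effect_sizes[[view_of(m, region)]]
      mu <- base[region, m] + sgn * d * config$patient_sd +
        stats::rnorm(1, 0, config$patient_sd)
      rmask <- if (region == "CE") masks$ce else masks$ne
      vol[rmask] <- stats::rlnorm(sum(rmask), mu, config$voxel_sdlog)
    }
    maps[[m]] <- vol
  }

  covariates <- generate_covariates(config)
  survival <- generate_survival(true_cluster, config)
  survival$covariates <- covariates
  bundle <- list(id = sprintf("P%03d", index), true_cluster = true_cluster,
                 maps = maps, masks = masks, covariates = covariates,
                 survival = survival)
  bundle$csi <- generate_csi_grid(bundle, config)
  bundle
}

# Table-1 marginal frequencies, independent of cluster.
generate_covariates <- function(config) {
  list(
    age_group = sample(c("<60", ">=60"), 1, prob = c(35, 45) / 80),
    sex = sample(c("male", "female"), 1, prob = c(58, 22) / 80),
    resection = sample(c("complete", "partial", "biopsy"), 1,
                       prob = c(56, 22, 2) / 80),
    mgmt = sample(c("methylated", "unmethylated"), 1, prob = c(37, 41) / 78),
    idh1 = sample(c("mutant", "wildtype"), 1, prob = c(7, 73) / 80),
    ce_volume = max(1, stats::rnorm(1, 49.7, 28.1))
  )
}

#' Generate one censored survival record under proportional hazards
#'
#' Exponential event times with cluster-1 baseline medians and the configured
#' hazard ratio applied to cluster 2, for both OS and PFS. Censoring times are
#' independent exponentials whose rate is calibrated so that, averaged over the
#' cluster mix, the probability of censoring equals `censoring_rate`.
#'
#' @inheritParams generate_patient
#' @return list with `os_days`, `os_event`, `pfs_days`, `pfs_event`.
#' @export
generate_survival <- function(true_cluster, config) {
  assert_that(true_cluster %in% c(1, 2), "true_cluster must be 1 or 2")
  assert_that(all(config$hr_cluster2 > 0), "hazard ratios must be positive")
  one <- function(endpoint) {
    lam1 <- log(2) / config$median_survival_cluster1[[endpoint]]
    hr <- config$hr_cluster2[[endpoint]]
    lam <- lam1 * if (true_cluster == 2) hr else 1
    t_event <- stats::rexp(1, lam)
    cr <- config$censoring_rate
    if (cr > 0) {
      p1 <- config$cluster_proportions[1]
      lam_bar <- lam1 * (p1 + (1 - p1) * hr)
      mu <- lam_bar * cr / (1 - cr)
      t_cens <- stats::rexp(1, mu)
    } else {
      t_cens <- Inf
    }
    list(days = max(min(t_event, t_cens), 1), event = t_event <= t_cens)
  }
  os <- one("os"); pfs <- one("pfs")
  list(os_days = os$days, os_event = os$event,
       pfs_days = pfs$days, pfs_event = pfs$event)
}

#' Generate a synthetic 8 x 8 CSI metabolite grid for one patient
#'
#' Each CSI voxel covers a block of map-grid columns on the central slice
#' (its footprint). NAA/Cr is near normal-tissue levels outside tumor and
#' depressed inside; cluster-2 patients get an extra NAA/Cr shift in voxels
#' dominated by non-enhancing tumor. Cho/Cr is elevated in tumor independent
#' of cluster. Per-voxel, per-metabolite quality SDs (percent, Cramer-Rao
#' style) are log-normal, so a realistic minority exceeds the 20% cutoff.
#'
#' @param patient_bundle per-patient bundle holding at least `masks$flair`.
#' @inheritParams generate_patient
#' @return object of class `csi_grid`: 8 x 8 matrices `naa_cr`, `cho_cr`,
#'   `sd_naa`, `sd_cho`, plus `footprints` (linear map-voxel indices).
#' @export
generate_csi_grid <- function(patient_bundle, config) {
  assert_that(!is.null(patient_bundle$masks$flair), "patient must have a FLAIR mask")
  g <- config$grid_shape
  flair <- patient_bundle$masks$flair
  ce <- patient_bundle$masks$ce %||% array(FALSE, g)
  nrows <- 8L; ncols <- 8L
  xb <- floor(seq(0, g[1], length.out = ncols + 1))
  yb <- floor(seq(0, g[2], length.out = nrows + 1))
  zmid <- ceiling(g[3] / 2)
  footprints <- vector("list", nrows * ncols)
  naa <- cho <- sd_naa <- sd_cho <- matrix(NA_real_, nrows, ncols)
  for (i in seq_len(nrows)) {
    for (j in seq_len(ncols)) {
      xs <- (xb[j] + 1):xb[j + 1]; ys <- (yb[i] + 1):yb[i + 1]
      idx <- as.vector(outer(xs, (ys - 1) * g[1], "+") +
                         (zmid - 1) * g[1] * g[2])
      k <- (j - 1) * nrows + i
      footprints[[k]] <- sort(idx)
      frac_tumor <- mean(flair[idx])
      frac_ne <- mean(flair[idx] & !ce[idx])
      mu_naa <- log(1.6) + frac_tumor * (log(0.8) - log(1.6))
      if (patient_bundle$true_cluster == 2 && frac_ne > 0.5)
        mu_naa <- mu_naa + config$naa_shift_cluster2
      mu_cho <- log(1.0) + frac_tumor * (log(1.5) - log(1.0))
      naa[i, j] <- stats::rlnorm(1, mu_naa, 0.20)
      cho[i, j] <- stats::rlnorm(1, mu_cho, 0.20)
      sd_naa[i, j] <- stats::rlnorm(1, log(12), 0.45)
      sd_cho[i, j] <- stats::rlnorm(1, log(12), 0.45)
    }
  }
  structure(list(naa_cr = naa, cho_cr = cho, sd_naa = sd_naa, sd_cho = sd_cho,
                 footprints = footprints, grid_shape = g),
            class = "csi_grid")
}

#' Generate a synthetic cohort
#'
#' Draws `n_patients` per-patient bundles (five parametric maps, mask set,
#' covariates, OS/PFS survival, CSI grid, true cluster label). Cluster counts
#' are deterministic (`round(n * proportions)`), so the default 80-patient
#' cohort splits exactly 53/27. Identical configs (including seed) give
#' bit-identical cohorts, and patient `i` is unchanged by varying `n_patients`.
#'
#' @param config a [cohort_config()].
#' @return object of class `synthetic_cohort`: list with `patients` and `config`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 8, seed = 1))
#' table(vapply(cohort$patients, `[[`, 1L, "true_cluster"))
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  n1 <- round(n * config$cluster_proportions[1])
  clusters <- rep(c(1L, 2L), c(n1, n - n1))
  patients <- lapply(seq_len(n), function(i)
    generate_patient(i, clusters[i], config))
  structure(list(patients = patients, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cl <- vapply(x$patients, `[[`, 1L, "true_cluster")
  cat(sprintf("synthetic_cohort: %d patients (cluster 1: %d, cluster 2: %d), grid %s\n",
              length(x$patients), sum(cl == 1), sum(cl == 2),
              paste(x$config$grid_shape, collapse = "x")))
  invisible(x)
}

#' Write a cohort to disk as NIfTI volumes plus CSV/JSON metadata
#'
#' One directory per patient with the five maps and four masks as `.nii.gz`,
#' a cohort-level `clinical.csv` (covariates + survival + true cluster) and a
#' `manifest.json` mapping patients to files.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  rows <- list()
  for (p in cohort$patients) {
    pdir <- file.path(dir, p$id)
    dir.create(pdir, showWarnings = FALSE)
    files <- list()
    for (m in names(p$maps)) {
      f <- file.path(pdir, paste0(m, ".nii.gz"))
      write_nifti(p$maps[[m]], f)
      files[[m]] <- f
    }
    for (m in c("ce", "flair", "nawm")) {
      f <- file.path(pdir, paste0("mask_", m, ".nii.gz"))
      write_nifti(p$masks[[m]], f)
      files[[paste0("mask_", m)]] <- f
    }
    manifest[[p$id]] <- files
    rows[[p$id]] <- data.frame(id = p$id, true_cluster = p$true_cluster,
                               as.data.frame(p$covariates),
                               as.data.frame(p$survival[c("os_days", "os_event",
                                                          "pfs_days", "pfs_event")]))
  }
  utils::write.csv(do.call(rbind, rows), file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort previously written by [write_cohort()]
#'
#' @param dir directory produced by [write_cohort()].
#' @return a `synthetic_cohort`-shaped list (without CSI grids).
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  clinical <- utils::read.csv(file.path(dir, "clinical.csv"))
  patients <- lapply(names(manifest), function(id) {
    files <- manifest[[id]]
    maps <- lapply(files[map_names()], read_nifti)
    ce <- read_nifti(files$mask_ce); flair <- read_nifti(files$mask_flair)
    row <- clinical[clinical$id == id, ]
    list(id = id, true_cluster = row$true_cluster, maps = maps,
         masks = list(ce = ce, flair = flair, ne = flair & !ce,
                      nawm = read_nifti(files$mask_nawm)),
         covariates = as.list(row[c("age_group", "sex", "resection", "mgmt",
                                    "idh1", "ce_volume")]),
         survival = as.list(row[c("os_days", "os_event", "pfs_days", "pfs_event")]))
  })
  structure(list(patients = patients, config = NULL), class = "synthetic_cohort")
}
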