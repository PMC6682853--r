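#' Pipeline configuration
#'
#' One JSON-serializable document controlling an end-to-end run: either a
#' synthetic-cohort specification or a path to an on-disk cohort, plus the
#' knobs of every stage. Every run writes its resolved configuration next to
#' its outputs.
#'
#' @param cohort_dir path to a cohort written by [write_cohort()]; `NULL`
#'   (default) generates a synthetic cohort instead.
#' @param synthetic list of [cohort_config()] overrides for synthetic runs.
#' @param n_bins histogram bins.
#' @param feature_k,patient_k candidate k ranges (2-vectors `c(lo, hi)`).
#' @param integration `"ward"` or `"spectral"`.
#' @param final_k final number of patient clusters.
#' @param min_prop cutpoint admissibility fraction.
#' @param n_boot bootstrap resamples for ROC comparison.
#' @param run_loocv,run_survival,run_mrs stage switches.
#' @param seed root seed.
#' @param out_dir output directory.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort_dir = NULL, synthetic = list(),
                            n_bins = 100L, feature_k = c(2L, 10L),
                            patient_k = c(2L, 10L),
                            integration = c("ward", "spectral"),
                            final_k = 2L, min_prop = 0.1, n_boot = 2000L,
                            run_loocv = TRUE, run_survival = TRUE,
                            run_mrs = TRUE, seed = 1L, out_dir = NULL) {
  integration <- match.arg(integration)
  structure(list(cohort_dir = cohort_dir, synthetic = synthetic,
                 n_bins = as.integer(n_bins),
                 feature_k = as.integer(feature_k),
                 patient_k = as.integer(patient_k),
                 integration = integration, final_k = as.integer(final_k),
                 min_prop = min_prop, n_boot = as.integer(n_boot),
                 run_loocv = run_loocv, run_survival = run_survival,
                 run_mrs = run_mrs, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path JSON file path.
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, x[intersect(names(x), names(formals(pipeline_config)))])
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  invisible(path)
}

resolve_cohort <- function(config) {
  if (!is.null(config$cohort_dir)) {
    if (!dir.exists(config$cohort_dir))
      stop("cohort_dir does not exist: ", config$cohort_dir)
    read_cohort(config$cohort_dir)
  } else {
    cc <- do.call(cohort_config,
                  utils::modifyList(list(seed = config$seed), config$synthetic))
    generate_cohort(cc)
  }
}

pipeline_log <- function(log, stage, msg) {
  line <- sprintf("[%s] %s", stage, msg)
  message(line)
  c(log, line)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: cohort (load or simulate), feature extraction, multi-view
#' clustering, LOOCV consensus, survival and feature-ranking analyses, MRS
#' comparison. When `config$out_dir` is set, artifacts are written there
#' (feature table / final labels / consensus matrix / ranked features as CSV,
#' centroid sets, survival and ROC results as JSON, the resolved config, and
#' a run log); otherwise everything stays in memory.
#'
#' @param config a [pipeline_config()].
#' @return list of stage results, invisibly when writing to disk.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character()
  out <- list(config = config)
  log <- pipeline_log(log, "cohort", "resolving cohort")
  cohort <- resolve_cohort(config)
  out$cohort <- cohort
  n <- length(cohort$patients)
  log <- pipeline_log(log, "cohort", sprintf("%d patients", n))

  log <- pipeline_log(log, "features", "extracting histogram features")
  ft <- build_feature_table(cohort, n_bins = config$n_bins)
  out$feature_table <- ft

  log <- pipeline_log(log, "cluster", sprintf("multi-view clustering (%s)",
                                              config$integration))
  fk <- seq(config$feature_k[1], config$feature_k[2])
  pk <- seq(config$patient_k[1], config$patient_k[2])
  clustering <- multiview_cluster(ft, feature_k_candidates = fk,
                             patient_k_candidates = pk,
                             final_k = config$final_k,
                             method = config$integration)
  out$clustering <- clustering
  log <- pipeline_log(log, "cluster",
                      sprintf("final sizes %s",
                              paste(table(clustering$final_labels), collapse = "/")))

  if (config$run_loocv) {
    log <- pipeline_log(log, "loocv", "leave-one-out consensus")
    parts <- loocv_clusterings(ft, feature_k_candidates = fk,
                               patient_k_candidates = pk,
                               final_k = config$final_k,
                               method = config$integration)
    M <- consensus_matrix(parts, rownames(ft))
    out$loocv <- list(partitions = parts, consensus = M,
                      cluster_means = cluster_consensus_means(M, clustering$final_labels))
    log <- pipeline_log(log, "loocv",
                        sprintf("cluster consensus means: %s",
                                paste(round(out$loocv$cluster_means, 3), collapse = ", ")))
  }

  if (config$run_survival) {
    log <- pipeline_log(log, "survival", "survival and ranking analyses")
    surv <- do.call(rbind, lapply(cohort$patients, function(p)
      as.data.frame(p$survival[c("os_days", "os_event", "pfs_days", "pfs_event")])))
    covs <- do.call(rbind, lapply(cohort$patients, function(p)
      as.data.frame(p$covariates)))
    labels <- clustering$final_labels[rownames(ft)]
    centroids <- unique(unlist(lapply(clustering$centroid_sets, `[[`, "centroids")))
    ranked <- rank_features(unclass(ft)[, centroids, drop = FALSE], labels)
    lr <- log_rank_test(factor(labels), surv$os_days, surv$os_event)
    km <- kaplan_meier(surv$os_days, surv$os_event, factor(labels))
    cox_df <- cbind(covs, cluster2 = as.integer(labels == 2))
    cox_os <- cox_ph_fit(cox_df, surv$os_days, surv$os_event)
    cox_pfs <- cox_ph_fit(cox_df, surv$pfs_days, surv$pfs_event)
    sel <- ranked$feature[ranked$selected]
    roc <- NULL
    y12 <- outcome_12mo(surv$os_days, surv$os_event)
    if (length(sel) > 0 && length(unique(stats::na.omit(y12))) == 2) {
      roc <- incremental_auc(covs, unclass(ft)[, sel, drop = FALSE], y12,
                             n_boot = config$n_boot, seed = config$seed)
    }
    out$survival <- list(records = surv, covariates = covs, ranked = ranked,
                         log_rank_os = lr, km_os = km, cox_os = cox_os,
                         cox_pfs = cox_pfs, roc_os_12mo = roc)
    log <- pipeline_log(log, "survival",
                        sprintf("OS log-rank p = %.4g; %d feature(s) selected",
                                lr$p, sum(ranked$selected)))
  }

  if (config$run_mrs && !is.null(cohort$patients[[1]]$csi)) {
    log <- pipeline_log(log, "mrs", "CSI metabolite comparison")
    sm <- patient_metabolite_summary(cohort)
    comp <- compare_metabolites(sm[, c("id", "naa_cr", "cho_cr")],
                                stats::setNames(clustering$final_labels[sm$id], sm$id))
    out$mrs <- list(summaries = sm, comparison = comp)
  }

  out$log <- log
  if (!is.null(config$out_dir)) {
    write_pipeline_artifacts(out, config$out_dir)
    return(invisible(out))
  }
  out
}

# CSV/JSON artifact writer; deterministic content for a fixed config + seed.
write_pipeline_artifacts <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f) utils::write.csv(x, file.path(dir, f), row.names = TRUE)
  w(as.data.frame(unclass(out$feature_table)), "feature_table.csv")
  utils::write.csv(data.frame(id = names(out$clustering$final_labels),
                              cluster = out$clustering$final_labels),
                   file.path(dir, "final_labels.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(centroids = lapply(out$clustering$centroid_sets, `[[`, "centroids"),
         per_view_k = as.list(out$clustering$per_view_k),
         method = out$clustering$method),
    file.path(dir, "clustering.json"), auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(out$loocv)) w(as.data.frame(out$loocv$consensus), "consensus_matrix.csv")
  if (!is.null(out$survival)) {
    utils::write.csv(out$survival$ranked, file.path(dir, "ranked_features.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(log_rank_os = out$survival$log_rank_os,
           cox_os = out$survival$cox_os$terms,
           cox_pfs = out$survival$cox_pfs$terms,
           km_medians_os = as.list(out$survival$km_os$medians),
           roc_os_12mo = if (!is.null(out$survival$roc_os_12mo))
             out$survival$roc_os_12mo[c("delta", "p", "method", "n",
                                        "auc_baseline", "auc_augmented")]),
      file.path(dir, "survival.json"), auto_unbox = TRUE, pretty = TRUE,
      digits = 10, null = "null")
  }
  if (!is.null(out$mrs))
    utils::write.csv(out$mrs$comparison, file.path(dir, "mrs_comparison.csv"),
                     row.names = FALSE)
  write_pipeline_config(out$config, file.path(dir, "config.json"))
  writeLines(out$log, file.path(dir, "run.log"))
  invisible(dir)
}
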