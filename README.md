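# mvmri

Multi-view histogram analysis of multi-parametric MRI for brain-tumor
phenotyping.

## The problem

Glioblastoma is radiologically heterogeneous: perfusion maps (rCBV, MTT,
rCBF from dynamic susceptibility contrast MRI) and diffusion maps (the
isotropic *p* and anisotropic *q* components of the diffusion tensor) each
capture a different facet of tumor physiology, and the contrast-enhancing
(CE) core behaves differently from the non-enhancing (NE) FLAIR-hyperintense
margin where infiltration happens. Pooling all of these features into one
matrix ("early integration") lets noisy views drown informative ones. This
package implements the alternative: **multi-view late integration**, where
each modality-region view is reduced and clustered on its own, and only the
per-view partitions are fused into the final patient phenotypes.

It is aimed at imaging researchers who want a tested, reproducible
implementation of the full workflow — and a synthetic-cohort generator so
that every stage can be exercised and validated without access to clinical
data.

## The method

For each patient, the five co-registered maps are normalized voxel-wise by
the mean over normal-appearing white matter (NAWM), and 10 histogram
statistics (mean, SD, median, 100-bin histogram mode, skewness, excess
kurtosis, Prc5/Prc25/Prc75/Prc95) are extracted from the CE region and from
the NE region (FLAIR ∧ ¬CE), giving 100 features split into four views:
CE-diffusion (20), NE-diffusion (20), CE-perfusion (30), NE-perfusion (30).

Within each view *v* with standardized feature matrix X⁽ᵛ⁾:

1. **Feature clustering** — Ward agglomeration under d(fᵢ, fⱼ) = 1 − |r(fᵢ, fⱼ)|,
   k chosen by average silhouette width;
2. **Centroid selection** — each feature cluster is represented by its
   correlation medoid, argmaxᵢ meanⱼ≠ᵢ |r(fᵢ, fⱼ)|;
3. **Patient clustering** — Ward on Euclidean distance over the centroid
   features, k again by silhouette;
4. **Late integration** — per-view labels are one-hot encoded, stacked, and
   Ward-clustered into the two final phenotypes (a spectral cut of the
   co-association matrix is available as an alternative).

Stability is assessed by leave-one-out cross-validation: the whole pipeline
is rerun n times leaving one patient out, and the consensus matrix M(i,j) —
the fraction of repetitions containing both i and j in which they co-cluster
— is summarized per cluster. Prognostic value is assessed with maximally
selected log-rank cutpoints, Kaplan-Meier/log-rank, Cox proportional hazards
(Efron ties), logistic-model ROC comparison for 12-month outcomes (paired
bootstrap), and Wilcoxon + Benjamini-Hochberg comparison of CSI metabolite
ratios (NAA/Cr, Cho/Cr) over tumor-dominant spectroscopy voxels.

## Worked example

```r
library(mvmri)

cohort <- generate_cohort(cohort_config(seed = 1))   # 80 patients, 2 phenotypes
ft <- build_feature_table(cohort)
cl <- multiview_cluster(ft)
print(cl)
#> multiview_clustering: 80 patients -> 2 final clusters (ward)
#>   per-view k: 10, 8, 10, 2
#>   final sizes: 54/26

truth <- vapply(cohort$patients, `[[`, 1L, "true_cluster")
adjusted_rand_index(cl$final_labels, truth)
#> [1] 0.95
```

The generator plants a 53/27 phenotype split (cluster 2 favorable, larger NE
volume); the recovered 54/26 partition agrees with the planted one at
ARI 0.95. Leave-one-out consensus and survival contrast:

```r
parts <- loocv_clusterings(ft)
M <- consensus_matrix(parts, rownames(ft))
round(cluster_consensus_means(M, cl$final_labels), 2)
#>    1    2
#> 0.97 0.94     # within-cluster co-occurrence: the partition is stable

surv <- do.call(rbind, lapply(cohort$patients,
                              function(p) as.data.frame(p$survival[1:4])))
cox_ph_fit(data.frame(cluster2 = as.integer(cl$final_labels == 2)),
           surv$os_days, surv$os_event)
#> cox_model: n = 80, events = 59, loglik = -199.014
#>       term    hr    lo    hi      p
#> 1 cluster2 0.527 0.293 0.949 0.0329
```

The recovered cluster 2 has a lower hazard (HR 0.53 in this 80-patient draw;
the generator's true HR is 0.32, recovered within [0.25, 0.41] at n = 1000
in the test suite). Ranking the centroid features by logistic-regression
importance puts NE-region means on top, mirroring where the generator
concentrates the phenotype contrast:

```r
#>        feature     importance selected
#> 17 Mean-MTT-NE      100.00000     TRUE
#> 5    Mean-p-NE       85.79732     TRUE
#> 15 Mean-rCBV-NE      71.53144     TRUE
#> 19 Mean-rCBF-NE      56.46932     TRUE
```

A command-line interface covers the same stages
(`inst/cli/mvmri simulate|features|cluster|loocv|survival|mrs|run-all`),
with `--seed`, `--config cfg.json`, `--out dir`, and `--show-config`.

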