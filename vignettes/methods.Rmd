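---
title: "Multi-view histogram analysis of multi-parametric MRI: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-view histogram analysis of multi-parametric MRI: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mvmri)
```

This vignette is the package's own account of its statistical machinery: the
models and procedures, the parameters that matter, what the synthetic world
does and does not emulate, and the places where the design was genuinely
open and a choice had to be made. It states no empirical result that the
test suite does not itself compute.

## 1. Regions, normalization, histogram features

Each patient contributes five co-registered parametric maps — DTI-p
(isotropic diffusion), DTI-q (anisotropic diffusion), rCBV, MTT, rCBF — and
three masks: contrast-enhancing tumor (CE), FLAIR-hyperintense tumor, and
contralateral normal-appearing white matter (NAWM). The non-enhancing region
is the exact Boolean subtraction NE = FLAIR ∧ ¬CE (`derive_ne_mask()`). Maps
are normalized by dividing every voxel by the scalar NAWM mean of that map
(`normalize_map()`), making intensities dimensionless ratios with NAWM ≈ 1;
features are therefore invariant to any joint rescaling of a map and its
NAWM reference, a property the suite checks.

Ten statistics are computed per map and region (`compute_histogram_features()`):
mean, SD, median, mode, skewness, excess kurtosis, and the 5th/25th/75th/95th
percentiles — 10 × 5 maps × 2 regions = 100 features, in four views
(CE-diffusion 20, NE-diffusion 20, CE-perfusion 30, NE-perfusion 30).
Numerical conventions, fixed and documented because the underlying
definitions admit variants:

* **Percentiles** — linear interpolation between order statistics
  (`stats::quantile` type 7), the common statistical default.
* **Mode** — center of the most populated of 100 equal-width bins spanning
  [min, max], ties to the lowest bin. A raw-value mode is ill-defined for
  continuous data; the histogram itself supplies the natural definition.
  All other statistics are computed on the raw voxel values, not on binned
  counts — binning would discard information the estimators can use.
* **Skewness/kurtosis** — population (biased) moment estimators; kurtosis is
  reported as excess kurtosis. A constant region returns SD 0 and
  skewness/kurtosis 0 by convention, with a warning, rather than NaN.
* Non-finite voxels are dropped before any computation, with a message
  carrying the count; regions with fewer than 2 finite voxels are an error
  that `build_feature_table()` surfaces per patient (abort, NA-fill, or drop,
  per its `on_failure` argument).

## 2. Multi-view late-integration clustering

Views are standardized (each feature to mean 0, SD 1) independently in every
run — including inside every leave-one-out repetition, so no scaling
information leaks from a held-out patient.

* **Feature clustering** uses Ward linkage on d = 1 − |Pearson r|. The
  absolute value makes anticorrelated features (e.g. a mean and a skewness
  responding oppositely to the same shift) neighbors, which is what centroid
  *representation* requires. The number of feature clusters is chosen by
  average silhouette width over candidates 2–10.
* **Centroid selection** takes, per feature cluster, the member maximizing
  the mean absolute correlation with the other members (the correlation
  medoid); singletons represent themselves; exact ties go to the earlier
  column, for determinism.
* **Patient clustering** per view is Ward on Euclidean distance over the
  standardized centroid features, k again by silhouette over 2–10. The
  2–10 range admits the fine per-view partitions (k of 7–10) this family of
  methods tends to produce on clinical-scale cohorts.
* **Late integration**: each view's labels become a one-hot membership
  matrix; the matrices are stacked and patients are Ward-clustered into the
  final k = 2. Because Euclidean distance on one-hot encodings depends only
  on same-cluster/different-cluster indicators, the integration is invariant
  to relabeling any view's clusters (tested). An alternative strategy —
  normalized spectral partitioning of the patient co-association matrix
  (fraction of views co-clustering a pair) — is selectable via
  `integrate_views(method = "spectral")`; the stacked-Ward default was chosen
  because it is deterministic (no k-means restarts) and the two agree on
  well-separated cohorts. Final labels are renumbered by decreasing cluster
  size, so "cluster 1" is always the larger group.

The silhouette index was chosen as the internal criterion for every k
selection because one criterion applied uniformly keeps the pipeline
coherent, and silhouette is defined for arbitrary dissimilarities (it reuses
the clustering's own distance in each stage). Ward merge ties are resolved
by `stats::hclust`'s deterministic ordering.

## 3. Leave-one-out consensus

`loocv_clusterings()` reruns the *entire* pipeline n times, leaving out one
patient each time. The consensus matrix M(i,j) is the fraction of
repetitions containing both i and j in which they share a cluster; the
denominator is the number of co-present repetitions (n − 2 for LOOCV) — the
only well-defined convention when every repetition omits someone. Left-out
patients are not post-hoc assigned to a cluster in their repetition: the
consensus uses co-occurrence only. Per-cluster stability is the mean of
off-diagonal within-cluster entries; a singleton cluster has no pair and
reports NA. In the perfect-stability limit (every LOOCV partition restricts
the full-data partition) within-cluster means are exactly 1, a limit the
suite checks.

## 4. Survival and discrimination machinery

* **Feature ranking** (`rank_features()`): logistic regression of the final
  label on the standardized centroid features; importance is the absolute
  Wald z per coefficient, min-max scaled to [0, 100]; score > 50 flags a
  feature as selected. This is the glm variable-importance convention of the
  caret ecosystem. Under (quasi-)perfect separation — common when the
  clustering is sharp, since the labels were derived from these features —
  the unpenalized Wald statistics degenerate, so the model is refit with a
  small ridge penalty (λ = 0.01 on standardized coefficients) and z is taken
  from the penalized curvature, with a warning. Aliased or constant columns
  score 0.
* **Cutpoints** (`optimal_cutpoint()`): maximally selected rank statistics —
  the absolute standardized log-rank statistic is scanned over every
  observed split leaving at least `min_prop = 0.1` of patients on each side
  (the cited ecosystem's default), ties to the smaller cutpoint. The scan
  uses the package's own O−E/√V implementation; the tests compare it against
  exhaustive `survival::survdiff` enumeration.
* **Log-rank, Kaplan-Meier, Cox** are backed by the `survival` package
  (`survdiff`, `survfit`, `coxph` with Efron ties by default, Breslow
  selectable) behind this package's interfaces; the tests verify them
  against textbook hand computations and a brute-force partial-likelihood
  oracle. Constant covariates are dropped with a warning (small cohorts
  routinely collapse a factor to one level).
* **12-month outcomes** (`outcome_12mo()`): event by day 365 → 1; event-free
  past day 365 → 0; censored before day 365 → excluded, with a logged count.
  The exclusion rule is the package's choice where the underlying procedure
  is silent; the alternative (treating early-censored patients as
  event-free) biases toward 0.
* **Incremental AUC** (`incremental_auc()`): in-sample ROC AUCs of the
  baseline and the baseline-plus-features logistic models, percentile
  bootstrap CIs (models refit per resample), and a paired bootstrap p-value
  for the AUC difference (2000 resamples, seeded). A one-way ANOVA across
  the two bootstrap AUC sets is retained as `method = "anova"` for
  comparability with older workflows, but the paired bootstrap is primary:
  ANOVA on resampled AUCs treats dependent resamples as independent
  replicates. Note that in-sample AUC of a nested model is *not* guaranteed
  to be monotone (the likelihood is); the suite tests the deviance
  inequality exactly and the AUC version with small reordering slack.
* **MRS comparison**: CSI voxels are retained when tumor occupancy is
  *strictly* above 50% and quality SD is at most 20% (the discard rule is
  strictly-greater, so exactly 20% survives); per-patient summaries are the
  median over retained voxels (robust in the few-voxel regime; configurable),
  compared between clusters by two-sided Wilcoxon rank-sum with
  Benjamini-Hochberg adjustment across the whole family of
  metabolite-region comparisons in one batch. Per-patient summaries (rather
  than pooled per-voxel values) keep the test's independence assumption.

## 5. The synthetic world

`generate_cohort()` draws a cohort with the statistical structure the
downstream analysis assumes — it is a stated world, not a tuning knob:

* **Two phenotypes**, deterministic 53/27 split at n = 80 (cluster counts
  are `round(n·p)`, so the default cohort reproduces the canonical sizes
  exactly). Cluster 2 is the favorable minority.
* **Voxel intensities** are log-normal per modality and region (ratio images
  are positive and right-skewed). A patient's regional log-mean is the
  modality-region baseline + half the cluster contrast (sign by cluster) + a
  patient-level random effect (SD 0.15); voxel log-SD is 0.3. The view
  effect size is the cluster contrast in units of the patient SD, i.e. the
  standardized between-patient shift of the downstream mean-type features.
  Defaults are d = 3.0 for the NE views and 1.5 for the CE views: the
  contrast is concentrated in the non-enhancing margin (where infiltration
  differentiates phenotypes) but present in the core, matching a world in
  which CE-view features still carry prognostic signal. These magnitudes
  were fixed once so that the planted structure is clearly present —
  two phenotypes that the method itself can recover (end-to-end ARI ≥ 0.8
  averaged over seeds, the calibration the acceptance criteria state) —
  and were verified on an independent seed range before freezing.
* **Within-cluster independence**: patient-level effects are drawn
  independently per modality-region. Real multi-parametric features are
  correlated within patients beyond cluster membership; this is a known
  simplification (the underlying covariance is not reported anywhere to
  emulate), so a green recovery test establishes correct mechanics on
  independent views, not performance under realistic cross-view covariance.
* **Masks** are spheres with per-patient jitter: CE nucleus inside a FLAIR
  envelope, NAWM contralateral and disjoint from FLAIR by construction.
  Cluster-2 patients get a 1.25× FLAIR radius (≈ 2× NE volume), mirroring
  the larger non-enhancing volume of the favorable phenotype; CE volume is
  cluster-independent.
* **Survival** is exponential proportional hazards: cluster-1 median OS 424
  days (PFS 248), hazard ratio 0.32 (OS) / 0.33 (PFS) for cluster 2.
  Censoring is an independent exponential whose rate is calibrated so the
  cluster-averaged censoring probability equals `censoring_rate` (default
  0.2); the realized fraction differs slightly by cluster (the favorable
  cluster is censored more often), which is how administrative censoring
  behaves in practice. The generator was validated by large-sample Cox
  recovery of the true HR before the package was built.
* **Covariates** (age group, sex, resection extent, MGMT, IDH-1, CE volume)
  follow realistic marginal frequencies for a newly diagnosed glioblastoma
  cohort and are independent of cluster — the phenotype is an imaging
  phenotype, not a clinical-covariate artifact.
* **CSI grids** are 8 × 8, each voxel's footprint a block of map-grid
  columns on the central slice (footprints partition the slice). NAA/Cr
  falls with tumor occupancy; cluster-2 patients get an additional −0.3
  log-shift in NE-dominant voxels (lower neuronal integrity signal in the
  favorable, more infiltrated-margin phenotype). Cho/Cr rises with tumor
  occupancy, cluster-independent — though because cluster 2 has larger
  tumors, occupancy differences can induce a secondary Cho/Cr contrast;
  tests therefore assert only the planted NAA/Cr behavior. Quality SDs are
  log-normal around 12%, so a realistic minority of voxels fails the 20%
  filter.
* **Reproducibility**: one root seed; per-patient child seeds are derived
  deterministically from it, so patient i's data are identical regardless of
  cohort size, and identical configs give bit-identical cohorts.

What the world does *not* emulate: raw DWI/DSC signal formation,
registration error, scanner effects, pseudoprogression dynamics, or
within-patient spatial correlation of voxel noise. Histogram features are
insensitive to the last of these (they are permutation-invariant within a
region), but any conclusion about spatial methods would be out of scope.

## 6. Known limitations

* The per-view silhouette k-selection often returns fine partitions
  (k 7–10); the final two-phenotype cut then rests on the late integration,
  which uses only pairwise co-clustering information. On cohorts with weak
  planted contrast the end-to-end recovery is honestly variable from seed to
  seed — the LOOCV consensus means are the instrument for judging whether a
  given partition is trustworthy.
* The minimal NIfTI-1 reader/writer supports little-endian float32/uint8
  single-file volumes on an identity grid; it is an interchange format for
  co-registered arrays, not a general neuroimaging I/O layer.
* In-sample AUCs are optimistic; the bootstrap CIs quantify resampling
  variability, not out-of-sample performance.
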