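---
title: "Microstructural tissue classification: model, choices, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microstructural tissue classification: model, choices, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qmriclass)
```

## The model

`qmriclass` treats each brain voxel as a point in a three-dimensional
microstructural feature space: myelin water fraction (MWF, unitless fraction
in [0, 1], a myelin proxy), microscopic fractional anisotropy (µFA, unitless
in [0, 1], axonal integrity corrected for orientation dispersion) and C_MD
(unitless, non-negative, the normalised variance of sub-voxel mean
diffusivities — a heterogeneity proxy). Tissue classes are defined *only* by
where voxels sit in this space; spatial position never enters the model. The
assumptions behind that choice are:

* the three metrics carry largely non-redundant information (checked by
  `metric_structure()`: correlation matrix plus correlation-PCA explained
  variance ratios — if one ratio were near zero a metric could be dropped);
* healthy tissue occupies a small number of reasonably compact regions in
  feature space, so a fuzzy mixture of K clusters is an adequate taxonomy;
* metric maps of different subjects are comparable after CSF exclusion,
  i.e. acquisition and preprocessing are consistent across the cohort.
  Registration, CSF segmentation and map estimation happen upstream; the
  package consumes co-registered per-subject volumes and treats masks as
  given.

Fitting proceeds as pool → scale → cluster → order → classify:

1. **Pooling** (`pool_subjects()`): all valid masked voxels of the training
   subjects form an N × 3 matrix. Voxels with non-finite metrics are dropped
   (with a reported count) rather than imputed.
2. **Scaling** (`fit_scaler()`): per-metric standardisation using the
   population (divide-by-N) standard deviation — the conventional "standard
   scaler". Test subjects are always scaled with the *training* parameters;
   refitting on a test subject would break the classifier contract.
3. **Clustering** (`fcm_fit()`): fuzzy c-means minimising
   \(J_m=\sum_i\sum_k u_{ik}^m\|x_i-c_k\|^2\) under row-stochastic
   memberships, fuzzifier \(m = 2\) (the conventional default; configurable).
   Iteration stops when the largest membership change drops below `tol`
   (default 1e-5) or after `max_iter` (1000) sweeps. A voxel coinciding with
   one or more centroids splits its membership evenly among the
   zero-distance clusters.
4. **Ordering** (`order_clusters_by_mwf()`): clusters are relabelled by
   descending mean native-unit MWF of their hard-assigned voxels, so
   "cluster 1" always means the most myelinated class; ties break by
   descending mean µFA, then raw index. Ordering uses hard assignments
   rather than fuzzy-weighted means — simpler, and at the separations where
   the taxonomy is meaningful the two coincide.
5. **Classification** (`classify_subject()`): each masked voxel of a new
   subject is assigned the majority label among its `knn_k = 5` nearest
   labelled training points (Euclidean distance in scaled space), with vote
   ties going to the lowest (most myelinated) label. Invalid voxels get
   label 0, which downstream comparison excludes and tallies.

## Choosing the number of clusters

`select_cluster_number()` fits each candidate K on the training pool,
classifies held-out test pools, and computes the Calinski–Harabasz and
Davies–Bouldin indices on the *test-side* classifications — scoring a
clustering by how well it transfers to unseen subjects, not by training-set
fit. Scores are averaged across test pools (one per test subject). The
selected K maximises the combined rank (CH descending + DB ascending);
rank-sum ties break toward the higher CH, then the lower K. The full score
table is always returned: the indices are guides, and a reader should inspect
them rather than trust the argmax blindly — for brain data adjacent K are
often nearly equivalent, and the report makes an informed override possible.
The default search range 2–10 brackets the plausible taxonomies for
three-metric brain data.

`rotation_cv()` complements this with a stability check: a seeded shuffle
partitions the cohort into 5 folds (contiguous blocks), each subject is
classified by the model trained on the other folds, and the labels are
compared voxelwise with the all-subject model. Stable taxonomies change only
a few percent of voxels.

## Comparison against the atlas and severity

`build_metric_atlas()` averages each metric voxelwise over the subjects whose
mask covers the voxel; the atlas mask keeps voxels covered by at least half
the cohort. The atlas pseudo-subject is classified with the same model as any
individual. `difference_map()` then looks only at voxels the atlas labels
white matter (clusters 1–3 by default): a positive `subject − atlas`
difference marks a shift toward less-myelinated classes, the signature of
demyelination and axonal damage; shifts in the opposite direction would claim
*more* myelin than the healthy average — usually partial-volume or
registration artefact — and are excluded from the map but reported as the
`opposite_change_fraction`. The severity score
\(S = 1000\,\#\{d{=}1\}/V - 50\) (with V the CSF-excluded brain voxel count)
is kept exactly in this form, offset included, so scores are comparable
across studies; scores for larger differences \(d \ge 2\) use the same
per-mille scale but no offset, since the offset is defined only for the
\(d = 1\) score. The brain denominator excludes CSF (label 0); a different
denominator can be supplied via `normalized_cluster_sizes(total_voxels=)` if
a mask including CSF is preferred.

## The synthetic phantom

`generate_cohort()` emulates the study conditions a healthy-control cohort
provides: 25 subjects, co-registered by construction, with K = 6 tissue
classes laid out as concentric ellipsoidal shells (deep white matter at the
core, cortical grey matter at the surface) plus two embedded deep-grey blobs
for the iron-like class, and CSF/background outside. Per class × metric the
voxel values are Gaussian; defaults follow the qualitative signatures of the
six healthy classes (class 1: MWF 0.15, µFA 0.90, C_MD 0.05 — high myelin,
high anisotropy, low heterogeneity; descending MWF to cortical grey matter at
0.03/0.40/0.30; iron-like class at 0.05/0.32/0.38, an apparent-MWF bump above
its grey-matter neighbours with low anisotropy and high heterogeneity).
Voxel noise SDs (0.010/0.020/0.015) put neighbouring classes ≳6 combined SDs
apart — clearly separated, as the real taxonomy's classes are in the measures
that define them. Subject-level offsets (SD 0.005/0.004/0.003) encode that
MWF varies relatively more between individuals than the diffusion metrics.
Gaussian draws are truncated at the physical bounds rather than re-sampled;
the induced bias is negligible at ≥3 SD from a bound (the worst case is
cortical MWF at 3 SD, where the mean shift is ~4e-5, an order of magnitude
below the subject-offset SE).

Because classes are reported in mean-MWF order while the iron class breaks
that order by design, `generate_cohort()` returns both the generated class
ids (`truth`) and the same layout mapped through the expected ordering
(`truth_ordered`); with the default parameters only the two grey-matter-range
classes swap (iron → ordered label 5), so white matter keeps ordered labels
1–3 and the difference-map semantics are untouched.

`inject_lesions()` places non-overlapping spheres wholly inside white-matter
classes and redraws their voxels from the class-(c+d) distribution (capped at
the highest non-iron class) — an idealised focal lesion whose voxels should
classify one class "worse" than their surroundings. `emit_clinical_scores()`
constructs SDMT/EDSS tables linearly tied to lesion burden so that rank
correlations with severity have a known sign and, at zero noise, magnitude 1.

What the phantom does *not* emulate: partial-volume mixing at class borders
(optional smoothing can approximate it but is off in tests), registration
error between subject and atlas (cohorts share a grid by construction),
field inhomogeneity or any MRI physics, atrophy, and the real covariance
structure between metrics within a class (noise is independent per metric).
Passing the phantom tests therefore demonstrates that the pipeline's
machinery is correct and that the statistical logic recovers known structure;
it does not certify performance on real, artefact-laden MRI.

## Numerical and computational choices

* **Multi-start clustering.** Random-membership initialisation (seeded)
  starts every centroid near the global mean; a fraction of starts settle in
  merged/split local minima. `tc_fit()` and `select_cluster_number()`
  therefore run several cheap pilot fits on a seeded subsample (default 10
  and 6 starts respectively) and warm-start the final fit from the
  lowest-objective pilot. Everything is deterministic given `seed`.
* **Subsampling.** Pools at cohort scale reach millions of rows while the
  fuzzy c-means centroids are three-dimensional means — statistically stable
  from far fewer points. The final model fits on a seeded uniform subsample
  capped at 2e5 rows (the K-scan uses 3e4), classifies *all* pooled voxels
  from the fitted centroids, and stores a stratified subsample of at most
  1e4 labelled points per cluster as the KNN training set. Validity indices
  during the scan use at most 1e4 rows per test pool. These caps are
  package defaults chosen to keep a cohort fit in seconds-to-minutes at
  desk scale; all are arguments.
* **Test problem sizes.** The test suite exercises cohort-scale recovery on
  a 25-subject 48³-grid cohort (~44k brain voxels per subject) for model
  recovery and cluster-number selection, and a 25-subject 32³ cohort for
  rotation stability and the lesion/severity end-to-end analogue; unit tests
  use 24³ and smaller.
* **Degenerate inputs.** Empty masks, all-background label volumes,
  zero-variance metrics, coincident centroids (Davies–Bouldin) and empty
  clusters raise informative errors rather than propagating NaN. Values
  outside physical metric ranges are flagged and kept — clipping would
  silently bias cluster statistics. Fully collapsed clusters make the
  Calinski–Harabasz ratio diverge; the implementation returns `Inf`.
* **Tie-breaking.** Hard assignment breaks membership ties toward the lowest
  cluster index; KNN votes break toward the lowest ordered label; the KNN
  neighbour set keeps training order among equidistant points. All paths are
  deterministic.

## Known limitations

* The KNN classifier is a brute-force scan (Rcpp); it is linear in the
  stored training points, which is why the per-cluster cap matters. A tree
  index would help at much larger scales.
* Cluster-number selection encodes a specific aggregation (mean over test
  pools, rank-sum of two indices). Other defensible rules exist; the full
  score table is exposed for that reason.
* Severity scores assume the atlas classification is already on the
  subject's grid. Real use requires a registration step outside this
  package, whose errors will contaminate difference maps near boundaries —
  visible in practice as a nonzero opposite-change fraction.
* The −50 offset and ×1000 scale of the severity score are kept verbatim
  for cross-study comparability, not derived from any principle.
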