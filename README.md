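# qmriclass

Microstructural brain tissue classification from quantitative MRI.

Conventional segmentation splits the brain into white matter, grey matter and
CSF from the intensities of qualitative images. `qmriclass` instead classifies
tissue purely from voxelwise *quantitative* microstructural measures — the
myelin water fraction (MWF, a validated myelin proxy), the microscopic
fractional anisotropy (µFA, axonal integrity free of orientation dispersion)
and the normalised variance of sub-voxel mean diffusivities (C_MD, tissue
heterogeneity) — with no spatial information entering the model. The package
is aimed at quantitative-MRI researchers who want to (a) learn a healthy-brain
tissue taxonomy from a control cohort, (b) classify new individuals against
it, and (c) quantify diffuse white-matter damage (e.g. in multiple sclerosis)
as deviation from a healthy atlas classification.

## Method

For training subjects, all CSF-excluded brain voxels are pooled into one
N × 3 feature matrix of (MWF, µFA, C_MD) triples, standardised by a Gaussian
scaler, and clustered by fuzzy c-means, which minimises

    J_m = Σ_i Σ_k u_ik^m ‖x_i − c_k‖²,   Σ_k u_ik = 1,

with fuzzifier m = 2. The number of clusters K is chosen by fitting candidate
K on a training pool, classifying held-out test subjects, and ranking the
Calinski–Harabasz (higher-better) and Davies–Bouldin (lower-better) indices of
the test-side classifications; a rotating train/test scheme checks that the
clustering is stable across cohort splits. Clusters are reported in order of
descending mean MWF (cluster 1 = most myelinated). New subjects are classified
voxel-by-voxel with a k-nearest-neighbour rule (k = 5) over labelled training
points in the scaled feature space.

An *atlas of tissue classification* is obtained by classifying the voxelwise
average metric maps of the healthy cohort. An individual is compared with it
through a white-matter **difference map**: at voxels the atlas calls white
matter (clusters 1–3), the map records `subject − atlas` when positive (a
shift toward less-myelinated classes); opposite shifts are tallied separately
as a fraction of brain voxels. The **severity score** summarises diffuse
damage:

    S = (#{voxels with cluster difference 1} / total brain voxels) × 1000 − 50,

so a subject identical to the atlas scores exactly −50. Group statistics
(one-way ANOVA with Tukey HSD on normalised cluster sizes, Welch's t-test on
severity, Spearman correlations with clinical scores) and a PCA/correlation
report of the three metrics complete the pipeline. A synthetic phantom
generator produces co-registered cohorts with known class structure,
inter-subject variability and injectable lesions, so every stage is testable
without MRI data.

## Worked example

```r
library(qmriclass)

# a 25-subject healthy phantom cohort on a 32^3 grid
spec   <- phantom_spec(grid_shape = c(32, 32, 32))
cohort <- generate_cohort(spec, n_subjects = 25, seed = 303)

fit <- tc_fit(cohort$subjects, K = 6, seed = 303)
fit
#> Tissue classification model
#>   K = 6 clusters (ordered by descending mean MWF), m = 2 , knn_k = 5
#>   trained on 25 subject(s), 314200 pooled voxels
#>   KNN training set: 60000 labelled points

head(summary(fit), 3)
#> Per-cluster training-pool statistics (native units):
#>  cluster count mwf_mean  mwf_sd ufa_mean  ufa_sd cmd_mean  cmd_sd
#>        1 37486  0.14967 0.01102   0.9009 0.02082  0.04968 0.01553
#>        2 66957  0.11989 0.01065   0.8002 0.02250  0.11930 0.01561
#>        3 67757  0.08944 0.01070   0.7017 0.02167  0.07963 0.01549

# classify the healthy average and one lesioned individual
atlas        <- build_metric_atlas(cohort$subjects)
atlas_labels <- classify_atlas(fit, atlas)
ms  <- inject_lesions(cohort$subjects[[1]], cohort$truth, spec,
                      n_lesions = 4, radius_vox = c(2.4, 2.8), seed = 11)
cmp <- compare_subject(fit, atlas_labels, ms$subject)
cmp$severity
#> Severity score: -28.278
#>   higher-difference scores: d2=0, d3=0, d4=0, d5=0
#>   opposite-change fraction: 0.0007957
```

The severity score rises from −50 (no difference) as injected lesion volume
grows — here four lesions totalling ~2% of brain volume lift it to −28.3: the
lesions were drawn from the adjacent, less-myelinated class distribution and
are picked up as cluster-difference-1 voxels in atlas white matter. The per-cluster summary shows the learned taxonomy: cluster 1 is the
high-myelin, high-anisotropy, low-heterogeneity class, and mean MWF descends
with cluster number.

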