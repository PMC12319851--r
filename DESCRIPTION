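Package: qmriclass
Title: Microstructural Brain Tissue Classification from Quantitative MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised tissue classification of the brain from co-registered
    quantitative MRI maps (myelin water fraction, microscopic fractional
    anisotropy, and tissue heterogeneity). Voxelwise metric triples are pooled
    across healthy subjects, standardised, and clustered with fuzzy c-means;
    the cluster number is selected with Calinski-Harabasz and Davies-Bouldin
    indices under a rotating train/test scheme, and new subjects are classified
    with a k-nearest-neighbour model ordered by mean myelin water fraction.
    Individual classifications are compared against a healthy atlas
    classification through white-matter difference maps, opposite-change
    fractions, and severity scores, with group-level statistics and a
    synthetic phantom generator for end-to-end validation without MRI data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
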