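Package: htncds
Title: Hybrid Patient Stratification and Rule-Based Lifestyle
    Recommendations for Hypertension
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Clinical decision-support toolkit for non-pharmacological
    management of hypertensive patients. Implements a tabular cohort model
    with explicit missingness tracking, a calibrated synthetic-cohort
    generator with planted patient profiles, a preprocessing pipeline
    (record filtering, unit repair, plausibility flags, partial-distance
    KNN and mode imputation, one-hot encoding, z-score standardization),
    PCA-based dimensionality reduction with variance-threshold component
    retention, clustering over a K-means/HAC/GMM grid scored by internal
    validity indices (silhouette, Davies-Bouldin, Calinski-Harabasz), a
    declarative six-domain rule knowledge base, a dual-weighting inference
    engine that blends individual and cluster-level evidence, and an
    expert-agreement validation module (stratified sampling, majority
    consensus, Cohen's kappa with confidence interval, chi-square
    homogeneity tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    mclust,
    stats,
    utils,
    yaml
Suggests:
    cluster,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
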