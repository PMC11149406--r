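Package: clustype
Title: Person-Oriented Cluster Typologies with Quality Coefficients and
    Simulation-Based Validation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A repertoire of clustering methods for person-oriented
    typology research on rectangular case-by-variable score tables:
    agglomerative hierarchical clustering (eight Lance-Williams linkages),
    divisive hierarchical clustering (DIANA), k-center partitioning
    (k-means with three classic algorithms, PAM k-medoids, geometric-median
    k-medians), and model-based Gaussian-mixture clustering over the
    fourteen eigen-decomposition covariance families with BIC/ICL model
    selection.  Every solution is scored by a common quality-coefficient
    suite (per-cluster homogeneity coefficients, explained error sum of
    squares percentage, a modified Xie-Beni separation index, silhouette,
    homogeneity percentages) and can be validated against a
    correlation-matched multivariate-normal null via MORI relative
    improvement coefficients, optimal centroid matching, and cell matching
    ratios of cross-tabulated partitions.  Includes the Likert-item
    preprocessing pipeline (item truncation, scale construction with
    missing-item rules, nearest-neighbour outlier screening, alpha and
    omega reliability) and a seeded synthetic typology generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, cluster, mclust, jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
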