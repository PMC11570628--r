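Package: twinphen
Title: Deep Metric Learning for Behavioral Phenotypic Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for phenotypic profiling of high-replicate behavioral
    screens in larval zebrafish and similar plate-based assays. Computes
    motion-index traces from grayscale frame stacks, trains twin (Siamese)
    neural networks with a contrastive loss to learn a phenotypic distance
    between behavioral time series, and compares the learned distance with
    correlation, Euclidean and dynamic-time-warping baselines. Includes a
    random-forest activity filter, drug-wise pair construction with control
    and toxicity quotas, a shortcut-learning diagnostic battery (smoothing
    ablation, label shuffling, input randomization, well-distance controls),
    replicate-identification and phenosearch library-ranking analyses,
    Tanimoto-based scaffold-hopping quadrant analysis, and a seeded synthetic
    screen simulator with fixed or randomized plate layouts and an optional
    planted well-position artifact.
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    randomForest,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    png,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
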