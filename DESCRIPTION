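Package: stcourse
Title: Feature-Based Analysis of Short Time-Course Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of sparse, irregularly sampled gene expression time
    courses using curve-summary features. Profiles measured at few time
    points are summarised by biologically interpretable features (signed
    area under the curve, slopes, extrema and their timing), which are then
    screened for differential expression between treatments with
    parametric, rank-based and permutation tests, optionally after
    small-sample outlier removal (mean-median discrepancy or Dixon's Q).
    Multiplicity is handled by Bonferroni, Benjamini-Hochberg, and an
    estimate of the number of true null hypotheses (m0) obtained from the
    p-value plot or the CDF of p-values, which sharpens the false discovery
    rate; operating characteristics (sensitivity, specificity, FDR) are
    tabulated over significance thresholds. Probes can be clustered in
    standardized feature space with k-means or partitioning around medoids
    under Euclidean or Manhattan distance, with silhouette, homogeneity and
    separation diagnostics and silhouette-based selection of the number of
    clusters. Includes a synthetic-data generator in the supported input
    formats and a command-line workbench wiring the steps into a pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    jsonlite
Config/testthat/edition: 3
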