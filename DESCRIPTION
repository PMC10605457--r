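Package: ctflow
Title: Normalization, Group Comparison and Differential Correlation for
    Large-Scale qPCR Ct Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A headless analysis engine for high-throughput (bulk or
    single-cell) qPCR experiments recorded as cycle-threshold (Ct) values.
    Reads wide or long Ct tables (CSV/TSV/XLSX) with per-sample group
    labels and optional categorical metadata, collapses technical
    replicates by geometric mean, scores candidate housekeeping genes
    (singly and in pairs) with a model-based NormFinder-type stability
    value restricted to grouped samples, normalizes target genes to
    -deltaCt by the Livak method, compares groups with
    distribution-routed Mann-Whitney or Student t tests, screens all
    genes in volcano tables with Benjamini-Hochberg adjustment, and maps
    differentially correlated gene pairs through the dR-val statistic
    (absolute difference of significance-gated per-group correlation
    coefficients). Includes a seeded synthetic-data generator with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    readxl,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    png
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: GeneExpression, Normalization, qPCR, DifferentialExpression,
    SingleCell
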