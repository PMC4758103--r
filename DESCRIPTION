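Package: cellqc
Title: Machine-Learning Quality Control for Single-Cell RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies low quality cells (broken cells, empty capture sites,
    multiples, and visually "deceptive" damaged cells) in single-cell RNA-seq
    experiments from the expression data alone. Curated biological features
    (proportions of reads in Gene Ontology derived gene sets such as cytoplasm,
    mitochondrially encoded genes, and mitochondrially localized proteins) and
    technical features (read-mapping proportions, spike-in ratios, expression
    shape summaries, distance-to-median noise) are extracted per cell,
    characterized with paired t-tests on mean expression and noise, reduced to
    a cell-type-independent subset by a principal-component loading-quartile
    rule, screened by robust Mahalanobis outlier detection, and classified by a
    majority-vote ensemble of radial-kernel support vector machines tuned by
    F-beta-driven nested cross-validation. A count transform for UMI data and a
    synthetic-cell generator for end-to-end testing are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    MASS,
    e1071,
    withr,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'cellqc-package.R'
    'cli.R'
    'dm.R'
    'features.R'
    'io-counts.R'
    'io-features.R'
    'io-genesets.R'
    'io-labels.R'
    'io-stats.R'
    'normalize.R'
    'outliers.R'
    'quality-stats.R'
    'selection.R'
    'simulate.R'
    'svm.R'
    'umi.R'
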