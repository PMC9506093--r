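Package: coexpair
Title: Cell-Type-Resolved Co-Expression of Interacting Gene Pairs
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to test whether genes encoding interacting (membrane)
    proteins are co-expressed at the cell-type level in droplet single-cell
    or single-nucleus RNA-seq data. Provides readers for 10x-style sparse
    UMI matrices and companion tables, percentile-based barcode QC, library
    size normalization, per-cluster average-expression profiles and dot-plot
    statistics, marker-based cluster annotation with barcode-majority label
    transfer, a minimum-expression co-expression filter with per-cluster
    Pearson correlation over gene pairs, a random-gene-pair null model, and
    a negative-binomial simulator of clustered UMI counts with planted
    pair co-expression for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
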