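Package: ubiscore
Title: Configurable Ubiquity Scoring of Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies how ubiquitously genes are expressed from gene-by-sample
    expression matrices. Combines expression breadth, level and variability into
    a configurable composite score; classifies genes into cross-dataset ubiquity
    sectors; assesses weight sensitivity of the resulting rankings; summarizes
    drug influence on ubiquitous versus non-ubiquitous genes; and performs
    sliding-bucket over-representation analysis along a ranking. Includes GeTMM
    normalization of raw read counts, readers and writers for GCT and tabular
    formats, a synthetic-data generator with planted gene classes, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
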