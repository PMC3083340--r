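Package: tfsarray
Title: Treatment-Interaction Classification for Two-Color Dye-Swap Microarrays
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for dual-treatment competitive two-color
    microarray experiments with dye-swap replication. Provides a synthetic
    experiment generator with known per-gene interaction structure,
    feature-quality filtering, within-array LOWESS normalization of
    intensity-dependent dye bias, error-weighted replicate combination with
    an intensity-dependent variance model, total-flag-sum (TFS)
    classification of genes into treatment-interaction classes, expected
    false-positive and apparent-FDR arithmetic, and Fisher's exact test
    gene-set enrichment (GO, transcription-factor motif and miRNA target
    collections in GMT format) per TFS group with hierarchical clustering
    of the resulting significance matrix.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
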