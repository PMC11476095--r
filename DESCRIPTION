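Package: biofilmq
Title: Microplate Biofilm Assay Analysis with Crystal Violet and Resazurin
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for 96-well crystal-violet biofilm assays with
    resazurin viability correction. Reads long-format plate-reader exports,
    computes sterility-based cutoffs (ODc) and the four-class producer
    classification (non/weak/moderate/strong), applies the AR570 resazurin
    correction with per-plate Ro factors, derives biofilm-per-viable-cell
    indices, compares timepoints with a permutation rank-product test, and
    summarises producer phenotypes by principal component analysis and a
    UPGMA dendrogram exportable as Newick. Includes a synthetic plate
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
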