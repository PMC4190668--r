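Package: gelminer
Title: Mining Gel-Electrophoresis Diagrams from Biomedical Figure Images
Version: 0.1.0
Authors@R: person("gelminer", "developers", role = c("aut", "cre"),
    email = "gelminer@example.org")
Description: Detects gel-electrophoresis segments in biomedical figure
    images with a 39-feature random-forest classifier read at calibrated
    high-precision and high-recall operating points, assembles the
    detected segments into gel panels with rule-based adjacency grouping
    (50 px, no intervening text), attributes nearby text labels (30/150 px
    edge-distance rules), and recognizes gene and protein symbols in those
    labels by case-sensitive lexicon lookup with exclusion filters.
    Includes a seeded synthetic-figure generator with exact ground truth
    so the whole pipeline is trainable and testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
SystemRequirements: zlib
Config/testthat/edition: 3
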