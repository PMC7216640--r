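Package: triadbias
Title: Homeolog Expression Bias Analysis for Allopolyploid Triads
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing subgenome expression partitioning in
    allohexaploid wheat and other allopolyploids. Computes per-triad
    relative expression values (the share of each A, B and D homeolog in
    the triad total), classifies each triad into one of seven homeolog
    expression bias categories by nearest-centroid assignment in ternary
    (barycentric) space, and calls stress-induced shifts in relative
    homeolog expression. Includes a differential-expression filter and
    hypergeometric gene-set enrichment, small biochemical utilities
    (solute percent contribution, delta-delta-Ct relative expression),
    and a negative-binomial synthetic-data generator with known ground
    truth for validating every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
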