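Package: coexmod
Title: Signed Weighted Co-Expression Networks, Module Detection and
    Cross-Network Module Preservation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building signed weighted gene co-expression networks
    from multi-region expression data and characterising their modules:
    soft-threshold selection by scale-free topology fit, topological overlap,
    dendrogram-based module detection with eigengene merging, module
    membership (kME) and hub/core-gene analysis, cross-tabulation module
    overlap with exact tests, permutation-based composite Zsummary module
    preservation, gene-set over-representation statistics, TOM-threshold
    neighbourhood extraction, and regional expression profiling. Includes a
    synthetic multi-region data generator with planted latent-factor modules
    so every stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
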