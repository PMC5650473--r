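Package: primmus
Title: Cell-Cycle Proteomics of FACS-Sorted Cell Subsets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative analysis of cell-cycle and intra-mitotic
    proteomics from FACS-sorted, immunostained cell subpopulations
    (the PRIMMUS approach). Converts flow-cytometry phase frequencies
    into ergodic cell-cycle positions, models exponential protein
    accumulation against an asynchronous SILAC internal standard,
    normalizes SILAC ratios and TMT reporter intensities (isotope
    impurity correction, sum normalization), screens for proteins
    degraded during mitotic progression with a max-fold-change
    Z-score cutoff plus replicate agreement, clusters abundance and
    phosphorylation-site dynamics (trough-phase agglomeration,
    "early riser" classification, CDK motif and residue statistics),
    and ships a synthetic-data generator that emulates sorted-fraction
    measurements so the whole workflow runs without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
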