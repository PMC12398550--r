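Package: oligomatch
Title: Cell-Identity Transfer, Species Demultiplexing and Myelin
    Morphometry for Stem-Cell-Derived Oligodendroglia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to judge the fidelity of stem-cell-derived
    oligodendroglia against adult reference atlases and to quantify
    treatment effects. Implements species demultiplexing of chimera
    single-cell count matrices, an ensemble of binarized-expression
    neural-network classifiers for cross-dataset cell-identity transfer
    with plurality voting, cosine-similarity cluster matching, a two-part
    hurdle differential-expression test with detection-rate and fold-change
    filters, electron-microscopy morphometry (g-ratios, myelinated-axon
    percentages, mitochondrial area fractions) and in situ hybridisation
    composite scores. Ships a synthetic-data generator with known ground
    truth for every pipeline input, plus standard single-cell
    preprocessing (QC, size-factor normalisation, variable features, PCA,
    KNN-graph Louvain clustering).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    nortest,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
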