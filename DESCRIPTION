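Package: salnet
Title: Time-Varying Brain-Network Centrality and Visual Saliency Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Links time-varying network centralities of parcellated fMRI
    time series to a bottom-up visual-saliency signal extracted from movie
    stimuli. Builds binary undirected functional-connectivity networks by
    proportional thresholding of parcel-wise correlation matrices (edge
    density selected by the mean flow coefficient), computes static and
    sliding-window eigenvector centrality and participation coefficient
    (with Louvain community detection), derives a per-TR mean visual
    saliency signal from an Itti-Koch saliency model with 0.1 Hz low-pass
    filtering, and performs Fisher-z group statistics with Bonferroni
    family-wise error control. A synthetic-data module generates cohorts
    with known modular structure and known saliency-coupled dynamics, plus
    synthetic movie frames, so every stage is verifiable without external
    neuroimaging data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    signal,
    png,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
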