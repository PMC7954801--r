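Package: convGRN
Title: Core Gene Regulatory Network Reconstruction and Prioritization of
    Instructive Factors for Cellular Conversion
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Reconstructs cell-type-specific core gene regulatory networks by
    integrating expression specificity (Jensen-Shannon divergence against a
    background compendium), histone-mark and chromatin-accessibility peaks,
    transcription-factor binding events and protein-protein interactions;
    infers Boolean cooperativity logic per regulatory region; and ranks
    combinations of instructive transcription factors for cellular conversion
    with a Markov-chain surrogate of conversion efficiency combining a
    transcriptional reachability score with an epigenetic remodeling score.
    Includes a seeded synthetic-fixture generator with planted ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: NetworkInference, GeneRegulation, Epigenetics, Transcriptomics,
    SystemsBiology
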