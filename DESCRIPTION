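Package: mircircuits
Title: Discovery of miRNA Regulatory Circuits from Multi-Omic Retina Data
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for discovering miRNA regulatory circuits
    by integrating in silico miRNA target-site predictions, a retinal
    transcriptome expression atlas, label-free proteomics differential
    abundance, hypergeometric pathway over-representation, miR-CATCH
    (miRNA capture affinity) qPCR enrichment analytics, and protein
    interactome overlay. Consensus target sites are called by requiring
    positional overlap of predictions from at least two tools on the same
    transcript; candidate miRNA-target pairs are identified under an
    inverse-expression rule between miRNA fold-changes and protein
    abundance changes. A synthetic-data generator with recorded planted
    truths allows every stage to be exercised and validated without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: Proteomics, GeneRegulation, NetworkEnrichment, Transcriptomics
RoxygenNote: 7.3.3
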