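Package: syntelnc
Title: Cross-Species Inference of Long Non-Coding RNAs from Conserved Synteny
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building a cross-species catalogue of long non-coding
    RNAs (lncRNAs) from de novo assembled transcript models. Candidate models
    are filtered by length, overlap with protein-coding annotation and
    coding-potential evidence; conserved gene-order (synteny) blocks of three
    consecutive genes are detected between genome pairs; lncRNAs captured in
    one species are inferred in the other by Needleman-Wunsch global alignment
    into the corresponding intergenic interval, accepting alignments that
    contain a gapless run of at least 20 identical residues. Expression is
    characterised with tissue-specificity statistics (tau, preferential
    expression measure, Human Protein Atlas style categories), thresholded
    Pearson co-expression graphs partitioned by Markov clustering, and
    genomic-distance randomisation tests for enhancer-like lncRNA/mRNA pairs.
    A synthetic-data generator with known ground truth (planted orthologues at
    controlled divergence, planted expression programmes, per-library transcript
    dropout) supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
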