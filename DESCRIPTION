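Package: mama
Title: Clustering-Free Cis-Regulatory Motif Discovery from Expression-Weighted k-mer Scores
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Discovers candidate cis-regulatory elements in promoter sequences
    without clustering genes. Every 8-bp candidate drawn from the promoters of
    the most strongly up-regulated genes is scored by a similarity-weighted
    average of capped expression ratios (the MAMA score); high-scoring
    candidates are grouped into motifs by Hamming distance, characterized by
    their positional distribution around the transcription start site and by
    pairwise co-localization statistics (chi-square, conditional enrichments,
    separation histograms), and the resulting motif and motif-pair presence
    features are validated by simulating gene up-regulation with a
    radial-basis-kernel margin classifier evaluated by AUC-ROC. Includes a
    synthetic promoter generator with planted motifs so the whole pipeline is
    testable without external genomes or microarrays, and sequential
    hyperparameter optimization of the score powers and the number of motif
    pairs.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
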