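Package: dbdlink
Title: Domain-Aware Linking of DNA-Binding Motifs to Transcription Factors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
                  email = "author@example.org")
Description: Scores how likely a candidate DNA-binding motif and a
    transcription factor share a DNA-binding domain (DBD). Builds a DBD
    collection by clustering database motifs within each DBD family under an
    exact overlap-hit similarity statistic (S^max), normalizes the maximal
    similarity into a domain score, converts scores to Monte-Carlo empirical
    p-values against randomly sampled position frequency matrices, and
    improves any motif-enrichment ranking either by Fisher meta-analysis of
    p-values or by filtering candidates whose domain-score p-value is not
    significant. Includes cluster-aware precision-recall evaluation, synthetic
    fixture generators, motif file IO (JASPAR, TRANSFAC, MEME), peak-centered
    sequence extraction, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
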