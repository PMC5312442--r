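Package: orthomapr
Title: Reciprocal Best-Hit Assignment of Transcripts to Ortholog Groups
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Maps coding nucleotide sequences (assembled transcripts) to
    known clusters of orthologous genes using a globally sorted
    best-reciprocal-hit strategy: per-group profile hidden Markov models
    are searched against six-frame translations of the transcript library,
    candidate regions are re-searched against the full reference protein
    database with Smith-Waterman local alignment, and candidates are
    accepted in order of descending forward bit score under a region
    ledger that guarantees non-redundant assignment. Accepted transcripts
    are post-processed into frameshift-corrected open reading frames with
    exactly corresponding amino-acid and nucleotide sequences, suitable
    for phylogenomic matrix construction. Includes a synthetic fixture
    generator with planted orthologs, inparalogs, isoforms and frameshift
    errors for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
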