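Package: famscan
Title: Profile Hidden Markov Model Mining of Protein Families in
    (Meta)genomic Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds profile hidden Markov models of protein families from
    multiple sequence alignments, screens six-frame-translated nucleotide
    assemblies for significant matches with forward/Viterbi scoring and
    Gumbel-calibrated E-values, and summarises hits per sample as
    hits-per-megabase densities with rank-sum and Welch comparisons across
    body sites.  Includes control-set validation (sensitivity/specificity
    against producer and non-producer strains) and a synthetic-data
    generator (families, decoys, and contigs with implanted coding loci)
    so every stage is testable with known ground truth.
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
    jsonlite
Config/testthat/edition: 3
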