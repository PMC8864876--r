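Package: hifiscrub
Title: Adapter Contamination Screening and Filtering for PacBio HiFi Reads
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects residual PacBio SMRTbell blunt-adapter and C2
    sequencing-primer sequence inside HiFi/CCS reads using a strict
    VecScreen-style local aligner (match +1, mismatch -5, affine gaps), and
    removes contaminated reads whole rather than trimming them. Classifies
    contamination by position within the read (5', internal, 3',
    distributed), summarizes dataset-level contamination statistics, and
    applies the same detector to assembled contigs. Includes a spike-in
    simulator that generates HiFi-like read pools with adapters inserted at
    known positions, orientations and rates, so detection recall and
    specificity can be evaluated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rsamtools,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
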