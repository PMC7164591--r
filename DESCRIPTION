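Package: viromarker
Title: Marker-Virus Detection and Archaeal Host Prediction in Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects a marker virus across shotgun metagenome samples and predicts its
    prokaryotic host from three independent sequence signals. Provides direct terminal
    repeat (circularity) detection for assembled viral contigs, a seed-and-extend read
    mapper with duplicate removal for library-size-normalised abundance and breadth of
    coverage, presence calling with explicit thresholds, CRISPR spacer (protospacer)
    matching with a Hamming mismatch budget, tetranucleotide frequency correlation with a
    shuffled-sequence null, binary co-occurrence (phi) analysis against a pollution label,
    and a synthetic study generator that emulates multi-sample paired-end libraries with a
    planted virus-host relationship for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    S4Vectors,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
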