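Package: ipedr
Title: Machine-Learning Denoising of Illumina MiSeq Paired-End Amplicon Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Denoising of Illumina MiSeq paired-end 16S rRNA gene amplicon
    sequencing data. Paired reads are merged into contigs with per-position
    provenance, a plurality-voting ensemble (multilayer perceptron plus random
    forest) predicts potentially erroneous positions from quality and context
    features, and an abundance-sorted single-linkage preclustering step merges
    error-containing reads into correct ones while masked positions do not
    contribute to the distance. Includes a mock-community read simulator with
    a MiSeq-like error profile and seq.error-style error-rate evaluation
    against reference sequences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    tibble,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    yaml,
    Biostrings,
    S4Vectors,
    ranger,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
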