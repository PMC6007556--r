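Package: kmerlink
Title: Alignment-Free Read-Pair Linking and Scaffolding-Graph Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
                  email = "author@example.org")
Description: Builds a fingerprint-verified dictionary of the k-mers occurring
    exactly once in a set of contigs and uses it to place read pairs without
    base-level alignment: k-mer hits are window-scored per read, weak mates
    are rescued under library distance and orientation constraints, and
    placements are emitted as SAM. Synthetic mate-pair libraries at chosen
    insert sizes can be cut from long reads, library insert parameters are
    estimated by trimmed statistics with a majority-rule orientation, and
    cross-contig pairs are assembled into a scaffolding graph whose joins
    can be scored against a known true layout (bit-wise error flags, recall,
    precision, F-score). A seeded simulator supplies genomes with planted
    repeats, fragmented contigs, Illumina-like mate-pairs and long reads
    with technology-flavoured error profiles, so the whole pipeline runs on
    synthetic data with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    withr,
    jsonlite,
    yaml,
    readr,
    Biostrings,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Rsamtools
Config/testthat/edition: 3
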