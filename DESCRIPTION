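Package: mirsite
Title: MiRNA Binding-Site Prediction, Cluster Compaction and Association
    Analysis for mRNA Targets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts miRNA binding sites in mRNAs by scoring gapless
    antiparallel miRNA:mRNA duplexes with a hydrogen-bond-weighted free
    energy (G-C, A-U, G-U and A-C pairs contributing 3, 2, 1 and 1 bonds),
    retains sites whose free energy reaches a configurable fraction of the
    perfect-complement reference energy, and localizes them in the 5'UTR,
    CDS or 3'UTR of each transcript. Overlapping sites are organized into
    clusters with span, summed site length and compaction statistics.
    Also provides miRNA-gene association tables, an occupancy model of
    translational suppression from miRNA:mRNA concentration ratios,
    expression-weighted competition ranking, ortholog conservation
    comparison of cluster regions, and a synthetic-data generator with
    planted sites for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
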