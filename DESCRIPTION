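Package: seedbin
Title: Two-Phase Composition-Based Binning of Metagenomic Reads
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Unsupervised binning of metagenomic sequencing reads into
    species-level clusters. Phase one links reads that share at least m
    q-mers into an overlap graph and partitions it greedily into groups,
    each carrying a seed of mutually non-overlapping reads capped at
    S_max base pairs. Phase two summarises every seed by its normalized,
    reverse-complement-collapsed l-mer frequency vector (136 entries for
    l = 4) and merges the groups with Lloyd k-means on these genomic
    signatures. Includes the matching precision, recall and F-measure
    evaluation metrics and a Markov-chain community simulator with
    recorded ground truth, so the whole pipeline is testable at desk
    scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
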