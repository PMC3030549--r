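Package: fluidity
Title: Genomic Fluidity and Gene-Family Diversity of Genome Groups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates genomic fluidity, a pairwise gene-level dissimilarity
    statistic for groups of genomes, together with its jackknife variance and
    a two-sample z-test for comparing groups. Includes the supporting
    pipeline: strict-clique gene-family clustering from all-vs-all protein
    alignment tables with identity and coverage thresholds, threshold sweeps
    with rank-ordering summaries, pan/core rarefaction curves and gene
    frequency spectra, and a calibrated synthetic population simulator that
    demonstrates why pan and core genome sizes cannot be estimated from
    sampled genomes while fluidity can.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    Biostrings
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
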