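Package: sinetails
Title: Classification and Evolutionary Analysis of SINE 3' Tail Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Post-processing of RepeatMasker annotations of Short Interspersed
    Nuclear Elements (SINEs): locates the body-to-tail boundary of each element
    by hierarchical cutoff-motif matching (exact, then single-mismatch, with a
    terminal 30-bp fallback), classifies the extracted 3' tails into sixteen
    structural categories (A-rich, AT-/AC-/AG-series microsatellite repeats and
    composites) plus "Other", dates insertions with the Jukes-Cantor correction
    and a neutral molecular clock, summarises tails against chromosomes and gene
    features, calls tail polymorphisms across genome assemblies through
    PAF-based coordinate lifting and pairwise global alignment, and reports
    coding-sequence consequences (frameshifts, altered proteins) of tail
    insertions. Ships a seeded synthetic-fixture generator that plants SINE
    copies of known subfamily, divergence, strand and tail category so the whole
    pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    methods,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
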