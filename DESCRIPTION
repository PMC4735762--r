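Package: spliceselect
Title: Comparative Splice-Signal Analysis of Cassette Exon Skipping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for explaining cassette-exon skipping from comparative
    splice-signal architecture: donor-site position weight matrix (PWM)
    construction and scoring, branchpoint (YURAY) motif detection with
    distance-to-3'-end optimality, Shannon-entropy conservation profiling of
    protein alignments, exon/intron length summaries, a +6-site exon-skipping
    predictor, exact junction-spanning isoform-evidence counting with PSI and
    Wilson intervals, and peptide composition/charge profiling of the skipped
    exon. Includes a seeded synthetic-data generator (gene models with planted
    donor sites and branchpoints, junction-spanning reads) so every stage has
    a ground-truth test surface, and a pipeline driver composing the stages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    stringr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
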