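Package: groupreadr
Title: Emotional and Semantic Profiling of Reading-Group Discussion Transcripts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of shared-reading (group bibliotherapy)
    discussion transcripts and the literary texts discussed. Scores documents
    on the valence-arousal-dominance (VAD) dimensional model of emotion using
    word-norm lexicons, computes decile word tiers per emotion dimension,
    embeds discussions and texts with a deterministic in-package paragraph
    vector (PV-DBOW) model to measure text-discussion semantic similarity,
    and provides the session-level correlation and between-group comparison
    statistics built on top. Includes a seeded synthetic-corpus generator
    with known ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    generics,
    stats,
    tools,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
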