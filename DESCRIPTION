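Package: neoms
Title: Microstate Analysis of Neonatal Sleep EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete, testable pipeline for EEG microstate analysis of
    neonatal sleep recordings. Reads multichannel EEG epochs (EDF or a plain
    text matrix dialect), applies zero-phase Butterworth band-pass filtering,
    resampling and common-average re-referencing, extracts dominant microstate
    templates with a two-step polarity-invariant modified k-means on global
    field power (GFP) peak topographies, selects the number of templates with
    the Krzanowski-Lai criterion, backfits templates to obtain microstate
    sequences and their metrics (duration, occurrence, coverage, global
    explained variance), tests microstate syntax (observed versus expected
    transition probabilities, chi-square distance with a randomization test,
    directional predominance), compares topographies (global dissimilarity,
    TANOVA permutation test), repeats the pipeline in narrow frequency bands
    with log-log scaling fits, and provides the study's inferential layer
    (repeated-measures ANOVA with Greenhouse-Geisser correction, Bonferroni
    and FDR-corrected post-hoc tests). A seeded synthetic-cohort generator
    with planted templates, Markov syntax and 1/f background noise makes
    every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    dplyr,
    tidyr,
    tibble,
    ggplot2,
    generics,
    rlang,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
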