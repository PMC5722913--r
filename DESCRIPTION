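Package: elongrate
Title: Genome-Wide Inference of Transcription Elongation Rates from
    Steady-State Expression, RNAP Occupancy and mRNA Half-Life Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-based inference of per-gene RNA polymerase elongation
    rates (transcription speeds) in bacteria from three steady-state
    observables: mRNA level, RNAP occupancy density and mRNA half-life.
    Includes tiling-array style normalization (quantile normalization,
    strand-max selection, median scaling, running-quantile background
    subtraction, probe-to-gene aggregation), reference-gene speed scaling,
    operon regulation delays, molecule-census scale validation, a
    clearance-lag grid optimizer and stationarity-robustness checks for
    the promoter-activity model, a feature-association battery (codon
    usage, GC by codon position, wobble pairing, rank correlations,
    group tests with Benjamini-Hochberg adjustment), random-forest speed
    estimation without half-life data, and a synthetic-data generator
    with known ground truth so every stage is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    limma,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
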