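Package: breakome
Title: Single-Strand DNA Break Hotspots and Promoter Enrichment Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing genome-wide maps of single-strand DNA breaks
    (SSBs) called at single-nucleotide resolution. Identifies recurrent break
    positions (hotspots) across biological replicas and tests them against a
    Monte-Carlo null, assigns expressed genes an operative transcription start
    site from CAGE tags, computes strand-aware, repeat-normalised break density
    profiles and enrichment ratios around TSSs, hierarchically associates breaks
    with genomic elements via odds ratios, relates promoter-proximal breaks to
    gene expression rank, and summarises break sequence context including
    cytosine preference. Ships a synthetic-data generator that emulates the
    structure of real breakome studies so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
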