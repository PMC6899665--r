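Package: dietmerge
Title: Multi-Marker DNA Metabarcoding Diet Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for dietary DNA metabarcoding of trophic generalists with
    several taxonomically overlapping markers. Implements a per-marker exact
    sequence variant (ESV) filtering cascade (fragment-length windows, one-off
    denoising, PCR-failure and per-PCR relative-abundance filters), most
    inclusive rank (lowest common ancestor) taxonomic assignment, identity
    threshold MOTU clustering, and a per-sample algorithm that merges
    detections from multiple markers into a single non-redundant, maximally
    resolved taxa list. Also provides the dietary descriptors commonly used to
    compare detection methods: frequency of occurrence, per-sample richness,
    taxonomic resolution profiles, and Czekanowski's niche overlap index,
    together with a deterministic simulator of multi-marker detection data and
    ESV tables for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    utils,
    stats,
    yaml
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
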