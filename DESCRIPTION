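Package: wgmm
Title: Whole-Genome DNA Marker Maps from Genetic Maps and Reference Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds whole-genome DNA marker maps (WGMMs) by placing
    sequence-tagged markers (RFLP probes and SSR primer pairs) on a
    reference genome assembly, assembling alignment hits into marker
    loci, anchoring loci to a genetic map by colinearity with
    centiMorgan interpolation, and deriving downstream summaries:
    marker density and coverage statistics, inversion and translocation
    calls from genetic-versus-physical comparisons, resistance gene
    analog (RGA) clusters from protein domain architectures, and
    projection of quantitative trait loci (QTL) onto physical intervals
    with multi-trait hotspot detection. Includes a synthetic-data
    generator that emits a toy genome with planted marker copies,
    rearrangements, RGA clusters and QTL hotspots with a known truth
    table, so every pipeline stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    GenomicRanges,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
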