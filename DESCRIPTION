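Package: h1scape
Title: Genome-Wide Occupancy Analysis of Linker Histone H1 Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for mapping linker histone H1 variant occupancy from
    ChIP-seq read positions: input-subtracted binned signal tracks,
    expression-stratified TSS and metagene average profiles with LOESS
    smoothing, SICER-style enriched/depleted island calling with
    nearest-gene and genomic-feature annotation, and domain-scale
    statistics (per-chromosome gene-richness coefficient and occupancy
    clustering, lamina-associated-domain and CpG-island enrichment against
    a random-window Kolmogorov-Smirnov null, GC-content correlation, and
    distal-promoter ranking with top/bottom decile overlap analysis).
    Includes a synthetic-genome read simulator with tunable GC coupling,
    LAD enrichment, expression-dependent TSS valleys and a +1-nucleosome
    peak, so that every stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
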