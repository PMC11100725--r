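Package: secom
Title: Single-Cell Super-Enhancer Contact and Community Analysis
Version: 0.1.0
Authors@R:
    person("SE", "Interactome Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Analysis of multiplexed DNA-FISH (chromatin tracing) spot tables
    covering the super-enhancer (SE) complement of mouse embryonic stem
    cells. Provides readers and writers for SE locus tables and per-cell 3D
    spot tables (FOF-CT-style and flat TSV), point-level registration
    (chromatic-aberration polynomial correction, allele assignment,
    detection-efficiency and replicate-error quantification), per-cell
    distance maps with contact (200 nm) and community (600 nm) calling,
    partner-distribution entropy, triplet cooperativity, odds-ratio
    statistics, nascent-transcription burst coupling, per-SE genomic and
    epigenomic feature extraction from track files, a shallow-network
    regressor of community size with feature ablation, and a calibrated
    synthetic-data generator (uniform-sphere null, chromosome-territory
    model, detection dropout, localization noise, burst model) so that every
    stage is testable without the imaging dataset.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
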