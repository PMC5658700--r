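Package: promoterstates
Title: Promoter State Classification and Polycomb-RNAPII Dynamics Across
    Neuronal Differentiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies gene promoters into RNA polymerase II / Polycomb
    occupancy states (Active, Inactive, PRC Only, PRC/S5p, PRC/Active and the
    rarer single-mark states) from ChIP-seq enriched regions and TSS-window
    read counts across a five-point differentiation time course, tracks
    Polycomb trajectory groups (Maintained, Lost, Acquired) and the fates of
    poised PRC/S5p promoters, and relates promoter states to expression
    dynamics, Polycomb-knockout derepression, CpG-island and DNA-methylation
    features (hypomethylated-region clustering into methylation valleys), and
    transcription-factor influence ranks via hypergeometric tests and a
    preranked gene-set enrichment statistic with a permutation null. A
    synthetic multi-omics generator with planted ground truth makes every
    stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr
Config/testthat/edition: 3
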