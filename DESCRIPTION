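Package: epireprog
Title: Accelerated Epigenomic Aging Classification and Hybrid Multi-Omic
    Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative analysis of longitudinal histone-mark ChIP-seq,
    transcriptomic and metabolomic data after an early-life chemical
    exposure. Maps differential histone-mark regions to genes (TSS window)
    and enhancers, classifies each feature into reprogramming classes
    (Precocious, EDC-specific, Cumulative and related Venn strata) from its
    membership across age and exposure contrasts, computes odds-ratio
    enrichment of differential regions within chromatin-state
    segmentations, performs KNN imputation, log2 day-median normalization,
    per-feature Welch t-tests with BH FDR, z-score recurrence selection of
    metabolites, and hybrid gene+metabolite hypergeometric pathway
    enrichment (MetSEA). Includes a fully deterministic synthetic-data
    generator with planted ground truth and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
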