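Package: cnconcord
Title: Cross-Laboratory Concordance of Segmented Copy-Number, LOH and
    Somatic-Mutation Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reproducibility statistics for replicate molecular tumour
    profiles run across laboratories. Computes length-weighted genome-wide
    copy-number-call and loss-of-heterozygosity agreement on the common
    refinement of replicate segmentations, run-level quality-control
    statistics (MAPD computation, bounds classification, one-way ANOVA with
    pairwise follow-up, within- versus between-sample variance
    decomposition), three-tier somatic-mutation call classification with
    sensitivity against orthogonal validation, clinically oriented event
    scans (high focal amplification, copy-neutral LOH, mutation
    co-occurrence, cohort recurrence), and a synthetic triplicate generator
    with known truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
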