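Package: mosaicsnv
Title: Multi-Tissue Somatic SNV Filtering, Validation and Spectrum Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection of somatic single-nucleotide variants (mosaic sSNVs)
    from unpaired multi-tissue sequencing data. Annotates candidate calls
    with read-level evidence, applies a battery of per-site statistical
    filters (germline binomial test, exact strand Poisson test, position-in-
    reads bias score, clipping/mapping-quality/mismatch imbalances), supports
    single-sample and combined multi-tissue filtering, a beta-binomial
    panel-of-normals recurrence test, amplicon ultra-deep-sequencing
    validation decision rules, and 96-context trinucleotide mutational
    spectrum analysis with signature correlation. Includes a synthetic-cohort
    simulator so every component is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    GenomicRanges,
    IRanges,
    Biostrings,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
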