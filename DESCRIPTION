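Package: methdose
Title: Dose-Response EWAS and Differentially Methylated Region Analysis
    for RRBS Methylation Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for exposure-dose epigenome-wide association analysis of
    reduced representation bisulfite sequencing (RRBS) CpG methylation
    counts. Reads Bismark-coverage-style count files and sample sheets into
    a SummarizedExperiment-derived container, applies coverage and
    sample-count quality filters, estimates per-sample methylation levels
    with an optional kernel-weighted local smoother, regresses each CpG's
    methylation on a continuous exposure (years of contact-sports play)
    with covariate adjustment, calls differentially methylated regions by a
    length / significant-site-count / significant-fraction rule with an
    exhaustive brute-force verification oracle, annotates sites and regions
    by genomic and CpG-island context, and produces cohort descriptive
    tables. A beta-binomial simulator with known per-site effects makes
    every stage testable without restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
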