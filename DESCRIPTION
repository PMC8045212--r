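Package: cnvcohort
Title: Copy-Number Variant Calling, Regional Mapping and Case-Control
    Association for aCGH Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for cohort-scale copy-number variation
    (CNV) analysis from array comparative genomic hybridisation (aCGH)
    log2-ratio tracks. Calls per-sample gains and losses with a
    thresholded run-length rule (minimum consecutive-probe support),
    merges calls across samples into copy-number-variable regions (CNVRs)
    with trend classification and genome-coverage summaries, annotates
    regions with overlapping gene models, estimates integer copy number
    from TaqMan quantitative PCR replicates by the comparative
    delta-delta-Ct method, and computes case-control association
    statistics (Pearson chi-square, Wald odds-ratio confidence intervals,
    covariate-adjusted logistic regression, Mann-Whitney U). A
    synthetic-data module generates probe maps, case/control arrays with
    planted events, qPCR plates and cohort covariate tables with known
    ground truth, so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
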