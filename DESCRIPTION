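Package: dmrbump
Title: Bump-Hunting Detection of Differentially Methylated Regions
    Across Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects differentially methylated regions (DMRs) from
    Illumina 450K-style beta-value matrices by bump hunting: probe
    filtering (detection P, SNP-affected probes, sex chromosomes,
    cell-type marker masks), covariate-adjusted per-probe effect
    estimation on M-values, running-median smoothing within probe
    clusters, a bootstrap empirical null with quantile cut-offs, and
    region-level P, FDR and FWER. Includes direction-stratified
    multi-cohort consensus overlap of significant regions,
    nearest-gene annotation, and a synthetic multi-cohort study
    generator with planted DMRs for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
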