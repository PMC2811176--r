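Package: helpscan
Title: Differential DNA Methylation Scanning for HELP Assay Log-Ratio Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide differential cytosine-methylation analysis for
    matched case/control cohorts assayed by methylation-sensitive restriction
    digestion (HELP-style log2(HpaII/MspI) ratio matrices). Provides quantile
    normalization and sample-level quality control, a per-locus paired t-test
    scan with a permutation-calibrated genome-wide significance threshold, a
    fold-change-weighted ranking statistic, CpG-island/promoter/gene-body
    annotation of candidate loci, hypergeometric enrichment scoring,
    effect-size estimation, two-sample t-test power analysis (Monte Carlo and
    noncentral-t), cross-platform concordance with bisulphite percent
    methylation, and a synthetic matched-cohort generator with ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    limma,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
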