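Package: polysomeAPV
Title: Differential Translation Analysis of Polysome Profiling Data by
    Analysis of Partial Variance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-wide identification of differentially translated mRNAs
    from paired cytosolic and polysome-associated expression profiles. Fits
    a per-gene analysis of partial variance (ANCOVA of polysome-associated
    on cytosolic log2 levels with a common slope), moderates residual
    variances with an empirical-Bayes random variance model, applies slope
    and effect-size reliability filters with Benjamini-Hochberg FDR control,
    builds fold-change signatures with cross-study overlap and sign
    concordance testing, and performs filtered hypergeometric gene-set
    enrichment. Includes a seeded generator of paired translatome datasets
    with known ground truth for calibration and recovery testing, plus
    reproducibility QC by correlation clustering.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
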