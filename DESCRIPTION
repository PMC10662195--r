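Package: mrpipe
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a complete two-sample Mendelian randomization (MR)
    workflow over GWAS summary statistics: typed ingestion and validation of
    per-SNP association records, instrument selection (genome-wide
    significance filtering, greedy linkage-disequilibrium clumping against a
    supplied r-squared matrix, palindrome exclusion, per-SNP F-statistic
    screening), exposure/outcome allele harmonization, causal-effect
    estimation by inverse-variance weighting (fixed and multiplicative
    random effects), MR-Egger regression with intercept-based pleiotropy
    testing, and the weighted-median estimator with a parametric-bootstrap
    standard error, together with Cochran's Q heterogeneity tests,
    leave-one-out and single-SNP influence tables, and a seeded synthetic
    two-sample GWAS generator for parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    withr,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
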