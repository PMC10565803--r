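Package: mrscreen
Title: Two-Sample Mendelian Randomization Screening of GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening many genetically instrumented exposures (such
    as gut-microbiota taxa) against a binary disease outcome with two-sample
    Mendelian randomization. Provides reading, validation and writing of GWAS
    summary statistics, instrument selection by p-value filtering and greedy
    LD clumping, allele harmonization with palindrome removal, the
    inverse-variance-weighted, MR-Egger and weighted-median causal estimators,
    a sensitivity suite (Cochran's Q heterogeneity test, MR-Egger intercept,
    leave-one-out influence, F-statistic instrument strength), a batch
    screening pipeline with explicit verdict logic, and a synthetic
    summary-statistic generator with known ground truth for calibration and
    power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
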