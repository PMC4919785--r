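Package: scoremr
Title: Two-Sample Mendelian Randomisation with Allelic Score Instruments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomisation of a continuous
    exposure (estimated glomerular filtration rate, eGFR) on a binary outcome
    (coronary heart disease) using allelic score instruments. Derives eGFR from
    serum creatinine via the four-variable MDRD study equation; estimates
    per-SNP instrument weights by study-adjusted linear regression; builds
    unweighted and weighted gene scores and quantifies instrument strength;
    screens candidate confounders and the instrumental-variable assumptions by
    trait-wide scans with Benjamini-Hochberg false discovery rate control and a
    permutation calibration check; pools per-SNP outcome log odds ratios by the
    precision-weighted (inverse-variance) summary-statistic estimator, with
    leave-one-out, SNP-exclusion, subgroup and reverse-direction sensitivity
    analyses; and computes analytic power of the design for binary outcomes.
    Includes a synthetic-data generator emulating cohort-consortium
    individual-level data and GWAS-consortium summary statistics with known
    ground truth, so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
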