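# scoremr

Two-sample Mendelian randomisation (MR) with allelic score instruments, for
studies asking whether kidney function — measured as estimated glomerular
filtration rate (eGFR) — causally affects coronary heart disease (CHD) risk.
The package is aimed at epidemiologists who have individual-level cohort data
for the exposure side (genotypes, serum creatinine, demographics, a panel of
quantitative traits) and only per-SNP summary statistics (log odds ratios and
standard errors) for the outcome side, as released by large GWAS consortia.

## What it computes

The exposure is derived from serum creatinine by the four-variable MDRD Study
equation,

    eGFR = 175 x Scr^-1.154 x age^-0.203 x 0.742^[female] x 1.212^[black]

in ml/min/1.73 m². Per-SNP instrument weights w_j are the slopes of
study-adjusted linear regressions of eGFR on allele count, oriented so every
SNP is counted by its eGFR-increasing allele. The causal effect of the score
on the binary outcome is estimated from outcome summary statistics alone by
precision-weighted pooling:

    beta_hat = sum_j( w_j * beta_Yj / s_Yj^2 ) / sum_j( w_j^2 / s_Yj^2 )
    se(beta_hat) = ( sum_j w_j^2 / s_Yj^2 )^(-1/2)

where beta_Yj is the per-allele log odds ratio of SNP j on the outcome and
s_Yj its standard error. This is algebraically identical to weighted least
squares of beta_Yj on w_j through the origin with weights 1/s_Yj²; the
unweighted-score variant sets w_j = 1. Around this core the package provides:

- allele harmonization between exposure and outcome summary statistics,
  including sign flips, multi-meta-analysis rows and palindromic-SNP flags
  (`harmonize`);
- gene-score construction and instrument-strength diagnostics (partial R²
  and F statistic) (`build_score`, `instrument_strength`);
- phenome-wide screening of the MR assumptions: dual trait scans against
  exposure and outcome with Benjamini–Hochberg FDR control, confounder
  identification with documented exclusions, and a permutation check of the
  FDR calibration (`trait_scan`, `identify_confounders`,
  `permutation_fdr_check`);
- sensitivity analyses: leave-one-out, named-SNP exclusion, low-eGFR
  subgroup re-estimation, and reverse-direction MR (`leave_one_out`,
  `exclude_snps`, `subgroup_estimate`, `reverse_mr`);
- analytic power for binary outcomes from the non-centrality approximation
  sqrt(NCP) = |ln OR| * sqrt(N R² K(1-K)) (`mr_power`);
- a synthetic-data generator with known ground truth emulating a multi-study
  exposure consortium and a consortium-style outcome sample
  (`sim_config`, `generate_cohort`, `generate_outcome_summary`).

## Worked example

A complete run on generated data (exposure cohort of 10,000 across 4 studies,
score R² targeted at 1.5%, independent outcome sample of 6,600 cases and
13,400 controls, true causal log OR −0.016 per eGFR unit):

```r
library(scoremr)
av <- matrix(FALSE, 17, 3); av[, 3] <- TRUE   # SNPs in the combined meta-analysis
cfg <- sim_config(n_subjects = 2500, n_studies = 4, egfr_studies = 1:4,
                  true_causal_logOR = -0.016,
                  outcome = list(n_cases = 6600, n_controls = 13400,
                                 availability = av),
                  seed = 7)
cohort  <- generate_cohort(cfg)
pheno   <- derive_egfr(cohort$phenotypes)
weights <- estimate_weights(cohort$genotypes, pheno)
score   <- build_score(cohort$genotypes, weights, "weighted", study = pheno$study)
instrument_strength(score, pheno)
#> Instrument strength: partial R^2 = 0.0182, F = 185.2, n = 10000

summary_stats <- generate_outcome_summary(cfg)
mr_fit(summary_stats, weights, score_type = "weighted")
#> Two-sample Mendelian randomisation (summary-statistic allelic score)
#>   score: weighted, 17 SNPs used
#>   OR per score unit: 0.975  95% CI [0.96, 0.99]  p = 0.00124

mr_fit(summary_stats, weights, score_type = "unweighted")
#> Two-sample Mendelian randomisation (summary-statistic allelic score)
#>   score: unweighted, 17 SNPs used
#>   OR per score unit: 0.989  95% CI [0.978, 1]  p = 0.0525

observational_association(pheno)
#> Observational association (logistic), n = 10000
#>   OR per 1 ml/min/1.73m^2: 0.979  95% CI [0.975, 0.982]  p = 4.6e-30
```

The instrument is strong (F ≫ 10); the weighted-score MR odds ratio per score
unit is below 1, consistent with the generative causal effect, and the
observational OR per eGFR unit (0.979) reflects the same protective direction
of higher eGFR. Power of a consortium-scale outcome sample (N = 194,427,
63,746 cases, R² = 0.015) to detect causal odds ratios of 0.9 and 0.95:

```r
mr_power(194427, 63746/194427, 0.015, c(0.9, 0.95))
#> [1] 0.7614785 0.2553076
```

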