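---
title: "Score-based two-sample Mendelian randomisation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Score-based two-sample Mendelian randomisation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scoremr)
```

This vignette is the package's own account of the statistical procedure it
implements: the instrumental-variable logic, each model with its assumptions,
the tunable parameters and their defaults, what the synthetic-data generator
does and does not emulate, and the numerical conventions. It states no
empirical result that the test suite and the acceptance script do not
themselves compute.

## The design

Mendelian randomisation (MR) uses genetic variants as instrumental variables
to ask whether an exposure causally affects an outcome. Because alleles are
assigned at conception, a variant that influences the exposure is — under
assumptions spelled out below — free of the confounding and reverse causation
that afflict observational exposure–outcome associations. Here the exposure
is kidney function, measured as estimated glomerular filtration rate (eGFR,
ml/min/1.73 m²), and the outcome is coronary heart disease (CHD).

The design is *two-sample*: instrument–exposure associations are estimated in
an individual-level multi-study cohort consortium, while instrument–outcome
associations come from a much larger, independent consortium that releases
only per-SNP summary statistics (log odds ratios and standard errors). The
per-SNP exposure effects are combined into a single allelic score instrument,
which concentrates the (individually tiny) SNP effects and improves power.

A valid score instrument must satisfy three assumptions:

1. it is associated with the exposure (testable: the score–eGFR regression);
2. it is not associated with confounders of the exposure–outcome association
   (testable for *measured* traits: the trait-wide score scan);
3. it affects the outcome only through the exposure (not fully testable;
   probed by scanning the score against every available trait and by
   sensitivity analyses for single influential variants).

## Exposure derivation

eGFR is computed from serum creatinine by the IDMS-traceable four-variable
MDRD Study equation,
$$\mathrm{eGFR} = 175 \cdot \mathrm{Scr}^{-1.154} \cdot \mathrm{age}^{-0.203}
\cdot 0.742^{[\mathrm{female}]} \cdot 1.212^{[\mathrm{black}]},$$
with creatinine fixed to mg/dL at the interface. A conversion helper
(`creatinine_to_mgdl`, µmol/L ÷ 88.4) exists but is never applied implicitly
— silent unit mixing is the classic eGFR bug, so the unit conversion must be
a visible step. Missing creatinine propagates to missing eGFR; non-positive
creatinine or age is treated as a corrupt row and raises an error. The
ethnicity term is implemented but defaults to "not black" since the cohorts
emulated here are largely of European ancestry. eGFR is left untransformed
throughout (it is approximately normal in such cohorts), and the
conventional clinical categories use cutpoints 60 and 90 with the boundary
belonging to the upper category: `low` < 60, `intermediate` [60, 90),
`normal_high` ≥ 90.

## Gene scores and instrument strength

Per-SNP weights are estimated by one linear regression per SNP of eGFR on
allele count (additive coding), adjusting for study as a categorical
covariate; only study is adjusted for, since between-study differences are
the one structural nuisance the multi-study design imposes. Each SNP is then
oriented to its eGFR-*increasing* allele, making all reported weights
non-negative. A slope of exactly zero is oriented by alphabetical allele
label and flagged, so output is deterministic. The unweighted score of a
subject is the count of increasing alleles over the instrument SNPs (range 0
to 2J); the weighted score multiplies each count by its weight. Orientations
can be replaced for a subset of SNPs by an external direction catalog (a
larger published meta-analysis); flipping a SNP complements its oriented
coding, $g \mapsto 2-g$, and is an involution.

Missing genotypes are mean-imputed from the non-missing allele counts of that
SNP within study, which keeps the score scale comparable across subjects; a
subject missing every genotype gets a missing score. Instrument strength is
reported as the partial R² of the score in a study-adjusted regression of
eGFR on the score, with its F statistic ($F = t^2$ for a single predictor);
F well above 10 indicates limited weak-instrument bias.

## Screening the assumptions

Potential confounders are identified by a dual trait scan: every available
trait is tested for association with the exposure (study-adjusted linear
regression of trait on eGFR; logistic regression for binary traits such as
sex) and with the outcome (logistic regression of CHD on the trait). Each
scan family is adjusted by the Benjamini–Hochberg step-up procedure at FDR
0.05 — within-family rather than jointly, because the two scans answer
distinct questions and are reported as separate panels. A trait rejected in
*both* scans is a potential confounder; both associations are necessary but
not sufficient for confounding, so the set is deliberately conservative.
Traits with external evidence of lying on the causal pathway (the default
pathway-marker list ships with the renally cleared biomarker NTproBNP) and
traits measured in fewer than `min_study_coverage = 2` studies are moved to
an exclusion ledger with explicit reasons rather than silently dropped.

Benjamini–Hochberg assumes a form of positive dependence; correlated traits
could in principle distort its calibration. `permutation_fdr_check` enforces
the global null by permuting the target variable across subjects *within
study strata* (preserving study-level trait differences), reruns the scan
plus adjustment for each permutation, and summarises the distribution of
rejection counts and the probability of at least one rejection — which under
the global null should not exceed the nominal level by more than Monte-Carlo
error. Within-study permutation is this package's documented choice of
scheme; other schemes (unrestricted permutation, rotation tests) would be
defensible.

## The pooled causal estimator

With harmonized per-SNP outcome statistics $(\beta_{Yj}, s_{Yj})$ aligned to
the eGFR-increasing alleles and predetermined weights $w_j$, the causal
effect of the score is estimated by precision-weighted pooling
$$\hat\beta = \frac{\sum_j w_j \beta_{Yj} s_{Yj}^{-2}}
{\sum_j w_j^2 s_{Yj}^{-2}}, \qquad
\mathrm{se}(\hat\beta) = \Big(\sum_j w_j^2 s_{Yj}^{-2}\Big)^{-1/2},$$
the coefficient of the gene score on the outcome recoverable from summary
data alone. It is algebraically identical to weighted least squares of
$\beta_{Yj}$ on $w_j$ through the origin with weights $1/s_{Yj}^2$ — the test
suite certifies both the point estimate and the standard error against an
independent `lm()` oracle of that regression. The unweighted variant sets
$w_j = 1$; with a single SNP the estimator reduces to the ratio
$\beta_{Y}/w$, and with exchangeable SNPs to the precision-pooled mean.
Two-sided p-values compare $\hat\beta/\mathrm{se}$ to a standard normal.
The estimate is reported as an odds ratio per score unit and deliberately
*not* converted into an "effect of eGFR" — with a possibly invalid or
heterogeneous instrument its primary use is detecting the presence of a
causal effect. The estimator is invariant to joint re-orientation of any SNP
(weight sign and outcome sign flip together), and rescaling all weights by
$c$ divides the estimate by $c$ without changing the z-statistic.

Harmonization conventions: a SNP present in several outcome meta-analyses
contributes its smallest-SE row (largest effective sample), logged per SNP;
instrument SNPs absent from the outcome set are dropped with a logged count
(consortium panels rarely cover every instrument SNP); palindromic (A/T,
C/G) SNPs are harmonized by allele labels only, with a warning and no
frequency-based strand inference; an allele pair matching neither instrument
allele is a strand/label error and excludes the SNP with a flag.

## Sensitivity analyses

- **Leave-one-out** refits the estimate excluding each SNP in turn and flags
  exclusions that cross the two-sided 0.05 boundary — the signature of a
  single variant (e.g. a pleiotropic one) driving the pooled signal.
- **Named exclusion** refits without specified SNPs, for variants with known
  pleiotropic effects.
- **Subgroup estimation** restricts the cohort to one eGFR category
  (typically `low`, eGFR < 60, where observational risk is concentrated),
  re-estimates the weights there and refits. Conditioning on the exposure
  can bias a causal estimate, so the result carries an explicit caveat flag.
- **Reverse MR** swaps roles: a weighted score of outcome-associated SNPs
  (weights = their published log odds ratios) instruments CHD, and the
  "outcome" statistics are per-SNP eGFR regression coefficients from the
  cohort. The same pooled formula applies on the continuous scale.

## Power

For a binary outcome the two-sided Wald test of $\hat\beta$ has asymptotic
non-centrality $NCP = N R^2 K(1-K) (\ln OR)^2$, where $N$ is the total
outcome sample, $K$ the case fraction and $R^2$ the instrument's share of
exposure variance; power at level $\alpha$ is
$\Phi(\sqrt{NCP} - z_{1-\alpha/2}) + \Phi(-\sqrt{NCP} - z_{1-\alpha/2})$.
It equals $\alpha$ exactly at $OR = 1$ and is symmetric in $OR$ and $1/OR$.
The acceptance suite cross-checks the formula against the empirical
rejection rate of the pooled estimator over 1,000 simulated summary-statistic
replicates at a reduced design.

## The synthetic-data generator

The generator exists so that every downstream stage is testable with known
ground truth and no data access. It emulates:

- a multi-study exposure consortium: by default 7 studies of 1,878 subjects
  (≈13,100 total, CHD case fraction ≈ 0.17), with creatinine — hence eGFR —
  measured in only 4 of the 7 studies;
- genotypes drawn independently per SNP as binomial(2, freq) under
  Hardy–Weinberg equilibrium, with a default panel of 17 variants at known
  kidney-function loci (ids only; frequencies and relative effects are
  synthetic defaults, not estimates of any cohort);
- eGFR as study intercept + centred additive SNP effects + trait effects +
  Gaussian noise (default residual SD 14, mean 85, between-study SD 3), with
  the per-SNP effects rescaled *jointly* so the true score explains exactly
  `target_score_r2` (default 0.015) of within-study eGFR variance in
  expectation — the instrument-strength anchor of the emulated regime;
- serum creatinine obtained by inverting the MDRD equation on the true eGFR,
  so the derivation stage reproduces the generated ground truth exactly;
- CHD from a logistic model: baseline log-odds (default −1.58) + causal
  effect `true_causal_logOR` (default −0.016 per eGFR unit, the magnitude of
  the observational association in elderly cohorts) × centred eGFR + trait
  effects + optional direct (pleiotropic) SNP effects;
- declared traits by role: confounders (affect both), exposure-only,
  outcome-only, null, and pathway markers generated downstream of eGFR;
- an independent consortium-style outcome sample (default 6,600 cases /
  13,400 controls, case fraction ≈ 0.33) ascertained by oversampling cases
  from a generated population — per-allele odds ratios are invariant to
  outcome-dependent sampling, so ascertainment is benign — with per-SNP
  logistic fits emitted as summary rows from three pseudo-meta-analyses
  (two partial, one combined) under a per-SNP availability mask.

A single master seed spawns fixed substreams for the cohort and the outcome
sample, so the two-sample independence is structural: regenerating one
leaves the other bit-identical.

It does **not** emulate: linkage disequilibrium between instrument SNPs (the
emulated panel is pre-pruned), population stratification, imputation
dosages, genotyping error, or the real correlation structure of cohort trait
panels (trait covariances are free parameters of `trait_spec`, not
estimates). Passing tests therefore demonstrate the statistical machinery
under a clean generative model, not robustness to those real-data
complications.

## Numerical conventions and degenerate inputs

95% intervals use 1.96 exactly; p-values are two-sided from the normal (the
scans use the t reference with the exact residual df). Study-adjusted linear
fits are computed by within-study centring, which is algebraically identical
to including study dummies; the suite checks equality with `lm()` to 1e-10.
BH adjustment ignores missing p-values (the family size is the non-missing
count). Monomorphic SNPs have no defined weight and are excluded with a
warning; zero-variance traits are skipped; logistic separation is flagged
and the p-value set missing; an all-zero weight vector, all-missing eGFR, or
a subgroup/complete-case sample too small for its parameter count each
refuse with a diagnostic rather than returning numbers. Confidence intervals
and p-values are always derived from the same standard error, so every
reported triple (estimate, CI, p) is internally consistent.

## Problem sizes used by the test suite

The acceptance checks run the full pipeline at the scale of the emulated
study: 17 SNPs, score R² = 0.015, exposure cohort n = 10,000 (4 studies, all
with eGFR, so the weight regressions use the full cohort), outcome sample
n = 20,000 with one summary row per SNP, 200 replicates for bias and
coverage and 1,000 for type-I error; the screening calibration uses 94
independent null traits, 500 within-study permutations at n = 1,000, and a
planted 3-confounder design at n = 20,000. These sizes give Monte-Carlo
error small enough to resolve the calibration bands while keeping the whole
suite in a few minutes on one CPU.

Two properties of this regime are worth knowing. First, with 17 SNPs sharing
R² = 1.5% at n = 10,000, per-SNP F statistics are ≈ 9, so the two-sample
estimator carries the classic weak-instrument dilution of roughly
$F/(F+1) \approx 0.9$ toward the null; the bias and coverage bands in the
acceptance suite account for this known property rather than hiding it.
Second, case–control ascertainment in the outcome sample shifts only the
logistic intercepts, leaving per-allele odds ratios identifiable.

## Known limitations

The estimator assumes uncorrelated instruments (no LD) and fixed, known
weights; weight-estimation noise is what produces the dilution above.
Pleiotropy is probed, not corrected — robust estimators (median-based,
intercept-adjusted regression) are deliberately out of scope. Palindromic
SNPs are matched by label only, so strand mix-ups at A/T and C/G variants
must be resolved upstream. The power formula is asymptotic and ignores
weight-estimation noise, which is appropriate at consortium scale but
optimistic for small outcome samples.
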