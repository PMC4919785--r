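# Shared fixtures: toy weights/summary tables, random estimator instances,
# a hand-written Benjamini-Hochberg step-up oracle, and small simulation
# configs. Everything is built in code at test time.

toy_weights <- function(w = c(0.5, 1.0, 2.0),
                        inc = c("A", "C", "G"),
                        oth = c("G", "T", "A")) {
  inc <- rep_len(inc, length(w))
  oth <- rep_len(oth, length(w))
  data.frame(snp_id = paste0("rs", seq_along(w)),
             increasing_allele = inc, other_allele = oth,
             w = w, se_w = rep(0.1, length(w)),
             source = "internal_regression", stringsAsFactors = FALSE)
}

toy_summary <- function(weights, beta, se,
                        effect_allele = weights$increasing_allele,
                        other_allele = weights$other_allele,
                        source = "Metabochip") {
  data.frame(snp_id = weights$snp_id, effect_allele = effect_allele,
             other_allele = other_allele, beta = beta, se = se,
             n_cases = 1000L, n_controls = 2000L, source = source,
             stringsAsFactors = FALSE)
}

# Random pooled-estimator instance: weights, outcome betas and SEs.
random_instance <- function(k) {
  w <- toy_weights(w = runif(k, 0.05, 2),
                   inc = rep("A", k), oth = rep("G", k))
  s <- toy_summary(w, beta = rnorm(k, 0, 0.05), se = runif(k, 0.005, 0.05))
  list(weights = w, summary = s)
}

# Independent origin-constrained WLS oracle via lm(); the unscaled SE is the
# fixed-precision standard error of the pooled estimator.
wls_oracle <- function(beta_y, w, se_y) {
  fit <- lm(beta_y ~ 0 + w, weights = 1 / se_y^2)
  sm <- summary(fit)
  list(beta = unname(coef(fit)[1]),
       se = unname(sm$coefficients[1, 2] / sm$sigma))
}

# Textbook step-up BH adjustment, written independently of the package.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

# Small fast simulation config: all studies measure eGFR, SNPs only in the
# combined pseudo-meta-analysis (one summary row per SNP).
quick_config <- function(n_per_study = 500, n_studies = 4,
                         n_cases = 1000, n_controls = 3000,
                         snps = default_snp_panel(), seed = 1, ...) {
  av <- matrix(FALSE, nrow(snps), 3)
  av[, 3] <- TRUE
  sim_config(n_subjects = n_per_study, n_studies = n_studies,
             egfr_studies = seq_len(n_studies), snps = snps,
             outcome = list(n_cases = n_cases, n_controls = n_controls,
                            availability = av),
             seed = seed, ...)
}
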