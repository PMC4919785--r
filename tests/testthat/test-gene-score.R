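# local genotype fixture: n subjects x SNPs of toy_weights(), counted allele
# equal to the increasing allele
toy_genotypes <- function(g_rows, weights = toy_weights()) {
  G <- matrix(g_rows, ncol = nrow(weights), byrow = TRUE,
              dimnames = list(NULL, weights$snp_id))
  attr(G, "snp_info") <- data.frame(
    snp_id = weights$snp_id, counted_allele = weights$increasing_allele,
    other_allele = weights$other_allele, stringsAsFactors = FALSE)
  G
}

test_that("weighted score is the dot product; unweighted the allele count", {
  w <- toy_weights(w = c(0.5, 1.0, 0.25))
  G <- toy_genotypes(c(0, 1, 2), w)
  expect_equal(as.vector(build_score(G, w, "weighted")), 1.5)
  expect_equal(as.vector(build_score(G, w, "unweighted")), 3)
  # homozygous for the increasing allele at 17 SNPs scores 34
  w17 <- toy_weights(w = rep(1, 17), inc = rep("A", 17), oth = rep("G", 17))
  G17 <- toy_genotypes(rep(2, 17), w17)
  expect_equal(as.vector(build_score(G17, w17, "unweighted")), 34)
  # unit weights reduce the weighted score to the unweighted one
  expect_equal(build_score(G17, w17, "weighted"),
               build_score(G17, w17, "unweighted"),
               ignore_attr = TRUE)
})

test_that("score is linear in the weights and orientation is an involution", {
  w <- toy_weights(w = c(0.4, 1.2, 0.8))
  G <- toy_genotypes(c(0, 1, 2, 2, 0, 1, 1, 1, 2), w)
  s1 <- build_score(G, w, "weighted")
  w3 <- w; w3$w <- 3 * w3$w
  expect_equal(build_score(G, w3, "weighted"), 3 * s1, ignore_attr = TRUE)
  # flip one SNP's orientation twice -> original score
  cat1 <- data.frame(snp_id = "rs2", increasing_allele = w$other_allele[2])
  cat2 <- data.frame(snp_id = "rs2", increasing_allele = w$increasing_allele[2])
  w_flip <- orient_from_external(w, cat1)
  w_back <- orient_from_external(w_flip, cat2)
  expect_equal(build_score(G, w_back, "weighted"), s1, ignore_attr = TRUE)
  # a single flip complements the oriented genotype: g -> 2 - g
  s_flip <- build_score(G, w_flip, "unweighted")
  s_orig <- build_score(G, w, "unweighted")
  expect_equal(s_flip - s_orig, 2 - 2 * G[, "rs2"], ignore_attr = TRUE)
})

test_that("external catalog: agreement is a no-op, label errors are flagged", {
  w <- toy_weights()
  cat_same <- data.frame(snp_id = w$snp_id,
                         increasing_allele = w$increasing_allele)
  w_same <- orient_from_external(w, cat_same)
  expect_equal(w_same$increasing_allele, w$increasing_allele)
  expect_equal(w_same$w, w$w)
  cat_bad <- data.frame(snp_id = "rs1", increasing_allele = "Z")
  expect_warning(w_bad <- orient_from_external(w, cat_bad), "neither")
  expect_match(attr(w_bad, "flagged"), "rs1")
  expect_equal(w_bad$increasing_allele, w$increasing_allele)
})

test_that("weight estimation recovers generative per-allele effects", {
  cfg <- quick_config(n_per_study = 2500, seed = 21)
  coh <- generate_cohort(cfg)
  ph <- derive_egfr(coh$phenotypes)
  w <- estimate_weights(coh$genotypes, ph)
  truth <- attr(coh$phenotypes, "truth")
  delta <- truth$delta
  # orient the generative effect to the reported increasing allele
  info <- attr(coh$genotypes, "snp_info")
  flip <- w$increasing_allele != info$counted_allele[match(w$snp_id, info$snp_id)]
  delta_oriented <- ifelse(flip, -delta, delta)
  expect_true(all(abs(w$w - delta_oriented) < 3 * w$se_w))
  expect_true(all(w$w >= 0))
  # permuting subject order leaves the weights unchanged
  ord <- sample(nrow(ph))
  w2 <- estimate_weights(coh$genotypes[ord, , drop = FALSE], ph[ord, ],
                         snp_info = info)
  expect_equal(w2$w, w$w, tolerance = 1e-10)
  expect_equal(w2$increasing_allele, w$increasing_allele)
})

test_that("weight regressions match lm() with study covariate exactly", {
  cfg <- quick_config(n_per_study = 300, seed = 5)
  coh <- generate_cohort(cfg)
  ph <- derive_egfr(coh$phenotypes)
  w <- estimate_weights(coh$genotypes, ph)
  for (j in c(1, 8, 17)) {
    fit <- lm(ph$egfr ~ coh$genotypes[, j] + ph$study)
    sl <- coef(summary(fit))[2, ]
    expect_equal(w$w[j], abs(unname(sl["Estimate"])), tolerance = 1e-10)
    expect_equal(w$se_w[j], unname(sl["Std. Error"]), tolerance = 1e-10)
  }
})

test_that("monomorphic SNPs are excluded; all-missing eGFR errors", {
  cfg <- quick_config(n_per_study = 200, seed = 3)
  coh <- generate_cohort(cfg)
  ph <- derive_egfr(coh$phenotypes)
  G <- coh$genotypes
  G[, 2] <- 0L
  expect_warning(w <- estimate_weights(G, ph,
                                       snp_info = attr(coh$genotypes, "snp_info")),
                 "monomorphic")
  expect_false("rs2453533" %in% w$snp_id)
  expect_equal(attr(w, "excluded"), "rs2453533")
  ph$egfr <- NA_real_
  expect_error(estimate_weights(coh$genotypes, ph), "missing")
})

test_that("missing genotypes are mean-imputed within study; all-missing is NA", {
  w <- toy_weights(w = c(1, 1, 1))
  G <- toy_genotypes(c(0, 1, 2,
                       2, 1, 0,
                       NA, 1, 1,
                       NA, NA, NA), w)
  study <- c("a", "a", "a", "a")
  s <- build_score(G, w, "unweighted", study = study)
  expect_equal(unname(s[3]), 1 + 1 + 1) # imputed rs1 = mean(0, 2) = 1
  expect_true(is.na(s[4]))
})

test_that("instrument strength: perfect, null and F = t^2 identity", {
  set.seed(13)
  n <- 4000
  study <- factor(rep(1:4, each = n / 4))
  egfr <- rnorm(n, 85, 14)
  ph <- data.frame(egfr = egfr, study = study)
  perfect <- instrument_strength(egfr, ph)
  expect_equal(perfect$r_squared, 1)
  null_s <- instrument_strength(rnorm(n), ph)
  expect_lt(null_s$r_squared, 0.005)
  # algebraic identity with the study-adjusted lm fit
  score <- 0.3 * egfr + rnorm(n, 0, 13)
  st <- instrument_strength(score, ph)
  fit <- lm(egfr ~ score + study, data = ph)
  tval <- coef(summary(fit))["score", "t value"]
  expect_equal(st$f_statistic, tval^2, tolerance = 1e-9)
  expect_equal(st$r_squared, tval^2 / (tval^2 + df.residual(fit)),
               tolerance = 1e-9)
  expect_equal(st$f_statistic,
               (st$n_used - 4 - 1) * st$r_squared / (1 - st$r_squared),
               tolerance = 1e-9)
  expect_error(instrument_strength(rep(1, n), ph), "zero-variance")
})
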