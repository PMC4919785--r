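test_that("single-SNP and equal-SNP closed forms hold exactly", {
  w1 <- toy_weights(w = 1, inc = "A", oth = "G")
  f1 <- mr_fit(toy_summary(w1, beta = -0.02, se = 0.01), w1, "unweighted")
  expect_equal(f1$beta, -0.02)
  expect_equal(f1$se, 0.01)

  k <- 6
  wk <- toy_weights(w = rep(1, k), inc = rep("A", k), oth = rep("G", k))
  fk <- mr_fit(toy_summary(wk, beta = rep(0.03, k), se = rep(0.012, k)),
               wk, "unweighted")
  expect_equal(fk$beta, 0.03)
  expect_equal(fk$se, 0.012 / sqrt(k))
})

test_that("three-SNP example equals origin-constrained WLS", {
  w <- toy_weights(w = c(0.5, 1.0, 2.0))
  s <- toy_summary(w, beta = c(0.01, 0.03, 0.05), se = c(0.01, 0.02, 0.02))
  fit <- mr_fit(s, w, "weighted")
  expect_equal(fit$beta, 0.025) # hand computation
  o <- wls_oracle(s$beta, w$w, s$se)
  expect_equal(fit$beta, o$beta, tolerance = 1e-12)
  expect_equal(fit$se, o$se, tolerance = 1e-12)
})

test_that("estimator equals independent WLS oracle on random instances", {
  set.seed(31)
  for (i in 1:120) {
    inst <- random_instance(sample(2:25, 1))
    for (type in c("weighted", "unweighted")) {
      fit <- mr_fit(inst$summary, inst$weights, type)
      w_used <- if (type == "weighted") inst$weights$w else rep(1, nrow(inst$summary))
      o <- wls_oracle(inst$summary$beta, w_used, inst$summary$se)
      expect_equal(fit$beta, o$beta, tolerance = 1e-10)
      expect_equal(fit$se, o$se, tolerance = 1e-10)
    }
  }
})

test_that("estimate invariants: CI, p, scale invariance of the z-statistic", {
  set.seed(5)
  inst <- random_instance(12)
  fit <- mr_fit(inst$summary, inst$weights, "weighted")
  expect_equal(fit$ci, exp(fit$beta + c(-1.96, 1.96) * fit$se))
  expect_equal(fit$p, 2 * pnorm(abs(fit$beta / fit$se), lower.tail = FALSE))
  expect_equal(fit$or, exp(fit$beta))
  # multiplying all weights by c divides beta and se by c; z unchanged
  w2 <- inst$weights; w2$w <- 3 * w2$w
  fit2 <- mr_fit(inst$summary, w2, "weighted")
  expect_equal(fit2$beta, fit$beta / 3, tolerance = 1e-12)
  expect_equal(fit2$se, fit$se / 3, tolerance = 1e-12)
  expect_equal(fit2$z, fit$z, tolerance = 1e-12)
  expect_equal(coef(fit), c(score = fit$beta))
  expect_equal(unname(confint(fit, level = 0.95)[1, ]),
               fit$beta + qnorm(c(0.025, 0.975)) * fit$se)
})

test_that("degenerate estimator inputs are rejected", {
  w <- toy_weights(w = c(0, 0, 0))
  s <- toy_summary(w, beta = c(0.01, 0.02, 0.01), se = rep(0.01, 3))
  expect_error(mr_fit(s, w, "weighted"), "zero")
  s_bad <- s; s_bad$se[2] <- 0
  expect_error(mr_fit(s_bad, toy_weights(), "weighted"), "positive")
})

test_that("harmonization aligns, flips and drops correctly", {
  w <- toy_weights()
  s <- toy_summary(w, beta = c(0.05, -0.02, 0.03), se = rep(0.01, 3))
  # aligned input is untouched
  h <- harmonize(s, w)
  expect_equal(h$beta, s$beta)
  # swapped alleles at one SNP flip the sign
  s2 <- s
  s2$effect_allele[1] <- w$other_allele[1]
  s2$other_allele[1] <- w$increasing_allele[1]
  h2 <- harmonize(s2, w)
  expect_equal(h2$beta, c(-0.05, -0.02, 0.03))
  expect_equal(h2$effect_allele, w$increasing_allele)
  # flipping twice restores the input (involution)
  h3 <- harmonize(h2, w)
  expect_equal(h3$beta, h2$beta)
  # allele pair matching neither is flagged and excluded
  s4 <- s; s4$effect_allele[2] <- "T"; s4$other_allele[2] <- "G"
  h4 <- harmonize(s4, w)
  expect_equal(nrow(h4), 2)
  expect_match(attr(h4, "flagged"), "rs2")
  # instrument SNPs absent from the summary set land in the dropped ledger
  h5 <- harmonize(s[-c(1, 3), ], w)
  expect_equal(nrow(h5), 1)
  expect_setequal(attr(h5, "dropped"), c("rs1", "rs3"))
  expect_equal(mr_fit(s[-1, ], w, "unweighted")$n_snps, 2)
})

test_that("palindromic alleles warn; multi-source rows keep the smallest SE", {
  w <- toy_weights(w = 1, inc = "A", oth = "T")
  s <- toy_summary(w, beta = 0.02, se = 0.01, effect_allele = "A",
                   other_allele = "T")
  expect_warning(harmonize(s, w), "palindromic")

  w2 <- toy_weights(w = c(1, 1))
  s2 <- rbind(
    toy_summary(w2, beta = c(0.02, 0.04), se = c(0.02, 0.015),
                source = "CARDIoGRAM"),
    toy_summary(w2[1, ], beta = 0.05, se = 0.008, source = "Metabochip"))
  h <- harmonize(s2, w2)
  expect_equal(nrow(h), 2)
  expect_equal(h$beta[h$snp_id == "rs1"], 0.05) # smallest-SE row won
  expect_match(attr(h, "combined"), "Metabochip", all = FALSE)
})

test_that("leave-one-out matches direct recomputation and respects symmetry", {
  k <- 5
  w <- toy_weights(w = rep(1, k), inc = rep("A", k), oth = rep("G", k))
  s_same <- toy_summary(w, beta = rep(0.02, k), se = rep(0.01, k))
  loo <- leave_one_out(s_same, w, "unweighted")
  expect_equal(nrow(loo), k)
  expect_true(all(abs(loo$beta - loo$beta[1]) < 1e-14)) # exchangeable SNPs

  # one outlying SNP: its exclusion equals recomputation without it
  s_out <- s_same; s_out$beta[3] <- -0.40
  loo2 <- leave_one_out(s_out, w, "unweighted")
  direct <- mr_fit(s_out[-3, ], w, "unweighted")
  expect_equal(loo2$beta[3], direct$beta, tolerance = 1e-12)
  expect_equal(loo2$p[3], direct$p, tolerance = 1e-12)
  expect_error(leave_one_out(s_same[1, ], w[1, ]), "at least 2")
})

test_that("exclude_snps nests correctly and validates ids", {
  set.seed(9)
  inst <- random_instance(8)
  full <- mr_fit(inst$summary, inst$weights, "weighted")
  same <- exclude_snps(inst$summary, inst$weights, character(0), "weighted")
  expect_equal(same$beta, full$beta)
  one <- exclude_snps(inst$summary, inst$weights,
                      inst$summary$snp_id[-4], "weighted")
  expect_equal(one$beta, inst$summary$beta[4] / inst$weights$w[4],
               tolerance = 1e-12) # single-instrument ratio identity
  expect_error(exclude_snps(inst$summary, inst$weights, "rs999"), "rs999")
})

test_that("print, summary and residual methods expose the fit", {
  set.seed(3)
  inst <- random_instance(6)
  fit <- mr_fit(inst$summary, inst$weights, "weighted")
  expect_output(print(fit), "OR per score unit")
  expect_output(print(summary(fit)), "Per-SNP")
  r <- residuals(fit)
  expect_equal(unname(r),
               (inst$summary$beta - inst$weights$w * fit$beta) / inst$summary$se)
})
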