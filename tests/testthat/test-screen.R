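test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2) # m = 1: unchanged
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(17)
  for (i in 1:25) {
    p <- runif(sample(1:60, 1))
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
  # missing values are ignored, family size is the non-missing count
  p_na <- c(0.01, NA, 0.04)
  expect_equal(bh_adjust(p_na), c(bh_oracle(c(0.01, 0.04))[1], NA,
                                  bh_oracle(c(0.01, 0.04))[2]))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  # adjusted p never below raw p
  p <- runif(40)
  expect_true(all(bh_adjust(p) >= p))
})

make_scan_pheno <- function(n = 1200, n_null = 10, seed = 42) {
  set.seed(seed)
  study <- factor(rep(sprintf("s%d", 1:4), each = n / 4))
  egfr <- 85 + rnorm(n, 0, 14)
  chd <- rbinom(n, 1, plogis(-1.5 - 0.01 * (egfr - 85)))
  ph <- data.frame(study = study, egfr = egfr, chd = chd)
  for (i in seq_len(n_null)) ph[[sprintf("null%02d", i)]] <- rnorm(n)
  ph$signal <- egfr + rnorm(n, 0, 4)       # planted exposure association
  ph$binary_tr <- rbinom(n, 1, 0.5)        # sex-like binary trait
  ph
}

test_that("trait scan rejects planted signals and respects scan semantics", {
  ph <- make_scan_pheno()
  traits <- c(sprintf("null%02d", 1:10), "signal", "binary_tr")
  scan <- trait_scan(ph, "egfr", traits)
  expect_s3_class(scan, "trait_scan")
  expect_equal(scan$trait, sort(traits)) # deterministic ordering
  expect_true(scan$rejected[scan$trait == "signal"])
  expect_lt(sum(scan$rejected), 3) # null traits essentially never rejected
  expect_true(all(scan$p_adj >= scan$p, na.rm = TRUE))
  expect_equal(scan$rejected, !is.na(scan$p_adj) & scan$p_adj <= 0.05)
  expect_equal(unique(scan$scan_kind), "exposure_trait")
  # single-trait scan: adjusted p equals raw p
  one <- trait_scan(ph, "egfr", "null01")
  expect_equal(one$p_adj, one$p)
  # row-permutation invariance
  ord <- sample(nrow(ph))
  scan_perm <- trait_scan(ph[ord, ], "egfr", traits)
  expect_equal(scan_perm$beta, scan$beta, tolerance = 1e-10)
})

test_that("scan model forms: trait-on-target linear, CHD-on-trait logistic", {
  ph <- make_scan_pheno(n = 800)
  # continuous trait vs continuous target: linear regression trait ~ target
  sc <- trait_scan(ph, "egfr", "signal")
  ref <- lm(signal ~ egfr + study, data = ph)
  expect_equal(sc$beta, unname(coef(ref)["egfr"]), tolerance = 1e-10)
  expect_equal(sc$se, unname(coef(summary(ref))["egfr", 2]), tolerance = 1e-10)
  # binary trait: logistic of trait on target
  scb <- trait_scan(ph, "egfr", "binary_tr")
  refb <- glm(binary_tr ~ egfr + study, family = binomial(), data = ph)
  expect_equal(scb$beta, unname(coef(refb)["egfr"]), tolerance = 1e-6)
  # CHD target: logistic of CHD on the trait
  scc <- trait_scan(ph, "chd", "signal")
  refc <- glm(chd ~ signal + study, family = binomial(), data = ph)
  expect_equal(scc$beta, unname(coef(refc)["signal"]), tolerance = 1e-6)
  expect_equal(unique(scc$scan_kind), "outcome_trait")
  # score target uses the supplied score vector
  score <- rnorm(nrow(ph))
  scs <- trait_scan(ph, "score", "signal", score = score)
  expect_equal(unique(scs$scan_kind), "score_trait")
  # zero-variance trait is skipped with a warning
  ph$flat <- 1
  expect_warning(scf <- trait_scan(ph, "egfr", c("signal", "flat")),
                 "zero-variance")
  expect_true(is.na(scf$p[scf$trait == "flat"]))
})

test_that("confounder identification intersects scans and documents exclusions", {
  mk <- function(traits, rejected) {
    data.frame(trait = traits, rejected = rejected, stringsAsFactors = FALSE)
  }
  exp_scan <- mk(c("a", "b", "c", "d", "ntp"), c(TRUE, TRUE, FALSE, TRUE, TRUE))
  out_scan <- mk(c("a", "b", "c", "d", "ntp"), c(TRUE, FALSE, TRUE, TRUE, TRUE))
  cs <- identify_confounders(exp_scan, out_scan, pathway_markers = "ntp",
                             study_coverage = c(a = 4, b = 4, c = 4, d = 1,
                                                ntp = 4))
  expect_setequal(cs$confounders, "a")
  expect_setequal(cs$exclusions$trait, c("ntp", "d"))
  expect_match(cs$exclusions$reason[cs$exclusions$trait == "ntp"], "pathway")
  expect_match(cs$exclusions$reason[cs$exclusions$trait == "d"], "fewer than")
  # disjoint rejection sets give an empty confounder set
  cs2 <- identify_confounders(mk("a", TRUE), mk("a", FALSE))
  expect_length(cs2$confounders, 0)
})

test_that("permutation FDR check is deterministic and calibrated on null traits", {
  ph <- make_scan_pheno(n = 400, n_null = 20)
  traits <- sprintf("null%02d", 1:20)
  r1 <- permutation_fdr_check(ph, "egfr", traits, n_permutations = 3, seed = 99)
  r2 <- permutation_fdr_check(ph, "egfr", traits, n_permutations = 3, seed = 99)
  expect_identical(r1$reject_counts, r2$reject_counts)
  r3 <- permutation_fdr_check(ph, "egfr", traits, n_permutations = 120,
                              seed = 7)
  # BH under independent nulls: P(any rejection) near or below 0.05
  expect_lte(r3$p_any_rejection, 0.05 + 3 * sqrt(0.05 * 0.95 / 120))
})

test_that("perfectly correlated traits keep the any-rejection rate near nominal", {
  set.seed(8)
  n <- 300
  ph <- data.frame(study = factor(rep(1:2, each = n / 2)),
                   egfr = rnorm(n, 85, 14))
  base <- rnorm(n)
  for (i in 1:10) ph[[sprintf("dup%02d", i)]] <- base # 10 identical copies
  r <- permutation_fdr_check(ph, "egfr", sprintf("dup%02d", 1:10),
                             n_permutations = 250, seed = 3)
  # counts are lumpy (all-or-nothing) but P(any) stays controlled
  expect_lte(r$p_any_rejection, 0.05 + 3 * sqrt(0.05 * 0.95 / 250))
  expect_true(all(r$reject_counts %in% c(0L, 10L)))
})

test_that("adjusted observational analysis nests and rescales correctly", {
  ph <- make_scan_pheno(n = 1000)
  un <- observational_association(ph)
  ad0 <- adjusted_observational(ph, character(0))
  expect_equal(ad0$beta, un$beta, tolerance = 1e-10)
  or10 <- observational_association(ph, per_units = 10)
  expect_equal(or10$or, un$or^10, tolerance = 1e-10)
  expect_equal(or10$p, un$p) # rescaling does not change the test
  small <- ph[1:12, ]
  expect_error(adjusted_observational(small, sprintf("null%02d", 1:8)),
               "too small")
})
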