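#' Declare a simulated trait
#'
#' Helper building one entry of the `trait_spec` list of [sim_config()].
#' Roles: a `confounder` affects both eGFR and CHD log-odds; an
#' `exposure_only` trait affects eGFR only; an `outcome_only` trait affects
#' CHD only; a `null` trait affects neither; a `pathway_marker` is generated
#' downstream of eGFR (loading `beta_egfr` on centred eGFR plus noise), like
#' a renally cleared biomarker.
#'
#' @param name trait (column) name.
#' @param role one of `"confounder"`, `"exposure_only"`, `"outcome_only"`,
#'   `"null"`, `"pathway_marker"`.
#' @param beta_egfr effect on eGFR (ml/min/1.73 m\eqn{^2} per trait SD), or
#'   for pathway markers the loading of the marker on centred eGFR.
#' @param beta_chd effect on the CHD log-odds per trait SD.
#' @param sd trait standard deviation (noise SD for pathway markers).
#' @return a named list; combine several into a `trait_spec` list.
#' @export
trait_spec <- function(name, role = c("confounder", "exposure_only",
                                      "outcome_only", "null",
                                      "pathway_marker"),
                       beta_egfr = 0, beta_chd = 0, sd = 1) {
  role <- match.arg(role)
  list(name = name, role = role, beta_egfr = beta_egfr, beta_chd = beta_chd,
       sd = sd)
}

#' Default 17-SNP instrument panel
#'
#' An illustrative panel of 17 variants at well-known kidney-function loci
#' (ids only; frequencies and relative effect sizes are synthetic defaults,
#' not estimates from any study). `rs653178` is given the smallest relative
#' exposure effect, emulating a variant that is weakly associated with
#' creatinine-based eGFR in the exposure cohort yet strongly associated with
#' the outcome through other pathways.
#'
#' @param pleiotropy_logor direct (non-eGFR-mediated) per-allele effect of
#'   rs653178 on the CHD log-odds; 0 (default) means no pleiotropy.
#' @return data frame `snp_id`, `counted_allele`, `other_allele`, `freq`
#'   (counted-allele frequency), `rel_effect` (relative per-allele eGFR
#'   effect, rescaled jointly by the generator), `pleiotropy_logor`.
#' @export
default_snp_panel <- function(pleiotropy_logor = 0) {
  panel <- data.frame(
    snp_id = c("rs17319721", "rs2453533", "rs1260326", "rs13538",
               "rs347685", "rs11959928", "rs881858", "rs6465825",
               "rs4744712", "rs10794720", "rs3925584", "rs10774021",
               "rs653178", "rs626277", "rs1394125", "rs12917707",
               "rs911119"),
    counted_allele = c("A", "G", "T", "A", "A", "A", "A", "T", "A", "T",
                       "T", "T", "T", "A", "A", "T", "C"),
    other_allele   = c("G", "A", "C", "G", "C", "C", "G", "C", "C", "C",
                       "C", "C", "C", "C", "G", "G", "T"),
    freq = c(0.43, 0.62, 0.41, 0.22, 0.71, 0.55, 0.70, 0.61, 0.39, 0.92,
             0.55, 0.87, 0.49, 0.60, 0.35, 0.82, 0.79),
    rel_effect = c(1.6, 1.3, 0.9, 0.8, 0.7, 0.9, 0.8, 1.0, 0.8, 1.0,
                   0.9, 1.1, 0.25, 0.8, 0.9, 1.5, 1.2),
    stringsAsFactors = FALSE
  )
  panel$pleiotropy_logor <- ifelse(panel$snp_id == "rs653178",
                                   pleiotropy_logor, 0)
  panel
}

#' Simulation configuration for the synthetic MR study
#'
#' Defines a multi-study exposure cohort (genotypes under Hardy-Weinberg
#' equilibrium, eGFR from an additive genetic model plus confounders and
#' Gaussian noise, CHD from a logistic model) and an independent
#' consortium-style outcome sample released as per-SNP summary statistics
#' from three pseudo-meta-analyses with per-SNP availability. The defaults
#' emulate a consortium of 7 cohort studies totalling about 13,000 subjects
#' (case fraction about 0.17), eGFR measurable in 4 of the 7 studies, a
#' 17-SNP score explaining 1.5% of eGFR variance, and an outcome sample of
#' 20,000 with a case fraction of 0.33.
#'
#' Per-SNP eGFR effects are rescaled jointly so the score's population
#' R-squared (relative to within-study variance) equals `target_score_r2`
#' exactly in expectation. A master `seed` spawns fixed substreams for the
#' cohort and the outcome sample, so regenerating one leaves the other
#' unchanged.
#'
#' @param n_subjects subjects per study (scalar or vector of length
#'   `n_studies`).
#' @param n_studies number of cohort studies.
#' @param snps SNP panel as from [default_snp_panel()]: `snp_id`,
#'   `counted_allele`, `other_allele`, `freq` in (0.01, 0.99), `rel_effect`,
#'   optional `pleiotropy_logor`.
#' @param target_score_r2 fraction of (within-study) eGFR variance explained
#'   by the true score; must be < 0.5 (larger values signal a config error).
#' @param traits list of [trait_spec()] entries.
#' @param true_causal_logOR causal log odds ratio of CHD per one
#'   ml/min/1.73 m\eqn{^2} of eGFR (default -0.016, the magnitude of the
#'   observational association in elderly cohort data).
#' @param baseline_chd_logodds intercept of the CHD logistic model (default
#'   -1.58, about 17% prevalence at mean eGFR).
#' @param egfr_noise_sd residual eGFR SD, ml/min/1.73 m\eqn{^2} (> 0).
#' @param egfr_mean population mean eGFR; study intercepts are drawn around
#'   it with SD `study_sd`.
#' @param study_sd SD of between-study eGFR intercepts.
#' @param egfr_studies indices of studies with creatinine (hence eGFR)
#'   measured; others have it missing.
#' @param outcome list: `n_cases`, `n_controls`, and `availability`, a SNPs x
#'   3 logical matrix saying which pseudo-meta-analysis
#'   (`CARDIoGRAM`-like GWAS, `C4D`-like GWAS, combined `Metabochip`-like)
#'   contains each SNP; every SNP must be present in at least one.
#' @param outcome_fractions fraction of the outcome sample contributing to
#'   each pseudo-meta-analysis (the combined one uses everything).
#' @param seed master integer seed.
#' @return validated object of class `"sim_config"`.
#' @export
sim_config <- function(n_subjects = 1878, n_studies = 7,
                       snps = default_snp_panel(),
                       target_score_r2 = 0.015,
                       traits = list(),
                       true_causal_logOR = -0.016,
                       baseline_chd_logodds = -1.58,
                       egfr_noise_sd = 14,
                       egfr_mean = 85, study_sd = 3,
                       egfr_studies = 1:4,
                       outcome = list(n_cases = 6600, n_controls = 13400,
                                      availability = NULL),
                       outcome_fractions = c(CARDIoGRAM = 0.45, C4D = 0.16,
                                             Metabochip = 1),
                       seed = 1) {
  .stop_if(nrow(snps) < 1L, "empty SNP list")
  .stop_if(any(snps$freq <= 0.01 | snps$freq >= 0.99),
           "allele frequencies must lie in (0.01, 0.99)")
  .stop_if(anyDuplicated(snps$snp_id) > 0, "duplicate SNP ids")
  .stop_if(target_score_r2 < 0 || target_score_r2 >= 0.5,
           "target_score_r2 must be in [0, 0.5): larger values are an implausible instrument")
  .stop_if(egfr_noise_sd <= 0, "egfr_noise_sd must be positive")
  .stop_if(outcome$n_cases <= 0 || outcome$n_controls <= 0,
           "outcome n_cases and n_controls must be positive")
  if (length(n_subjects) == 1L) n_subjects <- rep(n_subjects, n_studies)
  .stop_if(length(n_subjects) != n_studies,
           "n_subjects must be scalar or one value per study")
  .stop_if(any(egfr_studies < 1 | egfr_studies > n_studies),
           "egfr_studies out of range")
  if (is.null(snps$pleiotropy_logor)) snps$pleiotropy_logor <- 0
  if (is.null(outcome$availability)) {
    av <- matrix(TRUE, nrow(snps), 3)
    # a few SNPs missing from the two component GWAS, all present somewhere
    if (nrow(snps) >= 3) av[1:2, 2] <- FALSE
    if (nrow(snps) >= 5) av[3, 1] <- FALSE
    outcome$availability <- av
  }
  av <- outcome$availability
  .stop_if(!is.matrix(av) || nrow(av) != nrow(snps) || ncol(av) != 3,
           "availability must be a SNPs x 3 logical matrix")
  .stop_if(any(rowSums(av) == 0),
           "each SNP must be available in at least one pseudo-meta-analysis")
  for (tr in traits) {
    .stop_if(!all(c("name", "role", "beta_egfr", "beta_chd", "sd") %in%
                    names(tr)), "traits must be built with trait_spec()")
  }
  structure(list(
    n_subjects = n_subjects, n_studies = n_studies, snps = snps,
    target_score_r2 = target_score_r2, traits = traits,
    true_causal_logOR = true_causal_logOR,
    baseline_chd_logodds = baseline_chd_logodds,
    egfr_noise_sd = egfr_noise_sd, egfr_mean = egfr_mean,
    study_sd = study_sd, egfr_studies = egfr_studies,
    outcome = outcome, outcome_fractions = outcome_fractions,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Per-allele eGFR effects rescaled so the true score explains exactly
# target_score_r2 of the within-study eGFR variance in expectation.
.scaled_effects <- function(config) {
  s <- config$snps
  delta0 <- s$rel_effect
  if (config$target_score_r2 == 0 || all(delta0 == 0)) {
    return(rep(0, nrow(s)))
  }
  v_g0 <- sum(delta0^2 * 2 * s$freq * (1 - s$freq))
  v_conf <- 0
  for (tr in config$traits) {
    if (tr$role %in% c("confounder", "exposure_only")) {
      v_conf <- v_conf + tr$beta_egfr^2 # traits enter standardised to SD 1
    }
  }
  v_rest <- v_conf + config$egfr_noise_sd^2
  r2 <- config$target_score_r2
  delta0 * sqrt(r2 * v_rest / ((1 - r2) * v_g0))
}

# Draw genotypes, traits, eGFR and CHD for n subjects (shared by the cohort
# and the outcome-sample generators; assumes the RNG stream is already set).
.draw_subjects <- function(config, n, study_intercepts, study_idx) {
  s <- config$snps
  J <- nrow(s)
  G <- matrix(stats::rbinom(n * J, 2L, rep(s$freq, each = n)), nrow = n,
              dimnames = list(NULL, s$snp_id))
  delta <- .scaled_effects(config)
  age <- pmin(pmax(stats::rnorm(n, 62, 8), 40), 90)
  female <- stats::rbinom(n, 1L, 0.5)
  traits <- list()
  # genetic contribution centred so study intercepts are the study means
  egfr <- study_intercepts[study_idx] + as.vector(G %*% delta) -
    sum(delta * 2 * s$freq)
  lp <- config$baseline_chd_logodds
  for (tr in config$traits) {
    if (tr$role == "pathway_marker") next
    z <- stats::rnorm(n, 0, tr$sd)
    traits[[tr$name]] <- z
    if (tr$role %in% c("confounder", "exposure_only")) {
      egfr <- egfr + tr$beta_egfr * z / tr$sd
    }
    if (tr$role %in% c("confounder", "outcome_only")) {
      lp <- lp + tr$beta_chd * z / tr$sd
    }
  }
  egfr <- egfr + stats::rnorm(n, 0, config$egfr_noise_sd)
  egfr <- pmax(egfr, 5) # floor: eGFR is a positive quantity
  lp <- lp + config$true_causal_logOR * (egfr - config$egfr_mean)
  if (any(s$pleiotropy_logor != 0)) {
    lp <- lp + as.vector(G %*% s$pleiotropy_logor) -
      sum(s$pleiotropy_logor * 2 * s$freq)
  }
  chd <- stats::rbinom(n, 1L, stats::plogis(lp))
  for (tr in config$traits) {
    if (tr$role == "pathway_marker") {
      traits[[tr$name]] <- tr$beta_egfr * (egfr - config$egfr_mean) +
        stats::rnorm(n, 0, tr$sd)
    }
  }
  list(G = G, egfr = egfr, chd = chd, age = age, female = female,
       traits = traits)
}

#' Generate the individual-level exposure cohort
#'
#' Simulates a multi-study cohort under the configured generative model:
#' genotypes binomial(2, freq) under Hardy-Weinberg, eGFR = study intercept +
#' additive SNP effects + confounder effects + Gaussian noise, CHD from a
#' logistic model with the configured causal effect of eGFR. Serum creatinine
#' is back-computed from true eGFR through the inverse MDRD equation for
#' studies that measure it (and left missing elsewhere), so
#' [derive_egfr()] recovers the generated values exactly.
#'
#' @param config a [sim_config()] object.
#' @return list with `genotypes` (matrix with `snp_info` attribute) and
#'   `phenotypes` (data frame: `subject_id`, `study`, `age`, `female`,
#'   `black`, `creatinine`, `chd`, one column per declared trait). Ground
#'   truth (true eGFR, scaled per-SNP effects, study intercepts) is attached
#'   as `attr(, "truth")`.
#' @export
generate_cohort <- function(config) {
  .stop_if(!inherits(config, "sim_config"), "config must be a sim_config")
  set.seed(config$seed + 1L)
  n <- sum(config$n_subjects)
  study_idx <- rep(seq_len(config$n_studies), config$n_subjects)
  study_intercepts <- config$egfr_mean +
    stats::rnorm(config$n_studies, 0, config$study_sd)
  d <- .draw_subjects(config, n, study_intercepts, study_idx)
  has_cr <- study_idx %in% config$egfr_studies
  creatinine <- rep(NA_real_, n)
  creatinine[has_cr] <- .creatinine_from_egfr(d$egfr[has_cr], d$age[has_cr],
                                              d$female[has_cr])
  pheno <- data.frame(
    subject_id = sprintf("S%06d", seq_len(n)),
    study = factor(sprintf("study%02d", study_idx)),
    age = d$age, female = d$female, black = 0L,
    creatinine = creatinine, chd = d$chd,
    stringsAsFactors = FALSE
  )
  for (nm in names(d$traits)) pheno[[nm]] <- d$traits[[nm]]
  genotypes <- d$G
  rownames(genotypes) <- pheno$subject_id
  attr(genotypes, "snp_info") <- config$snps[, c("snp_id", "counted_allele",
                                                 "other_allele", "freq")]
  attr(pheno, "truth") <- list(
    egfr = d$egfr, delta = .scaled_effects(config),
    true_causal_logOR = config$true_causal_logOR,
    study_intercepts = study_intercepts
  )
  list(genotypes = genotypes, phenotypes = pheno)
}

#' Generate consortium-style outcome summary statistics
#'
#' Simulates an outcome sample independent of the exposure cohort (its own
#' RNG substream of the master seed — the two-sample design), ascertains the
#' configured numbers of cases and controls by oversampling cases from a
#' generated population, and fits one logistic regression of CHD on allele
#' count per SNP. Each of the three pseudo-meta-analyses re-fits on its own
#' nested subsample (the combined one uses the full sample), and a SNP
#' contributes one summary row per meta-analysis in which it is available;
#' SNPs absent everywhere are omitted. Case-control ascertainment leaves the
#' per-allele odds ratio identifiable (only the intercept shifts).
#'
#' @param config a [sim_config()] object.
#' @return data frame of class `"outcome_summary"` in the summary-statistics
#'   layout: `snp_id`, `effect_allele` (the counted allele), `other_allele`,
#'   `beta` (log OR per effect allele), `se`, `n_cases`, `n_controls`,
#'   `source`.
#' @export
generate_outcome_summary <- function(config) {
  .stop_if(!inherits(config, "sim_config"), "config must be a sim_config")
  set.seed(config$seed + 2L)
  s <- config$snps
  nc <- config$outcome$n_cases
  nn <- config$outcome$n_controls
  study_intercepts <- config$egfr_mean # single "population" intercept
  case_rows <- list(); control_rows <- list()
  got_cases <- 0L; got_controls <- 0L
  batch <- max(20000L, 2L * (nc + nn))
  for (iter in 1:40) {
    d <- .draw_subjects(config, batch, study_intercepts, rep(1L, batch))
    is_case <- d$chd == 1L
    if (got_cases < nc) {
      take <- utils::head(which(is_case), nc - got_cases)
      case_rows[[iter]] <- d$G[take, , drop = FALSE]
      got_cases <- got_cases + length(take)
    }
    if (got_controls < nn) {
      take <- utils::head(which(!is_case), nn - got_controls)
      control_rows[[iter]] <- d$G[take, , drop = FALSE]
      got_controls <- got_controls + length(take)
    }
    if (got_cases >= nc && got_controls >= nn) break
  }
  .stop_if(got_cases < nc || got_controls < nn,
           "could not ascertain the requested outcome sample; check baseline_chd_logodds")
  G <- rbind(do.call(rbind, case_rows), do.call(rbind, control_rows))
  y <- rep(c(1L, 0L), c(nc, nn))
  # random order so nested subsamples preserve the case:control ratio
  ord <- sample.int(nc + nn)
  G <- G[ord, , drop = FALSE]; y <- y[ord]
  av <- config$outcome$availability
  fr <- config$outcome_fractions
  rows <- list()
  for (m in seq_along(fr)) {
    snps_m <- which(av[, m])
    if (!length(snps_m)) next
    n_m <- ceiling(fr[m] * (nc + nn))
    sub <- seq_len(n_m)
    for (j in snps_m) {
      g <- G[sub, j]
      totals <- tabulate(g + 1L, 3L)
      cases <- c(sum(y[sub][g == 0L]), sum(y[sub][g == 1L]),
                 sum(y[sub][g == 2L]))
      fit <- .logit_geno(cases, totals)
      rows[[length(rows) + 1L]] <- data.frame(
        snp_id = s$snp_id[j], effect_allele = s$counted_allele[j],
        other_allele = s$other_allele[j], beta = fit$beta, se = fit$se,
        n_cases = sum(y[sub]), n_controls = n_m - sum(y[sub]),
        source = names(fr)[m], stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("outcome_summary", "data.frame")
  out
}
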