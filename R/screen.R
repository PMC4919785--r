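#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment controlling the false discovery rate. Missing p-values
#' are ignored (the family size is the number of non-missing values) and
#' returned as missing. Values outside \[0, 1\] are an error.
#'
#' @param pvalues numeric vector of raw p-values.
#' @return adjusted p-values, monotone and capped at 1.
#' @export
bh_adjust <- function(pvalues) {
  .stop_if(any(pvalues < 0 | pvalues > 1, na.rm = TRUE),
           "p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(pvalues))
  ok <- !is.na(pvalues)
  out[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
  out
}

#' Trait-wide association scan against eGFR, CHD or a gene score
#'
#' One regression per trait, complete-case per trait (so the per-trait sample
#' sizes vary with availability). For continuous targets (`egfr`, `score`)
#' each trait is regressed on the target by study-adjusted linear regression;
#' a binary trait (e.g. sex) uses logistic regression instead. For the binary
#' target `chd` the direction is reversed: logistic regression of CHD on the
#' trait. P-values are two-sided Wald; Benjamini-Hochberg adjustment is
#' applied within the scan family. Zero-variance traits are skipped with a
#' warning; logistic separation is flagged and the p-value set missing.
#'
#' @param phenotypes phenotype table (needs `study`, plus `egfr` or `chd`
#'   depending on the target, and the trait columns).
#' @param target `"egfr"`, `"chd"` or `"score"`.
#' @param traits character vector of trait column names to scan.
#' @param score numeric per-subject gene score, required when
#'   `target = "score"`.
#' @param q FDR level for the rejection flag (default 0.05).
#' @return data frame of class `"trait_scan"`, ordered by trait name, with
#'   columns `trait`, `n`, `beta`, `se`, `p`, `p_adj`, `rejected`,
#'   `scan_kind`.
#' @export
trait_scan <- function(phenotypes, target = c("egfr", "chd", "score"),
                       traits, score = NULL, q = 0.05) {
  target <- match.arg(target)
  tgt <- switch(target,
                egfr = phenotypes$egfr,
                chd = phenotypes$chd,
                score = score)
  .stop_if(is.null(tgt), sprintf("target '%s' unavailable", target))
  .stop_if(target == "score" && length(score) != nrow(phenotypes),
           "score must align with the phenotype table")
  study <- if (is.null(phenotypes$study)) NULL else
    as.integer(factor(phenotypes$study))
  kind <- switch(target, egfr = "exposure_trait", chd = "outcome_trait",
                 score = "score_trait")
  rows <- lapply(sort(traits), function(tr) {
    y <- phenotypes[[tr]]
    .stop_if(is.null(y), sprintf("trait column '%s' not found", tr))
    ok <- is.finite(y) & is.finite(tgt)
    if (sum(ok) >= 2L && stats::var(y[ok]) == 0) {
      warning(sprintf("zero-variance trait '%s' skipped", tr), call. = FALSE)
      return(data.frame(trait = tr, n = sum(ok), beta = NA_real_,
                        se = NA_real_, p = NA_real_, stringsAsFactors = FALSE))
    }
    fit <- if (target == "chd") {
      .logit_xy(tgt, y, study)
    } else if (.is_binary(y)) {
      .logit_xy(.as01(y), tgt, study)
    } else {
      .lm_xy(y, tgt, study)
    }
    if (isTRUE(fit$separation)) {
      warning(sprintf("separation in logistic fit for trait '%s'", tr),
              call. = FALSE)
    }
    data.frame(trait = tr, n = fit$n, beta = fit$beta, se = fit$se,
               p = fit$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out$rejected <- !is.na(out$p_adj) & out$p_adj <= q
  out$scan_kind <- kind
  rownames(out) <- NULL
  attr(out, "target") <- target
  attr(out, "q") <- q
  class(out) <- c("trait_scan", "data.frame")
  out
}

#' Identify potential confounders from dual trait scans
#'
#' A trait is a potential confounder of the exposure-outcome association when
#' it is FDR-rejected in both the exposure-trait and the outcome-trait scans
#' (both associations are necessary, though not sufficient, for confounding).
#' Traits with external evidence of lying on the causal pathway (e.g. a
#' renally cleared biomarker) and traits measured in too few studies are
#' moved to an exclusion ledger with their reasons rather than silently
#' dropped.
#'
#' @param exposure_scan,outcome_scan `trait_scan` results for the exposure
#'   and the outcome.
#' @param pathway_markers trait names to exclude as on-pathway (default
#'   `"NTproBNP"`, the canonical renally cleared marker).
#' @param study_coverage optional named integer vector: number of studies in
#'   which each trait is measured.
#' @param min_study_coverage minimum coverage to retain a trait (default 2).
#' @return object of class `"confounder_set"`: list with `confounders`
#'   (character) and `exclusions` (data frame `trait`, `reason`).
#' @export
identify_confounders <- function(exposure_scan, outcome_scan,
                                 pathway_markers = "NTproBNP",
                                 study_coverage = NULL,
                                 min_study_coverage = 2) {
  both <- intersect(exposure_scan$trait[exposure_scan$rejected],
                    outcome_scan$trait[outcome_scan$rejected])
  both <- sort(both)
  excl <- data.frame(trait = character(0), reason = character(0),
                     stringsAsFactors = FALSE)
  on_path <- intersect(both, pathway_markers)
  if (length(on_path)) {
    excl <- rbind(excl, data.frame(
      trait = on_path, reason = "renally cleared / on causal pathway",
      stringsAsFactors = FALSE))
  }
  if (!is.null(study_coverage)) {
    low <- intersect(both, names(study_coverage)[study_coverage < min_study_coverage])
    low <- setdiff(low, excl$trait)
    if (length(low)) {
      excl <- rbind(excl, data.frame(
        trait = low,
        reason = sprintf("measured in fewer than %d studies", min_study_coverage),
        stringsAsFactors = FALSE))
    }
  }
  structure(list(confounders = setdiff(both, excl$trait), exclusions = excl),
            class = "confounder_set")
}

#' @export
print.confounder_set <- function(x, ...) {
  cat(sprintf("Potential confounders (%d): %s\n", length(x$confounders),
              paste(x$confounders, collapse = ", ")))
  if (nrow(x$exclusions)) {
    cat("Excluded:\n")
    for (i in seq_len(nrow(x$exclusions))) {
      cat(sprintf("  %s — %s\n", x$exclusions$trait[i], x$exclusions$reason[i]))
    }
  }
  invisible(x)
}

#' Permutation check of the FDR procedure under correlated traits
#'
#' Permutes the target variable across subjects within study strata (so
#' study-level trait differences are preserved while the global null is
#' enforced), reruns the trait scan plus Benjamini-Hochberg adjustment for
#' each permutation, and summarises the distribution of rejection counts. If
#' correlation among traits made the procedure conservative or anti-
#' conservative this shows up in the empirical probability of making at least
#' one rejection, which under the global null should not exceed the nominal
#' FDR level by more than Monte-Carlo error.
#'
#' @inheritParams trait_scan
#' @param n_permutations number of permutations (use several hundred for a
#'   stable estimate).
#' @param seed integer seed; results are reproducible given the seed.
#' @return object of class `"fdr_check"`: list with `reject_counts` (one
#'   count per permutation), `p_any_rejection`, `mean_rejections`, `q`,
#'   `n_permutations`, `mc_se` (Monte-Carlo SE of `p_any_rejection`).
#' @export
permutation_fdr_check <- function(phenotypes, target = c("egfr", "chd"),
                                  traits, n_permutations = 500, seed = 1,
                                  q = 0.05) {
  target <- match.arg(target)
  .stop_if(n_permutations < 1, "n_permutations must be >= 1")
  tgt_col <- target
  .stop_if(is.null(phenotypes[[tgt_col]]), sprintf("no '%s' column", tgt_col))
  grp <- if (is.null(phenotypes$study)) {
    rep(1L, nrow(phenotypes))
  } else as.integer(factor(phenotypes$study))
  set.seed(seed)
  counts <- integer(n_permutations)
  perm_pheno <- phenotypes
  for (b in seq_len(n_permutations)) {
    idx <- seq_len(nrow(phenotypes))
    for (g in unique(grp)) {
      at <- which(grp == g)
      idx[at] <- at[sample.int(length(at))]
    }
    perm_pheno[[tgt_col]] <- phenotypes[[tgt_col]][idx]
    scan <- suppressWarnings(
      trait_scan(perm_pheno, target = target, traits = traits, q = q)
    )
    counts[b] <- sum(scan$rejected)
  }
  p_any <- mean(counts > 0)
  structure(list(
    reject_counts = counts, p_any_rejection = p_any,
    mean_rejections = mean(counts), q = q, n_permutations = n_permutations,
    mc_se = sqrt(p_any * (1 - p_any) / n_permutations)
  ), class = "fdr_check")
}

#' @export
print.fdr_check <- function(x, ...) {
  cat(sprintf("Permutation FDR check (%d permutations, q = %g)\n",
              x$n_permutations, x$q))
  cat(sprintf("  P(any rejection under global null) = %.3f (MC SE %.3f)\n",
              x$p_any_rejection, x$mc_se))
  cat(sprintf("  mean rejections per permutation   = %.3f\n",
              x$mean_rejections))
  invisible(x)
}

#' Confounder-adjusted observational association
#'
#' Logistic regression of the outcome on eGFR plus the listed confounders,
#' on complete cases across all of them (adding many confounders typically
#' shrinks the usable sample substantially). Refuses to fit when the
#' complete-case sample is too small relative to the parameter count.
#'
#' @param phenotypes phenotype table with `egfr`, `chd`, `study` and the
#'   confounder columns.
#' @param confounders character vector of confounder column names (empty
#'   reduces to the unadjusted association).
#' @param per_units report the OR per this many eGFR units.
#' @return an `"or_estimate"` (see [observational_association()]).
#' @export
adjusted_observational <- function(phenotypes, confounders = character(0),
                                   per_units = 1) {
  vars <- c("egfr", "chd", confounders)
  cc <- stats::complete.cases(phenotypes[vars])
  n <- sum(cc)
  n_par <- length(confounders) + 2L +
    (if (is.null(phenotypes$study)) 0L else nlevels(factor(phenotypes$study)) - 1L)
  .stop_if(n < n_par + 10L,
           sprintf("complete-case n = %d too small for %d parameters (need >= %d)",
                   n, n_par, n_par + 10L))
  observational_association(phenotypes[cc, , drop = FALSE],
                            covariates = confounders, per_units = per_units)
}
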