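#' Harmonize outcome summary statistics with instrument weights
#'
#' Aligns per-SNP outcome effect estimates to the exposure-increasing allele
#' of each instrument. Where the summary-statistics effect allele is the
#' non-increasing allele, the sign of `beta` is flipped and the allele labels
#' swapped. SNPs whose allele pair matches neither instrument allele are
#' flagged and excluded; instrument SNPs absent from the summary set are
#' dropped with a logged ledger (`attr(, "dropped")`), mirroring the situation
#' where instrument SNPs are not available in all outcome meta-analyses.
#'
#' A SNP present in several source meta-analyses contributes its smallest-SE
#' row (largest effective sample); the choices are recorded in
#' `attr(, "combined")`. Palindromic (A/T or C/G) SNPs are harmonized by
#' allele labels only, with a warning — no allele-frequency inference is
#' attempted.
#'
#' @param summary outcome summary statistics: data frame with columns
#'   `snp_id`, `effect_allele`, `other_allele`, `beta`, `se` and optionally
#'   `n_cases`, `n_controls`, `source`.
#' @param weights an `instrument_weights` table (see [estimate_weights()]).
#' @return the harmonized summary (one row per retained SNP, effects per
#'   exposure-increasing allele) with attributes `dropped`, `flagged`,
#'   `combined` and `harmonized = TRUE`.
#' @export
harmonize <- function(summary, weights) {
  .check_summary(summary)
  .check_weights(weights)
  # collapse multi-source rows: keep smallest SE per SNP
  combined <- character(0)
  if (anyDuplicated(summary$snp_id)) {
    keep <- unlist(lapply(split(seq_len(nrow(summary)), summary$snp_id),
                          function(i) i[which.min(summary$se[i])]))
    multi <- unique(summary$snp_id[duplicated(summary$snp_id)])
    src <- if (is.null(summary$source)) rep("?", nrow(summary)) else summary$source
    combined <- vapply(multi, function(s) {
      j <- keep[match(s, summary$snp_id[keep])]
      sprintf("%s: kept %s (se=%.4g)", s, src[j], summary$se[j])
    }, character(1))
    summary <- summary[sort(keep), , drop = FALSE]
  }
  idx <- match(weights$snp_id, summary$snp_id)
  dropped <- weights$snp_id[is.na(idx)]
  w <- weights[!is.na(idx), , drop = FALSE]
  s <- summary[idx[!is.na(idx)], , drop = FALSE]
  flagged <- character(0)
  keep <- logical(nrow(s))
  for (j in seq_len(nrow(s))) {
    ea <- s$effect_allele[j]; oa <- s$other_allele[j]
    inc <- w$increasing_allele[j]; oth <- w$other_allele[j]
    if (all(sort(c(ea, oa)) == sort(c("A", "T"))) ||
        all(sort(c(ea, oa)) == sort(c("C", "G")))) {
      warning(sprintf("palindromic alleles at %s harmonized by label only",
                      s$snp_id[j]), call. = FALSE)
    }
    if (ea == inc && oa == oth) {
      keep[j] <- TRUE
    } else if (ea == oth && oa == inc) {
      s$beta[j] <- -s$beta[j]
      s$effect_allele[j] <- inc
      s$other_allele[j] <- oth
      keep[j] <- TRUE
    } else {
      flagged <- c(flagged, sprintf("%s: summary alleles %s/%s do not match instrument %s/%s",
                                    s$snp_id[j], ea, oa, inc, oth))
    }
  }
  out <- s[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  attr(out, "flagged") <- flagged
  attr(out, "combined") <- combined
  attr(out, "harmonized") <- TRUE
  out
}

.check_summary <- function(summary) {
  for (col in c("snp_id", "effect_allele", "other_allele", "beta", "se")) {
    .stop_if(is.null(summary[[col]]),
             sprintf("summary statistics lack column '%s'", col))
  }
  .stop_if(any(!is.finite(summary$se)) || any(summary$se <= 0),
           "all summary standard errors must be positive")
  .stop_if(any(summary$effect_allele == summary$other_allele),
           "effect and other allele must differ")
}

.check_weights <- function(weights) {
  for (col in c("snp_id", "increasing_allele", "other_allele", "w")) {
    .stop_if(is.null(weights[[col]]),
             sprintf("instrument weights lack column '%s'", col))
  }
  .stop_if(anyDuplicated(weights$snp_id) > 0,
           "duplicate SNP ids in instrument weights")
}

#' Summary-statistic causal estimate for an allelic score instrument
#'
#' Fits the precision-weighted summary-statistic estimator pooling per-SNP
#' outcome log odds ratios by predetermined instrument weights:
#' \deqn{\hat\beta = \frac{\sum_j w_j \beta_{Yj} s_{Yj}^{-2}}
#'                        {\sum_j w_j^2 s_{Yj}^{-2}}, \qquad
#'       se(\hat\beta) = \Big(\sum_j w_j^2 s_{Yj}^{-2}\Big)^{-1/2}}
#' which is the coefficient of the gene score on the outcome recoverable from
#' summary data alone, and is algebraically identical to weighted least
#' squares of \eqn{\beta_{Yj}} on \eqn{w_j} through the origin with weights
#' \eqn{1/s_{Yj}^2}. The unweighted-score variant sets \eqn{w_j = 1} for all
#' SNPs. Two-sided p-values compare \eqn{\hat\beta / se} to a standard
#' normal; the 95% CI is \eqn{\exp(\hat\beta \pm 1.96\, se)}.
#'
#' The estimate is reported per score unit (per exposure-increasing allele for
#' the unweighted score). No effect-size interpretation beyond that is
#' attached: the primary use is detecting the presence of a causal effect.
#'
#' @param summary outcome summary statistics (see [harmonize()]); harmonized
#'   automatically when `weights` carries allele orientations and the table is
#'   not already marked harmonized.
#' @param weights `instrument_weights` table; for
#'   `score_type = "unweighted"` only its allele orientations are used.
#' @param score_type `"weighted"` (per-SNP exposure regression weights) or
#'   `"unweighted"` (all weights 1).
#' @param outcome_type `"binary"` (outcome effects are log odds ratios) or
#'   `"continuous"` (regression betas, as in reverse MR); affects reporting
#'   only.
#' @return an object of class `"mr_fit"`: list with elements `beta`, `se`,
#'   `or`, `ci` (95%, odds-ratio scale), `ci_beta`, `z`, `p`, `n_snps`,
#'   `score_type`, per-SNP table `snps`, and the harmonization ledgers
#'   `dropped` / `flagged`.
#' @seealso [leave_one_out()], [exclude_snps()], [reverse_mr()],
#'   [subgroup_estimate()]
#' @examples
#' w <- data.frame(snp_id = c("rs1", "rs2", "rs3"),
#'                 increasing_allele = c("A", "C", "G"),
#'                 other_allele = c("G", "T", "A"),
#'                 w = c(0.5, 1.0, 2.0))
#' s <- data.frame(snp_id = w$snp_id, effect_allele = w$increasing_allele,
#'                 other_allele = w$other_allele,
#'                 beta = c(0.01, 0.03, 0.05), se = c(0.01, 0.02, 0.02))
#' mr_fit(s, w, score_type = "weighted")
#' @export
mr_fit <- function(summary, weights, score_type = c("weighted", "unweighted"),
                   outcome_type = c("binary", "continuous")) {
  score_type <- match.arg(score_type)
  outcome_type <- match.arg(outcome_type)
  if (!isTRUE(attr(summary, "harmonized"))) {
    summary <- harmonize(summary, weights)
  }
  .stop_if(nrow(summary) < 1L, "no SNPs shared between summary set and instrument")
  w_all <- weights$w[match(summary$snp_id, weights$snp_id)]
  wj <- if (score_type == "unweighted") rep(1, nrow(summary)) else w_all
  .stop_if(all(wj == 0), "all instrument weights are zero: estimate undefined")
  prec <- 1 / summary$se^2
  denom <- sum(wj^2 * prec)
  beta <- sum(wj * summary$beta * prec) / denom
  se <- sqrt(1 / denom)
  z <- beta / se
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  ci_beta <- beta + c(-1.96, 1.96) * se
  structure(list(
    beta = beta, se = se, z = z, p = p,
    or = exp(beta), ci = exp(ci_beta), ci_beta = ci_beta,
    n_snps = nrow(summary), score_type = score_type,
    outcome_type = outcome_type,
    snps = data.frame(snp_id = summary$snp_id, w = wj,
                      beta_y = summary$beta, se_y = summary$se,
                      stringsAsFactors = FALSE),
    dropped = attr(summary, "dropped") %||% character(0),
    flagged = attr(summary, "flagged") %||% character(0),
    subgroup = NULL, caveat = NULL,
    call = match.call()
  ), class = "mr_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mr_fit <- function(x, digits = 3, ...) {
  cat("Two-sample Mendelian randomisation (summary-statistic allelic score)\n")
  cat(sprintf("  score: %s, %d SNPs used", x$score_type, x$n_snps))
  if (length(x$dropped)) {
    cat(sprintf(" (%d instrument SNP%s absent from summary set)",
                length(x$dropped), if (length(x$dropped) > 1) "s" else ""))
  }
  cat("\n")
  if (!is.null(x$subgroup)) cat(sprintf("  subgroup: %s\n", x$subgroup))
  if (x$outcome_type == "binary") {
    cat(sprintf("  OR per score unit: %s  95%% CI [%s, %s]  p = %s\n",
                signif(x$or, digits), signif(x$ci[1], digits),
                signif(x$ci[2], digits), signif(x$p, 3)))
  } else {
    cat(sprintf("  beta per score unit: %s  95%% CI [%s, %s]  p = %s\n",
                signif(x$beta, digits), signif(x$ci_beta[1], digits),
                signif(x$ci_beta[2], digits), signif(x$p, 3)))
  }
  if (!is.null(x$caveat)) cat("  note:", x$caveat, "\n")
  invisible(x)
}

#' @export
summary.mr_fit <- function(object, ...) {
  snps <- object$snps
  snps$z_y <- snps$beta_y / snps$se_y
  prec_share <- snps$w^2 / snps$se_y^2
  snps$weight_share <- prec_share / sum(prec_share)
  structure(list(fit = object, snps = snps), class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, ...) {
  print(x$fit)
  cat("\nPer-SNP outcome associations (oriented to exposure-increasing allele):\n")
  print(x$snps, digits = 3, row.names = FALSE)
  if (length(x$fit$flagged)) {
    cat("\nFlagged during harmonization:\n")
    cat(paste0("  ", x$fit$flagged, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) c(score = object$beta)

#' @export
confint.mr_fit <- function(object, parm = "score", level = 0.95, ...) {
  z <- stats::qnorm((1 + level) / 2)
  ci <- object$beta + c(-z, z) * object$se
  m <- matrix(ci, nrow = 1,
              dimnames = list("score", sprintf("%.1f %%", 100 * c((1 - level) / 2, (1 + level) / 2))))
  m
}

#' @export
residuals.mr_fit <- function(object, ...) {
  with(object$snps, stats::setNames((beta_y - w * object$beta) / se_y, snp_id))
}

#' Per-SNP outcome effects against instrument weights
#'
#' Scatter of oriented per-SNP outcome effects (with 95% error bars) against
#' instrument weights; the fitted origin-constrained slope is the pooled
#' causal estimate.
#'
#' @param x an `mr_fit` object.
#' @param ... passed to [plot()].
#' @export
plot.mr_fit <- function(x, ...) {
  s <- x$snps
  ylim <- range(s$beta_y - 1.96 * s$se_y, s$beta_y + 1.96 * s$se_y, 0)
  graphics::plot(s$w, s$beta_y, xlim = range(0, s$w), ylim = ylim,
                 xlab = "instrument weight (exposure units per allele)",
                 ylab = "outcome log OR per allele", pch = 19, ...)
  graphics::segments(s$w, s$beta_y - 1.96 * s$se_y,
                     s$w, s$beta_y + 1.96 * s$se_y)
  graphics::abline(0, x$beta, lty = 2)
  graphics::abline(h = 0, col = "grey")
  invisible(x)
}

#' Leave-one-out sensitivity analysis
#'
#' Refits the pooled estimate excluding each SNP in turn and flags SNPs whose
#' exclusion moves the estimate across the two-sided 0.05 significance
#' boundary relative to the full fit — the signature of a single variant
#' driving the signal.
#'
#' @inheritParams mr_fit
#' @return data frame (class `"mr_loo"`) with one row per excluded SNP:
#'   pooled `beta`, `se`, `or`, CI bounds, `p`, and `crosses_boundary`.
#' @export
leave_one_out <- function(summary, weights,
                          score_type = c("weighted", "unweighted")) {
  score_type <- match.arg(score_type)
  if (!isTRUE(attr(summary, "harmonized"))) summary <- harmonize(summary, weights)
  .stop_if(nrow(summary) < 2L, "leave-one-out needs at least 2 SNPs")
  full <- mr_fit(summary, weights, score_type)
  rows <- lapply(seq_len(nrow(summary)), function(j) {
    fit <- mr_fit(summary[-j, , drop = FALSE], weights, score_type)
    data.frame(excluded_snp = summary$snp_id[j], n_snps = fit$n_snps,
               beta = fit$beta, se = fit$se, or = fit$or,
               ci_lower = fit$ci[1], ci_upper = fit$ci[2], p = fit$p,
               crosses_boundary = (fit$p > 0.05) != (full$p > 0.05),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "full_p") <- full$p
  class(out) <- c("mr_loo", "data.frame")
  out
}

#' Pooled estimate after excluding named SNPs
#'
#' Refits [mr_fit()] on the instrument set minus `snp_ids` — e.g. dropping a
#' known pleiotropic variant. An empty exclusion list returns the full
#' estimate.
#'
#' @inheritParams mr_fit
#' @param snp_ids character vector of SNP ids to exclude; every id must be
#'   present in the harmonized set.
#' @return an `mr_fit` object on the reduced SNP set.
#' @export
exclude_snps <- function(summary, weights, snp_ids,
                         score_type = c("weighted", "unweighted")) {
  score_type <- match.arg(score_type)
  if (!isTRUE(attr(summary, "harmonized"))) summary <- harmonize(summary, weights)
  unknown <- setdiff(snp_ids, summary$snp_id)
  .stop_if(length(unknown) > 0,
           "unknown SNP id(s): ", paste(unknown, collapse = ", "))
  keep <- !(summary$snp_id %in% snp_ids)
  out <- summary[keep, , drop = FALSE]
  attr(out, "harmonized") <- TRUE
  attr(out, "dropped") <- attr(summary, "dropped")
  attr(out, "flagged") <- attr(summary, "flagged")
  mr_fit(out, weights, score_type)
}

#' Causal estimate within an eGFR subgroup
#'
#' Restricts the exposure cohort to one eGFR category (e.g. `low`, eGFR < 60),
#' re-estimates the instrument weights on the restricted subjects and refits
#' the pooled estimate. Conditioning on the exposure can bias the causal
#' estimate, so the result carries an explicit caveat flag.
#'
#' @param genotypes genotype matrix (see [generate_cohort()]).
#' @param phenotypes phenotype table with derived `egfr` (see
#'   [derive_egfr()]).
#' @param summary outcome summary statistics.
#' @param category eGFR category to keep (`"low"`, `"intermediate"`,
#'   `"normal_high"`), or `NULL` for the full cohort.
#' @param score_type passed to [mr_fit()].
#' @param min_n minimum subgroup size for the weight regressions.
#' @return an `mr_fit` object with `subgroup` and `caveat` fields set.
#' @export
subgroup_estimate <- function(genotypes, phenotypes, summary,
                              category = "low",
                              score_type = c("weighted", "unweighted"),
                              min_n = 100) {
  score_type <- match.arg(score_type)
  .stop_if(is.null(phenotypes$egfr), "derive eGFR before subgroup analysis")
  keep <- if (is.null(category)) {
    rep(TRUE, nrow(phenotypes))
  } else {
    !is.na(phenotypes$egfr) & egfr_category(phenotypes$egfr) == category
  }
  .stop_if(sum(keep) < min_n,
           sprintf("subgroup '%s' has %d subjects (< %d): too small for weight regressions",
                   category %||% "full", sum(keep), min_n))
  w <- estimate_weights(genotypes[keep, , drop = FALSE],
                        phenotypes[keep, , drop = FALSE],
                        snp_info = attr(genotypes, "snp_info"))
  fit <- mr_fit(summary, w, score_type)
  fit$subgroup <- category %||% "full"
  if (!is.null(category)) {
    fit$caveat <- "weights conditioned on the exposure range; causal estimate may be biased"
  }
  fit
}

#' Reverse-direction Mendelian randomisation
#'
#' Tests whether the outcome causes the exposure by swapping roles: the
#' instrument is a weighted score of outcome-associated SNPs (weights = their
#' published per-SNP log odds ratios) and the "outcome" summary statistics are
#' per-SNP regression coefficients of the exposure (with SEs) estimated in the
#' cohort. The same pooled estimator applies; the estimate is in exposure
#' units per unit of the outcome gene score.
#'
#' @param chd_weights `instrument_weights`-shaped table of outcome-associated
#'   SNPs (`w` = published log OR per increasing allele).
#' @param egfr_summary per-SNP exposure regression coefficients and SEs in
#'   summary-statistics form (`beta`, `se` columns; continuous scale).
#' @return an `mr_fit` with `outcome_type = "continuous"`.
#' @export
reverse_mr <- function(chd_weights, egfr_summary) {
  fit <- mr_fit(egfr_summary, chd_weights, score_type = "weighted",
                outcome_type = "continuous")
  fit$call <- match.call()
  fit
}

#' Observational exposure-outcome association
#'
#' Study-adjusted logistic regression of the binary outcome on eGFR, with
#' optional further covariates (e.g. creatinine and serum urea). The odds
#' ratio is rescaled to `per_units` ml/min/1.73 m\eqn{^2}
#' (\eqn{OR_{10} = OR_1^{10}}).
#'
#' @param phenotypes phenotype table with `egfr`, `chd` and `study` columns.
#' @param covariates character vector of additional covariate column names.
#' @param per_units report the OR per this many eGFR units (1 or 10, say).
#' @param adjust_study include study as a categorical covariate (default).
#' @param by_category instead of the continuous slope, fit eGFR as the
#'   three-level category of [egfr_category()] and report odds ratios for
#'   `low` and `intermediate` relative to `normal_high`.
#' @return an object of class `"or_estimate"`: list with `or`, `ci`, `p`,
#'   `beta`, `se` (per single unit), `per_units`, `n`, `covariates`. With
#'   `by_category = TRUE`, `or`, `ci` and `p` are per-category (reference
#'   `normal_high`).
#' @export
observational_association <- function(phenotypes, covariates = character(0),
                                      per_units = 1, adjust_study = TRUE,
                                      by_category = FALSE) {
  if (by_category) {
    return(.observational_by_category(phenotypes, covariates, adjust_study))
  }
  .stop_if(is.null(phenotypes$egfr) || is.null(phenotypes$chd),
           "phenotype table needs 'egfr' and 'chd' columns")
  vars <- c("egfr", "chd", covariates)
  if (adjust_study && !is.null(phenotypes$study)) vars <- c(vars, "study")
  dat <- phenotypes[stats::complete.cases(phenotypes[vars]), vars, drop = FALSE]
  rhs <- c("egfr", covariates, if (adjust_study && !is.null(dat$study)) "study")
  f <- stats::as.formula(paste("chd ~", paste(rhs, collapse = " + ")))
  fit <- suppressWarnings(stats::glm(f, family = stats::binomial(), data = dat))
  co <- summary(fit)$coefficients
  beta <- co["egfr", 1]; se <- co["egfr", 2]
  if (!fit$converged || abs(beta) > 15) {
    warning("possible separation in logistic fit", call. = FALSE)
  }
  b <- beta * per_units; s <- se * per_units
  structure(list(
    or = exp(b), ci = exp(b + c(-1.96, 1.96) * s),
    p = 2 * stats::pnorm(abs(beta / se), lower.tail = FALSE),
    beta = beta, se = se, per_units = per_units, n = nrow(dat),
    covariates = covariates
  ), class = "or_estimate")
}

.observational_by_category <- function(phenotypes, covariates, adjust_study) {
  .stop_if(is.null(phenotypes$egfr) || is.null(phenotypes$chd),
           "phenotype table needs 'egfr' and 'chd' columns")
  dat <- phenotypes
  dat$egfr_cat <- stats::relevel(egfr_category(dat$egfr), "normal_high")
  vars <- c("egfr_cat", "chd", covariates)
  if (adjust_study && !is.null(dat$study)) vars <- c(vars, "study")
  dat <- dat[stats::complete.cases(dat[vars]), vars, drop = FALSE]
  rhs <- c("egfr_cat", covariates,
           if (adjust_study && !is.null(dat$study)) "study")
  f <- stats::as.formula(paste("chd ~", paste(rhs, collapse = " + ")))
  fit <- suppressWarnings(stats::glm(f, family = stats::binomial(), data = dat))
  co <- summary(fit)$coefficients
  lv <- c(low = "egfr_catlow", intermediate = "egfr_catintermediate")
  beta <- co[lv, 1]; se <- co[lv, 2]
  names(beta) <- names(se) <- names(lv)
  structure(list(
    or = exp(beta),
    ci = cbind(lower = exp(beta - 1.96 * se), upper = exp(beta + 1.96 * se)),
    p = 2 * stats::pnorm(abs(beta / se), lower.tail = FALSE),
    beta = beta, se = se, per_units = NA_real_, n = nrow(dat),
    covariates = covariates, reference = "normal_high"
  ), class = "or_estimate")
}

#' @export
print.or_estimate <- function(x, digits = 3, ...) {
  if (length(x$or) > 1L) {
    cat(sprintf("Observational association by eGFR category (ref %s), n = %d\n",
                x$reference, x$n))
    for (i in seq_along(x$or)) {
      cat(sprintf("  %s: OR %s  95%% CI [%s, %s]  p = %s\n",
                  names(x$or)[i], signif(x$or[i], digits),
                  signif(x$ci[i, 1], digits), signif(x$ci[i, 2], digits),
                  signif(x$p[i], 3)))
    }
    return(invisible(x))
  }
  cat(sprintf("Observational association (logistic), n = %d\n", x$n))
  cat(sprintf("  OR per %g ml/min/1.73m^2: %s  95%% CI [%s, %s]  p = %s\n",
              x$per_units, signif(x$or, digits), signif(x$ci[1], digits),
              signif(x$ci[2], digits), signif(x$p, 3)))
  if (length(x$covariates)) {
    cat("  adjusted for:", paste(x$covariates, collapse = ", "), "\n")
  }
  invisible(x)
}
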