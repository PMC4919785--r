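#' Per-SNP instrument weights from the exposure cohort
#'
#' One linear regression per SNP of eGFR on allele count (additive genotypic
#' coding) with study as a categorical covariate. Each SNP is then oriented to
#' its exposure-increasing allele, so the reported weight is the slope on the
#' oriented scale and is non-negative. A slope of exactly zero is oriented by
#' alphabetical allele label and flagged, so the output is deterministic.
#' Monomorphic SNPs have no defined weight and are excluded with a warning.
#'
#' @param genotypes subjects x SNPs matrix of allele counts (0/1/2) of each
#'   SNP's counted allele; column names are SNP ids. Allele labels come from
#'   `snp_info`.
#' @param phenotypes phenotype table aligned row-wise with `genotypes`;
#'   needs `egfr` (derive it with [derive_egfr()]) and `study` columns.
#' @param snp_info data frame `snp_id`, `counted_allele`, `other_allele`
#'   (defaults to `attr(genotypes, "snp_info")`).
#' @return data frame of class `"instrument_weights"`: `snp_id`,
#'   `increasing_allele`, `other_allele`, `w` (eGFR units per allele, >= 0),
#'   `se_w`, `source = "internal_regression"`. Excluded SNPs are listed in
#'   `attr(, "excluded")`; zero-slope tie-breaks in `attr(, "flagged")`.
#' @export
estimate_weights <- function(genotypes, phenotypes,
                             snp_info = attr(genotypes, "snp_info")) {
  .stop_if(is.null(phenotypes$egfr), "phenotype table lacks derived 'egfr'")
  .stop_if(all(is.na(phenotypes$egfr)), "all eGFR values missing")
  .stop_if(is.null(snp_info), "snp_info with allele labels is required")
  .stop_if(nrow(genotypes) != nrow(phenotypes),
           "genotypes and phenotypes must have the same subjects")
  study <- if (is.null(phenotypes$study)) NULL else
    as.integer(factor(phenotypes$study))
  rows <- vector("list", ncol(genotypes))
  excluded <- character(0); flagged <- character(0)
  for (j in seq_len(ncol(genotypes))) {
    id <- colnames(genotypes)[j]
    info <- snp_info[match(id, snp_info$snp_id), ]
    .stop_if(is.na(info$snp_id), sprintf("SNP %s missing from snp_info", id))
    g <- genotypes[, j]
    if (stats::var(g, na.rm = TRUE) == 0 || all(is.na(g))) {
      warning(sprintf("monomorphic SNP %s excluded: weight undefined", id),
              call. = FALSE)
      excluded <- c(excluded, id)
      next
    }
    fit <- .lm_xy(phenotypes$egfr, g, study)
    if (is.na(fit$beta)) {
      warning(sprintf("SNP %s excluded: weight regression failed", id),
              call. = FALSE)
      excluded <- c(excluded, id)
      next
    }
    if (fit$beta > 0) {
      inc <- info$counted_allele; oth <- info$other_allele; w <- fit$beta
    } else if (fit$beta < 0) {
      inc <- info$other_allele; oth <- info$counted_allele; w <- -fit$beta
    } else {
      alleles <- sort(c(info$counted_allele, info$other_allele))
      inc <- alleles[1]; oth <- alleles[2]; w <- 0
      flagged <- c(flagged, sprintf("%s: zero slope, oriented alphabetically", id))
    }
    rows[[j]] <- data.frame(snp_id = id, increasing_allele = inc,
                            other_allele = oth, w = w, se_w = fit$se,
                            source = "internal_regression",
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  .stop_if(is.null(out), "no SNP had an estimable weight")
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  attr(out, "flagged") <- flagged
  class(out) <- c("instrument_weights", "data.frame")
  out
}

#' Replace allele orientations with an external direction catalog
#'
#' For SNPs present in an external catalog of exposure-increasing alleles
#' (e.g. a larger published meta-analysis), the internal orientation is
#' replaced by the catalog direction; uncatalogued SNPs keep their internal
#' orientation. Flipping a SNP complements its oriented genotype coding
#' (\eqn{g \mapsto 2 - g}) in any score built afterwards, and negates the
#' internally estimated slope on the new orientation. A catalog allele that
#' matches neither of a SNP's alleles is a strand/label error: the SNP is
#' flagged and left unchanged.
#'
#' @param weights an `instrument_weights` table.
#' @param catalog data frame with `snp_id` and `increasing_allele` columns.
#' @return the weights table with updated orientations
#'   (`source = "external_catalog"` for flipped or confirmed SNPs);
#'   label errors accumulate in `attr(, "flagged")`.
#' @export
orient_from_external <- function(weights, catalog) {
  .check_weights(weights)
  .stop_if(is.null(catalog$snp_id) || is.null(catalog$increasing_allele),
           "catalog needs 'snp_id' and 'increasing_allele' columns")
  flagged <- attr(weights, "flagged") %||% character(0)
  for (i in seq_len(nrow(catalog))) {
    j <- match(catalog$snp_id[i], weights$snp_id)
    if (is.na(j)) next
    cat_allele <- catalog$increasing_allele[i]
    if (cat_allele == weights$increasing_allele[j]) {
      weights$source[j] <- "external_catalog"
    } else if (cat_allele == weights$other_allele[j]) {
      weights$other_allele[j] <- weights$increasing_allele[j]
      weights$increasing_allele[j] <- cat_allele
      weights$w[j] <- -weights$w[j]
      weights$source[j] <- "external_catalog"
    } else {
      msg <- sprintf("%s: catalog allele %s matches neither %s nor %s",
                     weights$snp_id[j], cat_allele,
                     weights$increasing_allele[j], weights$other_allele[j])
      warning(msg, call. = FALSE)
      flagged <- c(flagged, msg)
    }
  }
  attr(weights, "flagged") <- flagged
  weights
}

#' Build an allelic gene score
#'
#' Unweighted score: per-subject count of exposure-increasing alleles summed
#' over SNPs (range 0 to 2 x number of SNPs). Weighted score: the
#' weight-multiplied sum. Genotypes are oriented to each SNP's increasing
#' allele first (counted-allele coding is complemented where the orientation
#' differs). Missing genotypes are mean-imputed from the non-missing oriented
#' allele counts of that SNP within study; a subject missing all genotypes
#' gets a missing score.
#'
#' @inheritParams estimate_weights
#' @param weights `instrument_weights` table defining SNP set, orientation
#'   and (for the weighted score) the weights.
#' @param type `"unweighted"` or `"weighted"`.
#' @param study optional per-subject study labels for within-study imputation
#'   of missing genotypes.
#' @return numeric score vector (attribute `score_type` set).
#' @export
build_score <- function(genotypes, weights, type = c("unweighted", "weighted"),
                        study = NULL, snp_info = attr(genotypes, "snp_info")) {
  type <- match.arg(type)
  .check_weights(weights)
  .stop_if(is.null(snp_info), "snp_info with allele labels is required")
  miss <- setdiff(weights$snp_id, colnames(genotypes))
  .stop_if(length(miss) > 0,
           "SNPs absent from genotype matrix: ", paste(miss, collapse = ", "))
  G <- genotypes[, weights$snp_id, drop = FALSE]
  info <- snp_info[match(weights$snp_id, snp_info$snp_id), ]
  for (j in seq_len(ncol(G))) {
    inc <- weights$increasing_allele[j]
    if (inc == info$other_allele[j]) {
      G[, j] <- 2 - G[, j]
    } else if (inc != info$counted_allele[j]) {
      stop(sprintf("orientation allele %s not among alleles of %s", inc,
                   weights$snp_id[j]), call. = FALSE)
    }
  }
  all_missing <- rowSums(!is.na(G)) == 0L
  if (anyNA(G)) {
    grp <- if (is.null(study)) rep(1L, nrow(G)) else as.integer(factor(study))
    for (j in seq_len(ncol(G))) {
      na <- is.na(G[, j])
      if (!any(na)) next
      mu <- tapply(G[, j], grp, mean, na.rm = TRUE)
      G[na, j] <- mu[as.character(grp[na])]
    }
  }
  score <- if (type == "unweighted") {
    rowSums(G)
  } else {
    as.vector(G %*% weights$w)
  }
  score[all_missing] <- NA_real_
  attr(score, "score_type") <- type
  attr(score, "snps") <- weights$snp_id
  score
}

#' Instrument strength of a gene score
#'
#' Study-adjusted linear regression of eGFR on the score; reports the partial
#' R-squared of the score, its F statistic (for a single predictor,
#' \eqn{F = t^2}), and the number of subjects used. F well above 10 indicates
#' a strong instrument with limited weak-instrument bias.
#'
#' @param score numeric gene score (see [build_score()]).
#' @param phenotypes phenotype table with `egfr` and `study` columns.
#' @return object of class `"instrument_strength"`: list with `r_squared`,
#'   `f_statistic`, `n_used`.
#' @export
instrument_strength <- function(score, phenotypes) {
  .stop_if(is.null(phenotypes$egfr), "phenotype table lacks derived 'egfr'")
  ok <- is.finite(score) & is.finite(phenotypes$egfr)
  .stop_if(sum(ok) < 3L, "need at least 3 subjects with score and eGFR")
  .stop_if(stats::var(score[ok]) == 0, "zero-variance score")
  fit <- .lm_xy(phenotypes$egfr, score, phenotypes$study)
  f <- fit$t^2
  r2 <- if (is.infinite(f)) 1 else f / (f + fit$df)
  structure(list(r_squared = r2, f_statistic = f,
                 n_used = fit$n), class = "instrument_strength")
}

#' @export
print.instrument_strength <- function(x, ...) {
  cat(sprintf("Instrument strength: partial R^2 = %.4f, F = %.1f, n = %d\n",
              x$r_squared, x$f_statistic, x$n_used))
  invisible(x)
}
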