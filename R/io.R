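# Readers and writers for the plain-text interchange formats: phenotype CSV
# (missing = empty field), genotype TSV (subject id + one 0/1/2 column per
# SNP), the summary-statistics TSV dialect, instrument-weight TSV, and YAML
# simulation configs.

#' Read / write outcome summary statistics
#'
#' The TSV dialect has the fixed header
#' `snp_id effect_allele other_allele beta se n_cases n_controls source`;
#' `beta` holds natural-log odds ratios for binary outcomes. Files that
#' report an odds-ratio column instead can be read with `or_column = TRUE`,
#' which takes logs on input.
#'
#' @param file path to a TSV file.
#' @param or_column the file carries an `or` column in place of `beta`.
#' @return data frame of class `"outcome_summary"`.
#' @export
read_summary_stats <- function(file, or_column = FALSE) {
  x <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (or_column) {
    .stop_if(is.null(x$or), "or_column = TRUE but no 'or' column present")
    .stop_if(any(x$or <= 0, na.rm = TRUE), "odds ratios must be positive")
    x$beta <- log(x$or)
    x$or <- NULL
  }
  .check_summary(x)
  class(x) <- c("outcome_summary", "data.frame")
  x
}

#' @param x an `outcome_summary` data frame.
#' @rdname read_summary_stats
#' @export
write_summary_stats <- function(x, file) {
  cols <- c("snp_id", "effect_allele", "other_allele", "beta", "se",
            "n_cases", "n_controls", "source")
  for (col in setdiff(cols, names(x))) x[[col]] <- NA
  utils::write.table(x[cols], file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Read / write instrument weights
#'
#' TSV with columns `snp_id`, `increasing_allele`, `other_allele`, `w`,
#' `se_w`, `source`.
#'
#' @param file path to a TSV file.
#' @return data frame of class `"instrument_weights"`.
#' @export
read_weights <- function(file) {
  x <- utils::read.delim(file, stringsAsFactors = FALSE)
  .check_weights(x)
  class(x) <- c("instrument_weights", "data.frame")
  x
}

#' @param x an `instrument_weights` data frame.
#' @rdname read_weights
#' @export
write_weights <- function(x, file) {
  cols <- c("snp_id", "increasing_allele", "other_allele", "w", "se_w",
            "source")
  for (col in setdiff(cols, names(x))) x[[col]] <- NA
  utils::write.table(as.data.frame(x)[cols], file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Read / write a phenotype table (CSV, missing = empty field)
#'
#' @param file path to a CSV file.
#' @return data frame with `study` as a factor.
#' @export
read_phenotypes <- function(file) {
  x <- utils::read.csv(file, stringsAsFactors = FALSE, na.strings = "")
  if (!is.null(x$study)) x$study <- factor(x$study)
  x
}

#' @param x a phenotype data frame.
#' @rdname read_phenotypes
#' @export
write_phenotypes <- function(x, file) {
  utils::write.csv(as.data.frame(x), file, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(file)
}

#' Read / write a genotype matrix (TSV: subject id + one column per SNP)
#'
#' SNP allele metadata travels in a sidecar table written by
#' [write_snp_info()]; [read_genotypes()] re-attaches it when given.
#'
#' @param file path to a TSV file.
#' @param snp_info optional snp_info data frame (or path to one) to attach.
#' @return integer matrix with subject ids as row names.
#' @export
read_genotypes <- function(file, snp_info = NULL) {
  x <- utils::read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- x[[1]]
  if (!is.null(snp_info)) {
    if (is.character(snp_info)) snp_info <- read_snp_info(snp_info)
    attr(m, "snp_info") <- snp_info
  }
  m
}

#' @param x a genotype matrix.
#' @rdname read_genotypes
#' @export
write_genotypes <- function(x, file) {
  df <- data.frame(subject_id = rownames(x) %||% seq_len(nrow(x)),
                   as.data.frame(x), check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname read_genotypes
#' @export
read_snp_info <- function(file) {
  utils::read.delim(file, stringsAsFactors = FALSE)
}

#' @rdname read_genotypes
#' @export
write_snp_info <- function(x, file) {
  utils::write.table(x, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read / write a simulation config as YAML
#'
#' The document mirrors the [sim_config()] fields; `snps` and `traits` are
#' written as lists of records.
#'
#' @param file path to a YAML file.
#' @return a validated `sim_config`.
#' @export
read_sim_config <- function(file) {
  y <- yaml::read_yaml(file)
  snps <- do.call(rbind, lapply(y$snps, function(r)
    data.frame(r, stringsAsFactors = FALSE)))
  traits <- lapply(y$traits, function(tr) do.call(trait_spec, tr))
  av <- if (!is.null(y$outcome$availability)) {
    matrix(unlist(y$outcome$availability), ncol = 3, byrow = TRUE)
  } else NULL
  sim_config(
    n_subjects = y$n_subjects, n_studies = y$n_studies, snps = snps,
    target_score_r2 = y$target_score_r2, traits = traits,
    true_causal_logOR = y$true_causal_logOR,
    baseline_chd_logodds = y$baseline_chd_logodds,
    egfr_noise_sd = y$egfr_noise_sd, egfr_mean = y$egfr_mean,
    study_sd = y$study_sd, egfr_studies = y$egfr_studies,
    outcome = list(n_cases = y$outcome$n_cases,
                   n_controls = y$outcome$n_controls, availability = av),
    outcome_fractions = unlist(y$outcome_fractions),
    seed = y$seed
  )
}

#' @param config a `sim_config` object.
#' @rdname read_sim_config
#' @export
write_sim_config <- function(config, file) {
  y <- unclass(config)
  y$snps <- lapply(seq_len(nrow(config$snps)), function(i)
    as.list(config$snps[i, ]))
  y$traits <- config$traits
  y$outcome$availability <- lapply(
    seq_len(nrow(config$outcome$availability)),
    function(i) as.list(config$outcome$availability[i, ]))
  yaml::write_yaml(y, file)
  invisible(file)
}
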