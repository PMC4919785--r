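#' Estimated glomerular filtration rate by the four-variable MDRD equation
#'
#' Computes eGFR (ml/min/1.73 m\eqn{^2}) from serum creatinine, age, sex and
#' ethnicity using the IDMS-traceable four-variable MDRD Study equation:
#' \deqn{eGFR = 175 \times Scr^{-1.154} \times age^{-0.203} \times 0.742^{[female]} \times 1.212^{[black]}}
#' Creatinine must be in mg/dL; use [creatinine_to_mgdl()] to convert
#' micromol/L values first. The conversion is never applied implicitly,
#' because silent unit mixing is the classic eGFR bug.
#'
#' Missing creatinine propagates to a missing eGFR (a subject without a
#' measurement is not an error); non-positive creatinine or age is a domain
#' error signalling a corrupt input row.
#'
#' @param creatinine serum creatinine, mg/dL (numeric, NA allowed).
#' @param age age in years (> 0).
#' @param female logical (or 0/1): subject is female.
#' @param black logical (or 0/1): subject is of black ethnicity. The cohorts
#'   this package emulates are largely of European ancestry, so the default is
#'   `FALSE`, but the term is implemented.
#' @return numeric vector of eGFR values, ml/min/1.73 m\eqn{^2}.
#' @seealso [egfr_category()], [derive_egfr()]
#' @examples
#' mdrd_egfr(1.0, age = 60, female = FALSE) # about 76.2
#' mdrd_egfr(1.0, age = 60, female = TRUE) / mdrd_egfr(1.0, age = 60, female = FALSE)
#' @export
mdrd_egfr <- function(creatinine, age, female, black = FALSE) {
  .stop_if(any(creatinine <= 0, na.rm = TRUE),
           "non-positive serum creatinine: corrupt input row")
  .stop_if(any(age <= 0, na.rm = TRUE) || anyNA(age),
           "age must be positive and non-missing")
  female <- as.logical(female)
  black <- as.logical(black)
  175 * creatinine^(-1.154) * age^(-0.203) *
    ifelse(female, 0.742, 1) * ifelse(black, 1.212, 1)
}

#' Convert serum creatinine to mg/dL
#'
#' Divides micromol/L values by 88.4. Provided as an explicit helper so that
#' unit conversion is always a visible step in an analysis.
#'
#' @param x creatinine values.
#' @param from input unit, `"umoll"` (micromol/L) or `"mgdl"` (no-op).
#' @return creatinine in mg/dL.
#' @export
creatinine_to_mgdl <- function(x, from = c("umoll", "mgdl")) {
  from <- match.arg(from)
  if (from == "umoll") x / 88.4 else x
}

#' Categorise eGFR into the conventional clinical ranges
#'
#' `low` is eGFR < 60, `intermediate` is 60 to <90 and `normal_high` is
#' \eqn{\ge} 90 ml/min/1.73 m\eqn{^2}. The boundaries belong to the upper
#' category: 60 is intermediate, 90 is normal/high.
#'
#' @param egfr eGFR values, ml/min/1.73 m\eqn{^2} (> 0; NA allowed).
#' @return factor with levels `low`, `intermediate`, `normal_high`.
#' @export
egfr_category <- function(egfr) {
  .stop_if(any(egfr <= 0, na.rm = TRUE), "eGFR must be positive")
  cut(as.numeric(egfr), breaks = c(0, 60, 90, Inf), right = FALSE,
      labels = c("low", "intermediate", "normal_high"))
}

#' Add derived eGFR columns to a phenotype table
#'
#' Applies [mdrd_egfr()] row-wise to a phenotype table (columns `creatinine`,
#' `age`, `female` and optionally `black`) and appends `egfr` and
#' `egfr_category` columns. Rows with missing creatinine get missing eGFR.
#'
#' @param phenotypes data frame with `creatinine`, `age`, `female` and
#'   optionally `black` columns.
#' @param creatinine_units `"mgdl"` or `"umoll"`; micromol/L values are
#'   converted before evaluation.
#' @param ethnicity_correction apply the 1.212 black-ethnicity factor where a
#'   `black` column is present (default `TRUE`; without the column no
#'   correction is applied).
#' @return the phenotype table with `egfr` and `egfr_category` columns.
#' @export
derive_egfr <- function(phenotypes, creatinine_units = c("mgdl", "umoll"),
                        ethnicity_correction = TRUE) {
  creatinine_units <- match.arg(creatinine_units)
  for (col in c("creatinine", "age", "female")) {
    .stop_if(is.null(phenotypes[[col]]),
             sprintf("phenotype table lacks a '%s' column", col))
  }
  cr <- creatinine_to_mgdl(phenotypes$creatinine, creatinine_units)
  black <- if (ethnicity_correction && !is.null(phenotypes$black)) {
    phenotypes$black
  } else FALSE
  phenotypes$egfr <- mdrd_egfr(cr, phenotypes$age, phenotypes$female, black)
  phenotypes$egfr_category <- egfr_category(phenotypes$egfr)
  phenotypes
}

# Inverse of the MDRD equation: the creatinine giving a target eGFR for given
# demographics. Used by the generator so that derived eGFR matches the
# simulated ground truth exactly.
.creatinine_from_egfr <- function(egfr, age, female, black = FALSE) {
  denom <- 175 * age^(-0.203) * ifelse(as.logical(female), 0.742, 1) *
    ifelse(as.logical(black), 1.212, 1)
  (egfr / denom)^(-1 / 1.154)
}
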