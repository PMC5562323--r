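# Seven serum liver-fibrosis indexes.
#
# Unit conventions (fixed by the cutoffs the scores are used with):
#   AST, ALT, GGT in IU/L; PLT in 10^9/L; albumin on the ~20-55 numeric
#   scale; cholesterol in mmol/L; age in years; INR dimensionless.
# All vectorised over patients; an index is NA where a needed input is
# missing, and errors on non-positive inputs.

.check_pos <- function(..., .names) {
  args <- list(...)
  for (i in seq_along(args)) {
    x <- args[[i]]
    if (any(!is.na(x) & (x <= 0 | !is.finite(x))))
      stop(.names[i], " must be strictly positive and finite")
  }
}

#' AST-to-ALT ratio (AAR)
#'
#' \code{AAR = AST / ALT}.
#' @param ast,alt serum aminotransferases, IU/L (> 0).
#' @return numeric score vector.
#' @export
index_aar <- function(ast, alt) {
  .check_pos(ast, alt, .names = c("ast", "alt"))
  ast / alt
}

#' AST-to-platelet ratio index (APRI)
#'
#' \code{APRI = ((AST / ULN) * 100) / PLT}, where ULN is the upper limit of
#' normal for AST (default 40 IU/L, the conventional value from the original
#' APRI derivation; configurable because the study value is not pinned).
#' @param ast AST, IU/L (> 0).
#' @param plt platelet count, 10^9/L (> 0).
#' @param ast_uln AST upper limit of normal, IU/L (> 0).
#' @return numeric score vector.
#' @export
index_apri <- function(ast, plt, ast_uln = 40) {
  .check_pos(ast, plt, ast_uln, .names = c("ast", "plt", "ast_uln"))
  ((ast / ast_uln) * 100) / plt
}

#' Fibrosis index (FI)
#'
#' \code{FI = 8 - 0.01 * PLT - ALB}, albumin on the working numeric scale.
#' @param plt platelet count, 10^9/L (> 0).
#' @param albumin serum albumin (~20-55 scale).
#' @return numeric score vector (typically negative on this scale).
#' @export
index_fi <- function(plt, albumin) {
  .check_pos(plt, albumin, .names = c("plt", "albumin"))
  8 - 0.01 * plt - albumin
}

#' FIB-4 index
#'
#' \code{FIB-4 = (age * AST) / (PLT * sqrt(ALT))}.
#' @param age years (> 0).
#' @param ast,alt IU/L (> 0).
#' @param plt 10^9/L (> 0).
#' @return numeric score vector.
#' @export
index_fib4 <- function(age, ast, plt, alt) {
  .check_pos(age, ast, plt, alt, .names = c("age", "ast", "plt", "alt"))
  (age * ast) / (plt * sqrt(alt))
}

#' King's score
#'
#' \code{King's = age * AST * INR / PLT}.
#' @param age years (> 0).
#' @param ast IU/L (> 0).
#' @param inr international normalised ratio (> 0).
#' @param plt 10^9/L (> 0).
#' @return numeric score vector.
#' @export
index_kings <- function(age, ast, inr, plt) {
  .check_pos(age, ast, inr, plt, .names = c("age", "ast", "inr", "plt"))
  age * ast * inr / plt
}

#' Forns index
#'
#' \code{Forns = 7.811 - 3.131 ln(PLT) + 0.781 ln(GGT) + 3.467 ln(age)
#' - 0.014 * cholesterol}, with cholesterol in mmol/L (the convention the
#' cutoff 11.05 is consistent with; the original Forns publication used
#' mg/dL).
#' @param plt 10^9/L (> 0).
#' @param ggt gamma-glutamyl transferase, IU/L (> 0).
#' @param age years (> 0).
#' @param cholesterol mmol/L (> 0).
#' @return numeric score vector.
#' @export
index_forns <- function(plt, ggt, age, cholesterol) {
  .check_pos(plt, ggt, age, cholesterol,
             .names = c("plt", "ggt", "age", "cholesterol"))
  7.811 - 3.131 * log(plt) + 0.781 * log(ggt) + 3.467 * log(age) -
    0.014 * cholesterol
}

#' Lok index (linear predictor form)
#'
#' \code{Lok = -5.56 - 0.0089 * PLT + 1.26 * (AST/ALT) + 5.27 * INR}.
#' This is the linear predictor, not the original logistic probability:
#' the screening cutoffs used with it (1.30, 1.40) exceed 1 and are only
#' consistent with the linear form.
#' @param plt 10^9/L (> 0).
#' @param ast,alt IU/L (> 0).
#' @param inr international normalised ratio (> 0).
#' @return numeric score vector.
#' @export
index_lok <- function(plt, ast, alt, inr) {
  .check_pos(plt, ast, alt, inr, .names = c("plt", "ast", "alt", "inr"))
  -5.56 - 0.0089 * plt + 1.26 * (ast / alt) + 5.27 * inr
}

#' Names of the seven fibrosis indexes
#' @return character vector in canonical order.
#' @export
index_names <- function() c("aar", "apri", "fi", "fib4", "kings", "forns",
                            "lok")

#' Compute the seven-index panel for a cohort
#'
#' Each index is computed from the canonical cohort columns; a patient
#' missing an input for one index gets NA for that index only (per-index
#' exclusion), with exclusion counts recorded in the \code{"exclusions"}
#' attribute. Only Forns needs cholesterol and GGT, so their absence never
#' invalidates a whole record.
#'
#' @param cohort \code{ph_cohort} or data frame with the canonical columns.
#' @param ast_uln AST upper limit of normal for APRI, IU/L.
#' @return data frame with columns \code{id} and the seven scores
#'   (\code{aar}, \code{apri}, \code{fi}, \code{fib4}, \code{kings},
#'   \code{forns}, \code{lok}).
#' @examples
#' rec <- data.frame(id = "t1", age = 52.55, sex = "male", ast = 47.21,
#'                   alt = 39.19, ggt = 61.04, albumin = 33.29,
#'                   cholesterol = 3.81, plt = 99.5, inr = 1.24)
#' compute_panel(rec)
#' @export
compute_panel <- function(cohort, ast_uln = 40) {
  df <- as.data.frame(cohort)
  panel <- data.frame(
    id = df$id,
    aar = index_aar(df$ast, df$alt),
    apri = index_apri(df$ast, df$plt, ast_uln),
    fi = index_fi(df$plt, df$albumin),
    fib4 = index_fib4(df$age, df$ast, df$plt, df$alt),
    kings = index_kings(df$age, df$ast, df$inr, df$plt),
    forns = index_forns(df$plt, df$ggt, df$age, df$cholesterol),
    lok = index_lok(df$plt, df$ast, df$alt, df$inr),
    stringsAsFactors = FALSE)
  excl <- vapply(panel[index_names()], function(x) sum(is.na(x)), 0L)
  attr(panel, "exclusions") <- excl
  panel
}
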