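# Dual-index screening rule: two fibrosis indexes each at a fixed cutoff.
#
# Two positivity conventions are supported because published combined-rule
# metrics are ambiguous about the denominator:
#   both_above_vs_rest - positive iff both scores >= their cutoffs; metrics
#                        over all patients (the screening reading).
#   concordant_only    - metrics only among patients on whom the two
#                        indexes agree; discordant patients are counted but
#                        excluded from the 2x2 table.

#' Define a dual-index screening rule
#' @param index_a,index_b names of the two indexes (must differ).
#' @param cutoff_a,cutoff_b finite score cutoffs.
#' @param positivity \code{"both_above_vs_rest"} (default) or
#'   \code{"concordant_only"}.
#' @return object of class \code{ph_combo_rule}.
#' @export
combo_rule <- function(index_a, index_b, cutoff_a, cutoff_b,
                       positivity = c("both_above_vs_rest",
                                      "concordant_only")) {
  positivity <- match.arg(positivity)
  if (identical(index_a, index_b)) stop("the two indexes must be distinct")
  if (!is.finite(cutoff_a) || !is.finite(cutoff_b))
    stop("cutoffs must be finite")
  structure(list(index_a = index_a, index_b = index_b,
                 cutoff_a = cutoff_a, cutoff_b = cutoff_b,
                 positivity = positivity),
            class = "ph_combo_rule")
}

#' Apply a dual-index screening rule to a cohort
#'
#' Counts concordant-positive (both scores >= cutoffs), concordant-negative
#' (both below) and discordant patients, and evaluates the rule's
#' diagnostic metrics under the rule's positivity convention. Patients with
#' a missing score for either index are excluded (count reported).
#'
#' @param scores_a,scores_b per-patient scores for the two indexes.
#' @param labels logical (or 0/1) disease status.
#' @param rule \code{ph_combo_rule}.
#' @return list with \code{n}, \code{n_excluded}, \code{n_both_above},
#'   \code{n_both_below}, \code{n_discordant}, \code{agreement_fraction}
#'   and \code{metrics} (\code{ph_metrics}).
#' @export
apply_combo <- function(scores_a, scores_b, labels, rule) {
  stopifnot(inherits(rule, "ph_combo_rule"))
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    stop("scores and labels must have the same length")
  labels <- as.logical(labels)
  keep <- !is.na(scores_a) & !is.na(scores_b) & !is.na(labels)
  n_excluded <- sum(!keep)
  a <- scores_a[keep]; b <- scores_b[keep]; y <- labels[keep]
  n <- length(a)
  if (n == 0L) stop("no patients with complete scores")
  above_a <- a >= rule$cutoff_a
  above_b <- b >= rule$cutoff_b
  both_above <- above_a & above_b
  both_below <- !above_a & !above_b
  discordant <- !(both_above | both_below)
  metrics <- if (rule$positivity == "both_above_vs_rest") {
    metrics_from_confusion(confusion_table(
      tp = sum(both_above & y), fp = sum(both_above & !y),
      tn = sum(!both_above & !y), fn = sum(!both_above & y)))
  } else {
    conc <- !discordant
    metrics_from_confusion(confusion_table(
      tp = sum(both_above & y), fp = sum(both_above & !y),
      tn = sum(both_below[conc] & !y[conc]),
      fn = sum(both_below[conc] & y[conc])))
  }
  list(n = n, n_excluded = n_excluded,
       n_both_above = sum(both_above), n_both_below = sum(both_below),
       n_discordant = sum(discordant),
       agreement_fraction = (sum(both_above) + sum(both_below)) / n,
       rule = rule, metrics = metrics)
}
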