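# Empirical ROC analysis with the conventions used throughout the package:
# higher score means diseased, and a patient is test-positive when
# score >= cutoff. Candidate cutoffs are the unique observed scores plus a
# sentinel above the maximum (the all-negative operating point).

.check_scores <- function(scores_pos, scores_neg) {
  if (length(scores_pos) == 0L || length(scores_neg) == 0L)
    stop("both score classes must be non-empty")
  if (any(!is.finite(scores_pos)) || any(!is.finite(scores_neg)))
    stop("scores must be finite")
}

#' Empirical ROC curve
#'
#' Enumerates every unique observed score as a cutoff (positivity:
#' score >= cutoff) plus a sentinel above the maximum, so the curve always
#' contains the endpoints (sens 1, spec 0) and (sens 0, spec 1).
#'
#' @param scores_pos scores of diseased patients.
#' @param scores_neg scores of non-diseased patients.
#' @return object of class \code{ph_roc}: data frame of operating points
#'   (\code{cutoff}, \code{sens}, \code{spec}) ordered by increasing cutoff,
#'   with attributes \code{n_pos}, \code{n_neg}.
#' @export
empirical_roc <- function(scores_pos, scores_neg) {
  .check_scores(scores_pos, scores_neg)
  all_scores <- c(scores_pos, scores_neg)
  cutoffs <- c(sort(unique(all_scores)), max(all_scores) + 1)
  sens <- vapply(cutoffs, function(ct) mean(scores_pos >= ct), 0)
  spec <- vapply(cutoffs, function(ct) mean(scores_neg < ct), 0)
  structure(data.frame(cutoff = cutoffs, sens = sens, spec = spec),
            class = c("ph_roc", "data.frame"),
            n_pos = length(scores_pos), n_neg = length(scores_neg),
            direction = "higher score => diseased")
}

#' Empirical AUC with the Hanley-McNeil standard error
#'
#' The AUC is the Mann-Whitney statistic with ties counted one half:
#' the mean over all diseased/non-diseased pairs of
#' I(score_pos > score_neg) + 0.5 I(equal). The standard error uses the
#' Hanley-McNeil formula with auxiliary quantities Q1 = A/(2-A) and
#' Q2 = 2A^2/(1+A); the 95% CI is the normal approximation A +/- 1.96 SE
#' truncated to [0, 1].
#'
#' @inheritParams empirical_roc
#' @return object of class \code{ph_auc}: list with \code{auc}, \code{se},
#'   \code{ci95} (length-2), \code{q1}, \code{q2}, \code{n_pos},
#'   \code{n_neg}.
#' @export
roc_auc <- function(scores_pos, scores_neg) {
  .check_scores(scores_pos, scores_neg)
  m <- length(scores_pos)
  n <- length(scores_neg)
  # midrank formula == pairwise mean with ties counted 1/2
  r <- rank(c(scores_pos, scores_neg), ties.method = "average")
  a <- (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  se <- sqrt((a * (1 - a) + (m - 1) * (q1 - a^2) + (n - 1) * (q2 - a^2)) /
               (m * n))
  ci <- pmin(1, pmax(0, a + c(-1, 1) * 1.96 * se))
  structure(list(auc = a, se = se, ci95 = ci, q1 = q1, q2 = q2,
                 n_pos = m, n_neg = n),
            class = "ph_auc")
}

#' @export
print.ph_auc <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f), SE %.4f; n+ = %d, n- = %d\n",
              x$auc, x$ci95[1], x$ci95[2], x$se, x$n_pos, x$n_neg))
  invisible(x)
}

#' Youden-optimal cutoff
#'
#' Returns the cutoff maximising the Youden index J = sens + spec - 1 over
#' all empirical operating points. Ties are broken in favour of the highest
#' sensitivity (the screening-oriented choice), then the lowest cutoff.
#'
#' @inheritParams empirical_roc
#' @return list with \code{cutoff}, \code{youden_j}, \code{sens},
#'   \code{spec}.
#' @export
youden_cutoff <- function(scores_pos, scores_neg) {
  curve <- empirical_roc(scores_pos, scores_neg)
  j <- curve$sens + curve$spec - 1
  best <- which(j >= max(j) - 1e-12)
  best <- best[order(-curve$sens[best], curve$cutoff[best])][1]
  list(cutoff = curve$cutoff[best], youden_j = j[best],
       sens = curve$sens[best], spec = curve$spec[best])
}

# Placement values (DeLong): for each diseased patient, the fraction of
# non-diseased patients it outranks (ties 1/2), and vice versa.
.placements <- function(scores_pos, scores_neg) {
  v10 <- vapply(scores_pos, function(x)
    mean((x > scores_neg) + 0.5 * (x == scores_neg)), 0)
  v01 <- vapply(scores_neg, function(y)
    mean((scores_pos > y) + 0.5 * (scores_pos == y)), 0)
  list(v10 = v10, v01 = v01)
}

#' Compare two correlated (paired) AUCs
#'
#' Both markers are measured on the same patients, so their AUCs are
#' correlated. The difference is tested with a placement-based
#' (DeLong-style) variance-covariance estimate:
#' z = (A_a - A_b) / sqrt(var_a + var_b - 2 cov_ab), two-sided normal p.
#' When the difference and its variance are both zero (e.g. identical
#' markers) z = 0 and p = 1.
#'
#' @param scores_a,scores_b per-patient scores for the two markers, same
#'   patients in the same order.
#' @param labels logical (or 0/1) disease status per patient.
#' @return list with \code{auc_a}, \code{auc_b}, \code{delta_auc},
#'   \code{var_a}, \code{var_b}, \code{cov_ab}, \code{z}, \code{p}.
#' @export
compare_auc_paired <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    stop("scores_a, scores_b and labels must have the same length")
  labels <- as.logical(labels)
  if (!any(labels) || all(labels))
    stop("both disease classes must be represented")
  m <- sum(labels)
  n <- sum(!labels)
  pa <- .placements(scores_a[labels], scores_a[!labels])
  pb <- .placements(scores_b[labels], scores_b[!labels])
  auc_a <- mean(pa$v10)
  auc_b <- mean(pb$v10)
  cov2 <- function(x, y) if (length(x) > 1) stats::cov(x, y) else 0
  var_a <- cov2(pa$v10, pa$v10) / m + cov2(pa$v01, pa$v01) / n
  var_b <- cov2(pb$v10, pb$v10) / m + cov2(pb$v01, pb$v01) / n
  cov_ab <- cov2(pa$v10, pb$v10) / m + cov2(pa$v01, pb$v01) / n
  delta <- auc_a - auc_b
  v <- var_a + var_b - 2 * cov_ab
  if (v <= .Machine$double.eps) {
    z <- 0
    p <- 1
    if (abs(delta) > 1e-12)
      warning("zero variance estimate with non-zero AUC difference")
  } else {
    z <- delta / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = auc_a, auc_b = auc_b, delta_auc = delta,
       var_a = var_a, var_b = var_b, cov_ab = cov_ab, z = z, p = p)
}
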