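# Diagnostic-metric panels from 2x2 confusion tables.
#
# Conventions: test-positive means score >= cutoff; proportions are stored
# in [0,1] and printed as percentages to 2 decimals; Clopper-Pearson exact
# binomial 95% CIs for sens/spec/PPV/NPV/accuracy; log-variance method for
# the likelihood-ratio CIs. Ratios with zero denominators are flagged as
# undefined (NA) rather than returned as Inf.

#' Construct a confusion table
#' @param tp,fp,tn,fn non-negative integer cell counts.
#' @return object of class \code{ph_confusion}.
#' @export
confusion_table <- function(tp, fp, tn, fn) {
  cells <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("confusion cells must be non-negative integers")
  structure(as.list(round(cells)), class = "ph_confusion")
}

#' @export
print.ph_confusion <- function(x, ...) {
  cat(sprintf("2x2 table: TP %d, FP %d, TN %d, FN %d (n = %d)\n",
              x$tp, x$fp, x$tn, x$fn, x$tp + x$fp + x$tn + x$fn))
  invisible(x)
}

#' Confusion table from scores at a fixed cutoff
#'
#' A patient is test-positive when score >= cutoff.
#' @param scores numeric per-patient scores.
#' @param labels logical (or 0/1) disease status.
#' @param cutoff finite cutoff value.
#' @return \code{ph_confusion} object.
#' @export
confusion_from_scores <- function(scores, labels, cutoff) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels))
    stop("scores and labels must have the same length")
  if (!is.finite(cutoff)) stop("cutoff must be finite")
  if (!any(labels) || all(labels))
    stop("both disease classes must be represented")
  pos <- scores >= cutoff
  confusion_table(tp = sum(pos & labels), fp = sum(pos & !labels),
                  tn = sum(!pos & !labels), fn = sum(!pos & labels))
}

# Clopper-Pearson exact binomial CI via beta quantiles.
.clopper_pearson <- function(x, n, level = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  alpha <- 1 - level
  lo <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  c(lo, hi)
}

# log-variance CI for a likelihood ratio (Simel et al. convention)
.lr_ci <- function(lr, num_x, num_n, den_x, den_n, level = 0.95) {
  if (is.na(lr) || lr <= 0 || num_x == 0 || den_x == 0)
    return(c(NA_real_, NA_real_))
  se_log <- sqrt(1 / num_x - 1 / num_n + 1 / den_x - 1 / den_n)
  z <- stats::qnorm(1 - (1 - level) / 2)
  exp(log(lr) + c(-1, 1) * z * se_log)
}

#' Full diagnostic-metric panel from a confusion table
#'
#' Computes sensitivity, specificity, PPV, NPV, accuracy (all in [0,1] with
#' Clopper-Pearson exact 95% CIs) and the positive/negative likelihood
#' ratios (+LR = sens/(1-spec), -LR = (1-sens)/spec, log-method CIs).
#' Zero-denominator ratios are returned as NA with the metric name listed
#' in \code{undefined}.
#'
#' @param ct \code{ph_confusion} object (or list with tp, fp, tn, fn).
#' @return object of class \code{ph_metrics}: list with the point
#'   estimates, a \code{ci} list of length-2 vectors, \code{undefined}
#'   (character vector), and the source counts.
#' @export
metrics_from_confusion <- function(ct) {
  tp <- ct$tp; fp <- ct$fp; tn <- ct$tn; fn <- ct$fn
  n_pos <- tp + fn
  n_neg <- tn + fp
  n <- n_pos + n_neg
  if (n_pos == 0 || n_neg == 0)
    stop("both disease classes must have positive counts")
  undefined <- character()
  safe_div <- function(num, den, name) {
    if (den == 0) { undefined <<- c(undefined, name); return(NA_real_) }
    num / den
  }
  sens <- tp / n_pos
  spec <- tn / n_neg
  ppv <- safe_div(tp, tp + fp, "ppv")
  npv <- safe_div(tn, tn + fn, "npv")
  accuracy <- (tp + tn) / n
  lr_pos <- if (spec < 1) sens / (1 - spec) else {
    undefined <- c(undefined, "lr_pos"); NA_real_ }
  lr_neg <- if (spec > 0) (1 - sens) / spec else {
    undefined <- c(undefined, "lr_neg"); NA_real_ }
  ci <- list(
    sens = .clopper_pearson(tp, n_pos),
    spec = .clopper_pearson(tn, n_neg),
    ppv = if (tp + fp > 0) .clopper_pearson(tp, tp + fp) else c(NA, NA),
    npv = if (tn + fn > 0) .clopper_pearson(tn, tn + fn) else c(NA, NA),
    accuracy = .clopper_pearson(tp + tn, n),
    lr_pos = .lr_ci(lr_pos, tp, n_pos, fp, n_neg),
    lr_neg = .lr_ci(lr_neg, fn, n_pos, tn, n_neg))
  structure(list(sens = sens, spec = spec, ppv = ppv, npv = npv,
                 accuracy = accuracy, lr_pos = lr_pos, lr_neg = lr_neg,
                 ci = ci, undefined = undefined,
                 table = confusion_table(tp, fp, tn, fn)),
            class = "ph_metrics")
}

#' @export
print.ph_metrics <- function(x, ...) {
  pct <- function(p, ci) {
    if (is.na(p)) return("undefined")
    sprintf("%.2f%% (%.2f-%.2f)", 100 * p, 100 * ci[1], 100 * ci[2])
  }
  cat("Sensitivity:", pct(x$sens, x$ci$sens), "\n")
  cat("Specificity:", pct(x$spec, x$ci$spec), "\n")
  cat("PPV:        ", pct(x$ppv, x$ci$ppv), "\n")
  cat("NPV:        ", pct(x$npv, x$ci$npv), "\n")
  cat("Accuracy:   ", pct(x$accuracy, x$ci$accuracy), "\n")
  fmt_lr <- function(lr, ci) if (is.na(lr)) "undefined" else
    sprintf("%.2f (%.2f-%.2f)", lr, ci[1], ci[2])
  cat("+LR:        ", fmt_lr(x$lr_pos, x$ci$lr_pos), "\n")
  cat("-LR:        ", fmt_lr(x$lr_neg, x$ci$lr_neg), "\n")
  invisible(x)
}

# round-half-up to integer (R's round() is round-half-even)
.round_half_up <- function(x) floor(x + 0.5)

#' Reconstruct a confusion table and metric panel from printed rates
#'
#' Inverts a published (sensitivity, specificity, group sizes) cell back to
#' integer counts with round-half-up (tp = round(sens * n_pos),
#' tn = round(spec * n_neg)), then recomputes the full panel. Used to check
#' internal consistency of published metric tables.
#'
#' @param sens,spec proportions in [0, 1].
#' @param n_pos,n_neg diseased / non-diseased group sizes (> 0).
#' @return list with \code{table} (\code{ph_confusion}) and \code{metrics}
#'   (\code{ph_metrics}).
#' @export
metrics_from_rates <- function(sens, spec, n_pos, n_neg) {
  if (sens < 0 || sens > 1 || spec < 0 || spec > 1)
    stop("sens and spec must be in [0, 1]")
  if (n_pos <= 0 || n_neg <= 0) stop("group sizes must be positive")
  tp <- .round_half_up(sens * n_pos)
  tn <- .round_half_up(spec * n_neg)
  fn <- n_pos - tp
  fp <- n_neg - tn
  if (min(tp, fp, tn, fn) < 0)
    stop("rounded counts produce a negative cell")
  ct <- confusion_table(tp, fp, tn, fn)
  list(table = ct, metrics = metrics_from_confusion(ct))
}

#' Prevalence-parameterised predictive values (Bayes)
#'
#' \code{ppv = sens p / (sens p + (1-spec)(1-p))},
#' \code{npv = spec (1-p) / (spec (1-p) + (1-sens) p)}.
#' Degenerate denominators yield NA.
#'
#' @param sens,spec,prevalence proportions in [0, 1].
#' @return list with \code{ppv}, \code{npv}.
#' @export
bayes_ppv_npv <- function(sens, spec, prevalence) {
  stopifnot(all(c(sens, spec, prevalence) >= 0),
            all(c(sens, spec, prevalence) <= 1))
  den_p <- sens * prevalence + (1 - spec) * (1 - prevalence)
  den_n <- spec * (1 - prevalence) + (1 - sens) * prevalence
  list(ppv = if (den_p > 0) sens * prevalence / den_p else NA_real_,
       npv = if (den_n > 0) spec * (1 - prevalence) / den_n else NA_real_)
}
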