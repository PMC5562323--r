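# Full analysis pipeline: indexes -> ROC/Youden -> metric panels ->
# pairwise AUC comparison -> combination rule -> ordinal model ->
# subgroup AUC tables. Everything is a thin composition of the module
# functions, so the report never drifts from direct recomputation.

#' Run the full portal-hypertension screening analysis on a cohort
#'
#' For each endpoint (CSPH: HVPG >= 10; SPH: HVPG >= 12) and each fibrosis
#' index computable on the cohort: the Youden-optimal cutoff (or a pinned
#' override), the full diagnostic-metric panel at that cutoff, and the AUC
#' with Hanley-McNeil 95% CI; all pairwise paired AUC comparisons with
#' unadjusted and Holm-adjusted p-values; the dual-index combination rule;
#' the proportional-odds model of HVPG grade on AST/PLT/albumin; and
#' per-subgroup AUC tables (Child-Pugh A vs B/C, viral vs non-viral
#' etiology, sex). Subgroups with an empty endpoint class are flagged and
#' skipped.
#'
#' @param cohort \code{ph_cohort} with HVPG for all records.
#' @param ast_uln AST upper limit of normal for APRI.
#' @param cutoffs optional named list \code{list(csph = c(index = cutoff),
#'   sph = ...)} pinning cutoffs instead of Youden selection.
#' @param combo optional list \code{list(index_a, index_b, csph = c(a, b),
#'   sph = c(a, b))} defining the combination rule per endpoint; defaults
#'   to King's score + Lok index at the endpoint's Youden cutoffs.
#' @param fit_ordinal fit the proportional-odds model (needs all three
#'   grades represented).
#' @return object of class \code{ph_report}: list with \code{panel},
#'   \code{performance} (data frame), \code{metrics} (nested list of
#'   \code{ph_metrics}), \code{auc_comparisons} (data frame),
#'   \code{combo}, \code{ordinal}, \code{subgroups} (data frame).
#' @export
run_analysis <- function(cohort, ast_uln = 40, cutoffs = NULL,
                         combo = NULL, fit_ordinal = TRUE) {
  df <- as.data.frame(cohort)
  if (!nrow(df)) stop("empty cohort")
  if (any(is.na(df$hvpg))) stop("all records need HVPG for analysis")
  cls <- classify_hvpg(df$hvpg)
  panel <- compute_panel(df, ast_uln = ast_uln)
  endpoints <- list(csph = cls$csph, sph = cls$sph)

  perf <- list()
  metric_panels <- list(csph = list(), sph = list())
  for (ep in names(endpoints)) {
    y <- endpoints[[ep]]
    for (ix in index_names()) {
      s <- panel[[ix]]
      ok <- !is.na(s)
      if (!any(ok) || length(unique(y[ok])) < 2) {
        perf[[length(perf) + 1]] <- data.frame(
          endpoint = ep, index = ix, n = sum(ok), cutoff = NA_real_,
          youden_j = NA_real_, auc = NA_real_, auc_low = NA_real_,
          auc_high = NA_real_, sens = NA_real_, spec = NA_real_,
          ppv = NA_real_, npv = NA_real_, accuracy = NA_real_,
          lr_pos = NA_real_, lr_neg = NA_real_, flagged = TRUE)
        next
      }
      sp <- s[ok & y]; sn <- s[ok & !y]
      cut <- if (!is.null(cutoffs[[ep]]) && ix %in% names(cutoffs[[ep]]))
        cutoffs[[ep]][[ix]] else youden_cutoff(sp, sn)$cutoff
      yj <- {
        ct <- confusion_from_scores(s[ok], y[ok], cut)
        m <- metrics_from_confusion(ct)
        metric_panels[[ep]][[ix]] <- m
        m$sens + m$spec - 1
      }
      au <- roc_auc(sp, sn)
      m <- metric_panels[[ep]][[ix]]
      perf[[length(perf) + 1]] <- data.frame(
        endpoint = ep, index = ix, n = sum(ok), cutoff = cut,
        youden_j = yj, auc = au$auc, auc_low = au$ci95[1],
        auc_high = au$ci95[2], sens = m$sens, spec = m$spec,
        ppv = m$ppv, npv = m$npv, accuracy = m$accuracy,
        lr_pos = m$lr_pos, lr_neg = m$lr_neg, flagged = FALSE)
    }
  }
  perf <- do.call(rbind, perf)

  cmp <- list()
  for (ep in names(endpoints)) {
    y <- endpoints[[ep]]
    idx <- index_names()
    for (i in seq_along(idx)) for (j in seq_along(idx)) {
      if (j <= i) next
      sa <- panel[[idx[i]]]; sb <- panel[[idx[j]]]
      ok <- !is.na(sa) & !is.na(sb)
      if (!any(ok) || length(unique(y[ok])) < 2) next
      r <- compare_auc_paired(sa[ok], sb[ok], y[ok])
      cmp[[length(cmp) + 1]] <- data.frame(
        endpoint = ep, index_a = idx[i], index_b = idx[j],
        auc_a = r$auc_a, auc_b = r$auc_b, delta_auc = r$delta_auc,
        z = r$z, p = r$p)
    }
  }
  cmp <- do.call(rbind, cmp)
  if (!is.null(cmp)) {
    cmp$p_holm <- NA_real_
    for (ep in unique(cmp$endpoint)) {
      sel <- cmp$endpoint == ep
      cmp$p_holm[sel] <- stats::p.adjust(cmp$p[sel], method = "holm")
    }
  }

  combo_res <- list()
  for (ep in names(endpoints)) {
    ia <- if (is.null(combo)) "kings" else combo$index_a
    ib <- if (is.null(combo)) "lok" else combo$index_b
    ctf <- if (!is.null(combo) && !is.null(combo[[ep]])) combo[[ep]] else {
      y <- endpoints[[ep]]
      yc <- function(s) {
        ok <- !is.na(s)
        youden_cutoff(s[ok & y], s[ok & !y])$cutoff
      }
      c(yc(panel[[ia]]), yc(panel[[ib]]))
    }
    rule <- combo_rule(ia, ib, ctf[1], ctf[2])
    combo_res[[ep]] <- apply_combo(panel[[ia]], panel[[ib]],
                                   endpoints[[ep]], rule)
  }

  ordinal <- NULL
  if (fit_ordinal && length(unique(cls$grade)) == 3) {
    ordinal <- fit_proportional_odds(df)
  }

  sub <- list()
  for (axis in c("child_pugh_AB_C", "etiology_viral_nonviral", "sex")) {
    groups <- withCallingHandlers(
      split_subgroups(cohort, axis),
      warning = function(w) invokeRestart("muffleWarning"))
    for (g in names(groups)) {
      gdf <- as.data.frame(groups[[g]])
      gpanel <- if (nrow(gdf)) compute_panel(gdf, ast_uln = ast_uln) else NULL
      for (ep in c("csph", "sph")) {
        for (ix in index_names()) {
          row <- data.frame(axis = axis, group = g, endpoint = ep,
                            index = ix, n = nrow(gdf), auc = NA_real_,
                            auc_low = NA_real_, auc_high = NA_real_,
                            skipped = TRUE)
          if (nrow(gdf)) {
            gy <- if (ep == "csph") classify_hvpg(gdf$hvpg)$csph
                  else classify_hvpg(gdf$hvpg)$sph
            s <- gpanel[[ix]]
            ok <- !is.na(s)
            if (any(ok & gy) && any(ok & !gy)) {
              au <- roc_auc(s[ok & gy], s[ok & !gy])
              row$auc <- au$auc; row$auc_low <- au$ci95[1]
              row$auc_high <- au$ci95[2]; row$skipped <- FALSE
            }
          }
          sub[[length(sub) + 1]] <- row
        }
      }
    }
  }
  sub <- do.call(rbind, sub)

  structure(list(panel = panel, performance = perf, metrics = metric_panels,
                 auc_comparisons = cmp, combo = combo_res,
                 ordinal = ordinal, subgroups = sub,
                 n = nrow(df), prevalence_csph = mean(cls$csph),
                 prevalence_sph = mean(cls$sph)),
            class = "ph_report")
}

#' @export
print.ph_report <- function(x, ...) {
  cat(sprintf("<ph_report> n = %d (CSPH %.1f%%, SPH %.1f%%)\n", x$n,
              100 * x$prevalence_csph, 100 * x$prevalence_sph))
  cat("\nPer-index performance:\n")
  out <- x$performance
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], round, 3)
  print(out, row.names = FALSE)
  invisible(x)
}

#' Write the report's tables to a directory as CSV files
#' @param report \code{ph_report}.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    performance = file.path(dir, "performance.csv"),
    auc_comparisons = file.path(dir, "auc_comparisons.csv"),
    subgroups = file.path(dir, "subgroup_auc.csv"))
  utils::write.csv(report$performance, paths["performance"],
                   row.names = FALSE)
  utils::write.csv(report$auc_comparisons, paths["auc_comparisons"],
                   row.names = FALSE)
  utils::write.csv(report$subgroups, paths["subgroups"], row.names = FALSE)
  invisible(paths)
}
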