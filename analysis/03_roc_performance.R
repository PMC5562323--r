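#!/usr/bin/env Rscript
# Step 3: full diagnostic evaluation — Youden cutoffs, metric panels, AUCs
# with Hanley-McNeil CIs, pairwise paired AUC comparisons, and the
# subgroup AUC tables.

suppressPackageStartupMessages(library(phscreen))

cohort <- read_cohort("results/cohort.csv", provenance = "simulated cohort")
report <- run_analysis(cohort, ast_uln = 40)
write_report(report, "results")

perf <- report$performance
for (ep in c("csph", "sph")) {
  top <- perf[perf$endpoint == ep, ]
  top <- top[order(-top$auc), ][1:3, ]
  cat(sprintf("Top indexes for %s: %s\n", toupper(ep),
              paste(sprintf("%s (AUC %.3f, cutoff %.2f)", top$index,
                            top$auc, top$cutoff), collapse = ", ")))
}
cmp <- report$auc_comparisons
sig <- cmp[cmp$p < 0.05, ]
cat(sprintf("%d of %d pairwise AUC contrasts have unadjusted p < 0.05 (%d after Holm)\n",
            nrow(sig), nrow(cmp), sum(cmp$p_holm < 0.05)))
cat("Wrote performance.csv, auc_comparisons.csv, subgroup_auc.csv\n")
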