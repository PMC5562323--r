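#!/usr/bin/env Rscript
# Step 4: the dual-index screening rule — King's score AND Lok index at
# the published cutoffs (23.47 / 1.30 for CSPH; 35.17 / 1.40 for SPH).

suppressPackageStartupMessages(library(phscreen))

cohort <- read_cohort("results/cohort.csv", provenance = "simulated cohort")
panel <- compute_panel(cohort)
cls <- classify_hvpg(cohort$hvpg)

rows <- list()
for (ep in c("csph", "sph")) {
  cut <- if (ep == "csph") c(23.47, 1.30) else c(35.17, 1.40)
  y <- if (ep == "csph") cls$csph else cls$sph
  res <- apply_combo(panel$kings, panel$lok, y,
                     combo_rule("kings", "lok", cut[1], cut[2]))
  m <- res$metrics
  rows[[ep]] <- data.frame(
    endpoint = ep, cutoff_kings = cut[1], cutoff_lok = cut[2],
    n = res$n, n_both_above = res$n_both_above,
    n_both_below = res$n_both_below, n_discordant = res$n_discordant,
    agreement_pct = 100 * res$agreement_fraction,
    sens_pct = 100 * m$sens, spec_pct = 100 * m$spec,
    ppv_pct = 100 * m$ppv, npv_pct = 100 * m$npv,
    accuracy_pct = 100 * m$accuracy, lr_pos = m$lr_pos, lr_neg = m$lr_neg)
  cat(sprintf(
    "%s rule (King's >= %.2f AND Lok >= %.2f): %d/%d screened positive, agreement %.1f%%, PPV %.1f%%, +LR %.2f\n",
    toupper(ep), cut[1], cut[2], res$n_both_above, res$n,
    100 * res$agreement_fraction, 100 * m$ppv, m$lr_pos))
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/combination_rule.csv", row.names = FALSE)
cat("Wrote results/combination_rule.csv\n")
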