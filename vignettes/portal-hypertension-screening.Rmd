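---
title: "Serum fibrosis indexes as noninvasive predictors of portal hypertension: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serum fibrosis indexes as noninvasive predictors of portal hypertension}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phscreen)
```

## Clinical setting

The hepatic venous pressure gradient (HVPG) — wedged minus free hepatic
venous pressure, in mmHg — is the reference measure of portal pressure in
cirrhosis, but it requires jugular catheterisation. Two thresholds carry
clinical meaning: HVPG ≥ 10 mmHg defines clinically significant portal
hypertension (CSPH), the point at which varices and decompensation
become likely, and HVPG ≥ 12 mmHg defines severe portal hypertension
(SPH), the pressure range of variceal haemorrhage risk. `classify_hvpg()`
applies these as inclusive lower bounds, giving grades 1 (< 10),
2 (10–12) and 3 (≥ 12); the grading is deliberately the only place the
package interprets HVPG, so every downstream analysis states its
endpoint as "CSPH" or "SPH" explicitly.

Since portal pressure rises chiefly with the intrahepatic resistance
produced by fibrosis, serum fibrosis indexes are plausible screening
surrogates. The package evaluates seven (AAR, APRI, FI, FIB-4, King's
score, Forns index, Lok index), all computed from routine labs by
`compute_panel()`.

## Unit conventions

Printed screening cutoffs fix the unit system, and two choices deserve
emphasis:

* **Albumin** enters FI as `8 − 0.01·PLT − ALB`. The FI cutoff of about
  −25 is only arithmetically possible when albumin is on the ~20–55
  numeric scale (g/L numerically); a g/dL-scale column (values ~3–5)
  would put FI near +3. `read_cohort()` therefore warns when the
  albumin column's median is below 10 and offers `albumin_gdl_to_gl =
  TRUE` to rescale. The heuristic is column-level (median), so a single
  severely hypoalbuminaemic patient does not trigger it.
* **Cholesterol** enters Forns in mmol/L. The original Forns derivation
  used mg/dL, but the cutoff ~11 used here is only consistent with
  mmol/L input; this deviation is deliberate and documented on
  `index_forns()`.

Two further formula-level decisions: FIB-4 uses the √ALT denominator
(the standard definition), and the Lok index is the linear predictor
rather than the original logistic probability — its screening cutoffs
(1.30, 1.40) exceed 1, which no probability can. The AST upper limit of
normal for APRI is not derivable from the cutoffs alone; the package
pins the conventional 40 IU/L and exposes it as `ast_uln`.

Missing optional labs (cholesterol, GGT) invalidate only the indexes
that need them; the patient is excluded per-index, with counts in the
panel's `"exclusions"` attribute. This choice matters because global
exclusion would silently change every index's denominator when one lab
is unavailable.

## ROC analysis

All indexes are treated as positively oriented (higher score ⇒ more
likely portal hypertension) and a patient is test-positive when
score ≥ cutoff; there is no automatic direction detection, so an index
that discriminated in the opposite direction would honestly show
AUC < 0.5 rather than being silently flipped.

`roc_auc()` computes the empirical AUC as the Mann–Whitney statistic
with ties counted ½ (via midranks), which equals the trapezoidal area
under the empirical ROC polygon exactly — a property the test suite
verifies against brute-force enumeration. The standard error is
Hanley–McNeil:

$$\mathrm{SE}^2 = \frac{A(1-A) + (m-1)(Q_1 - A^2) + (n-1)(Q_2 - A^2)}{mn},
\qquad Q_1 = \frac{A}{2-A},\; Q_2 = \frac{2A^2}{1+A},$$

with m diseased and n non-diseased, and the 95% CI is the normal
approximation truncated to [0, 1].

`youden_cutoff()` maximises J = sens + spec − 1 over all observed scores
plus a sentinel above the maximum. Ties in J are resolved toward the
highest sensitivity, then the lowest cutoff — a screening-oriented
tie-break chosen because a first-line test should prefer catching cases;
the source analysis is silent on ties.

For comparing two indexes measured on the same patients,
`compare_auc_paired()` uses placement values (each diseased patient's
fraction of outranked non-diseased patients, and vice versa) to estimate
the variances of and covariance between the two AUCs. The cited
comparison method estimated the AUC correlation from a lookup table;
that table cannot be reproduced exactly, so the package substitutes the
exact placement-based (DeLong-style) covariance, which is
oracle-verifiable and agrees with the reference implementation in
`pROC` to 1e-8 in the tests. For internal consistency the z denominator
uses placement-based variances as well (mixing Hanley–McNeil variances
with a placement covariance can produce a negative variance estimate for
highly correlated markers). When both the AUC difference and its
variance vanish — identical markers — the comparison reports z = 0,
p = 1.

## Diagnostic metric panels

`metrics_from_confusion()` derives sens, spec, PPV, NPV, accuracy, +LR
and −LR from integer 2×2 counts. The source tables report 95% CIs
without naming a method; the package pins Clopper–Pearson exact binomial
intervals for the five proportions (conservative and exactly
reproducible, computed from beta quantiles and verified against
`binom.test`) and the standard log-variance method for likelihood
ratios. Ratios with zero denominators are returned as `NA` and named in
`undefined` rather than as `Inf`, so degenerate tables cannot leak
infinities into downstream tables.

`metrics_from_rates()` inverts a published (sens, spec, n⁺, n⁻) cell
back to integer counts with round-half-up. Round-half-up (not R's
round-half-even) is pinned because it reproduces the internally
consistent published cells exactly — e.g. sens 71.28% of 188 gives
tp = 134, from which PPV 89.93%, NPV 39.33% and accuracy 71.01% follow.
Some published accuracy cells are not consistent with their own
sens/spec/prevalence under any rounding; the acceptance checks use only
the self-consistent ones.

## The dual-index screening rule

`apply_combo()` evaluates a rule of the form "index A ≥ a AND index
B ≥ b". Published combined-rule metrics are not jointly consistent with
a single denominator convention (the reported accuracy equals the
agreement fraction, suggesting concordant-only counting, while the PPV
suggests all-patient counting), so both conventions are implemented:
`both_above_vs_rest` (default; positive = both above, metrics over all
patients — the screening intent) and `concordant_only` (metrics among
agreeing patients, discordant count reported). Because the convention
question cannot be settled from the text, the combined rule's published
metrics are not used as acceptance targets; the rule's counts and
agreement fraction on synthetic cohorts are reported instead.

## The proportional-odds model

`fit_proportional_odds()` fits logit P(grade ≤ k) = θₖ − β·x for
grades 1–3 on AST, PLT and albumin. The sign convention puts positive β
on predictors that raise the odds of a *higher* grade, so odds ratios
exp(β) > 1 mean "associated with worse portal hypertension" (AST), and
< 1 protective (PLT, albumin). Fitting is Newton's method with
step-halving on the log-likelihood: predictors are standardised
internally (the raw scales differ by a factor ~100, which would make
the Hessian needlessly ill-conditioned), the score is analytic, the
Hessian is a central difference of the score, and convergence requires
score norm < 1e-8 on the standardised scale within 100 iterations.
Non-convergence (e.g. separation) flags the result instead of raising.
Coefficients, Wald CIs and the covariance matrix are reported per unit
on the original scales. The test suite checks the fit against
`MASS::polr` (coefficients and log-likelihood to 1e-4), checks that the
log-likelihood trace is monotone, and checks 95% CI coverage near
nominal over 200 simulated replicates at n = 250.

Reported odds ratios of 1.033 (AST), 0.993 (PLT) and 0.943 (albumin)
per unit come with implausibly narrow published CIs (e.g. 1.031–1.034);
those widths cannot be reproduced without the original records and look
like a reporting artifact, so the package targets parameter *recovery*
on simulated data — refitting on grades drawn from the model at n = 5000
recovers each ln-OR within 15% relative error — rather than CI widths.

## The synthetic cohort generator

No patient-level data ship with the package; `generate_cohort()` stands
in for them. The mechanism is a single latent severity variable
Z ~ N(0,1), truncated to its central 99.8% to keep HVPG in a clinical
range, mapped to HVPG by a monotone piecewise-linear function whose
anchors are placed in probability space so that P(HVPG ≥ 10) = 0.79 and
P(HVPG ≥ 12) = 0.685 hold exactly under the truncation — the observed
CSPH/SPH prevalences of the study population (188/238 and 163/238). The
default HVPG range is 2–35 mmHg.

Labs are drawn conditional on the CSPH stratum with the study's
stratum means and SDs (e.g. AST 32.38 ± 13.91 without CSPH vs
51.15 ± 36.83 with; PLT 130.64 ± 90.30 vs 91.21 ± 60.92; albumin
36.10 ± 7.23 vs 32.55 ± 6.73). Right-skewed labs (AST, ALT, GGT,
bilirubin) are lognormal with moment-matched mean/SD; symmetric labs
(albumin, PLT, INR, cholesterol) are normal, resampled — not clamped —
while non-positive, to avoid point masses at a truncation boundary.
Categorical variables (sex, etiology, Child-Pugh, ascites) follow the
study's conditional frequencies per stratum, which is why, e.g., no
Child-Pugh C patient appears in the no-CSPH stratum.

`severity_coupling` (default 0.3, chosen once as a mild, realistic
within-stratum correlation; the study reports no lab–lab or lab–HVPG
correlations to calibrate against) reallocates part of each lab's
within-stratum variance onto Z, signed per lab (AST/ALT/GGT/bilirubin/INR
positive, PLT/albumin negative, age/cholesterol zero). The construction
standardises Z within each stratum using the analytic truncated-normal
moments, so the coupling changes no stratum mean or SD in expectation.
Two consequences are worth stating plainly. First, with stratum
marginals pinned to the study values, a single lab's CSPH AUC is fixed
regardless of the coupling; the coupling's observable effect is a
stronger within-stratum rank correlation between indexes and HVPG (and
it slightly *lowers* composite-index AUCs by correlating their
components). Second, an identity-scale lab whose SD is large relative
to its mean (PLT in the CSPH stratum) gains a few units of mean from
positivity resampling; the generator accepts this small bias rather
than inventing a skewed PLT distribution the study does not report.

What the generator does **not** emulate: inter-lab correlations beyond
the single latent factor, etiology-specific lab profiles, longitudinal
structure, or measurement error in HVPG itself. Passing tests on
synthetic cohorts therefore demonstrate that the machinery is correct
and calibrated to the study's marginal structure — not that the indexes
would achieve the same AUCs on new patients. On default synthetic
cohorts the headline indexes land around AUC 0.70–0.74 for CSPH,
inside the 0.65–0.85 plausibility band around the reported 0.740–0.755
(checked over 50 seeds), which is the appropriate strength of claim for
a marginal-structure emulator.

## Problem sizes and numerical choices

The test suite uses cohorts of 150–2000 for pipeline checks, 10 000 for
generator calibration (CSPH fraction within ±0.02 of 0.79), 5000 for
ordinal parameter recovery, 200 × 250 for CI coverage, and 50 seeds ×
2000 for the AUC plausibility band — sizes at which every Monte-Carlo
tolerance above holds comfortably while the whole suite runs in well
under a minute per file. ROC/Youden oracle equivalence is exhaustive at
n ≤ 50 per class where brute force is exact. Ties in scores are handled
identically (½-credit) in the AUC statistic, the placements and the
trapezoid, so the three agree to machine precision; Youden ties break
toward sensitivity as described; degenerate inputs (empty classes,
single grades, zero-denominator metrics, non-positive labs, unknown
categorical labels) are rejected or flagged at the boundary of each
module rather than propagated.
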