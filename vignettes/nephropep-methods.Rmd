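---
title: "Methods: eGFR-slope labeling and urinary peptide panel discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: eGFR-slope labeling and urinary peptide panel discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nephropep)
library(dplyr)
```

## The problem

Diabetic patients on renin--angiotensin system inhibitors (RASi) differ
widely in whether their kidney function stabilizes under treatment. The
observable is the estimated glomerular filtration rate (eGFR), computed from
serum creatinine and/or cystatin C together with age and sex, measured at
roughly annual visits. `nephropep` implements a complete, testable pipeline
for this setting:

1. compute eGFR under four estimating equations;
2. fit per-patient eGFR slopes and label each patient *controlled* (responder),
   *uncontrolled* (non-responder) or *excluded*;
3. screen a urinary peptide intensity matrix for association with that label,
   separately under each equation's labeling;
4. select a biomarker panel concordant across equations and refine it into an
   SVM classifier evaluated by leave-one-out (LOO) AUC.

Because labels derive from noisy trajectories through four different
equations, patient classification itself is method-dependent; the package
therefore also quantifies label concordance across equations, which is an
analysis output in its own right.

## Estimating equations

Four equations are implemented (`egfr_methods()`): the CKD-EPI 2009
creatinine equation, the CKD-EPI 2012 cystatin C equation, the CKD-EPI 2012
combined equation, and the EKFC cystatin C equation. Each is a product of a
demographic factor and piecewise power terms in the analyte with a knot at a
sex-specific (creatinine) or fixed (cystatin) normalization concentration.
Coefficients follow the published forms; the 2021 race-free CKD-EPI refits
are intentionally out of scope, and the published Black race coefficients of
the 2009/2012 equations are available behind an explicit flag, off by
default.

Units are fixed -- creatinine mg/dL, cystatin C mg/L -- with no
autodetection: silent unit confusion is the dominant failure mode of eGFR
code, so a wrong-looking input is an error, never a guess.

For the EKFC cystatin equation the rescaling constant Q (the population
median cystatin C in healthy adults) is configurable, default 0.83 mg/L and
sex-independent; whether a sex-specific Q should be used in a given cohort
is a substantive choice the package does not make for you (pass
`ekfc_q = c(F = ..., M = ...)` for a sex-specific policy).

Each equation is strictly decreasing in its analyte, so it inverts in closed
form per branch: `invert_egfr()` selects the branch by comparing the target
eGFR with the value at the knot and solves the power law analytically. The
combined equation is inverted for creatinine at a fixed cystatin value. The
round trip is exact to floating point (tested at 1e-9 relative error), which
is what makes the simulator's marker back-calculation trustworthy.

## Slope fitting and labeling

Per patient, eGFR is regressed on time by ordinary least squares (the same
`lm` fit a clinician-statistician would run), either through all visits
(`full_period`) or per consecutive visit pair (`between_visits`). The
annualized percentage slope is `100 * slope / denominator`.

Two conventions were genuinely open and are both implemented:

* **Denominator.** Default is the fitted value at the window start (the
  regression intercept at time 0 for the full period). It is robust to
  baseline measurement error; the observed-baseline denominator is available
  via a flag for sensitivity analysis.
* **Between-visit aggregation.** The per-patient summary is the arithmetic
  mean of the per-interval percentage slopes. For a two-point interval the
  fitted value at the interval start equals the observed value, so both
  denominator conventions coincide there.

Discovery labeling uses percentage-slope bands with literal boundary
semantics: below -10 %/yr is uncontrolled (strictly below: -10 exactly is
excluded), the closed band [-5, +5] %/yr is controlled, everything else is
excluded as unlabelable with confidence. Boundaries are measure-zero under
noise, so the choice is about contract clarity, not results.

Validation labeling uses absolute rules: uncontrolled requires a loss from
baseline of more than 10 mL/min/1.73 m² *and* progression below
60 mL/min/1.73 m²; controlled requires a total loss below the cohort
threshold (5 or 10 mL/min/1.73 m²) with eGFR above 60 throughout, baseline
included. The loss is measured to the minimum follow-up value by default
(the most sensitive reading); measuring to the last visit is a flag.

## Peptide preprocessing

Intensities are non-negative with 0 meaning *not detected*; zeros are never
treated as small abundances. Normalization regresses each sample's detected
internal-standard log-intensities on reference log-intensities with the
slope fixed at 1 -- i.e. a single multiplicative factor per sample,
`exp(mean(log(standard) - log(reference)))`. The reference defaults to the
per-standard median across samples, making the operation self-contained;
samples with fewer than two detected standards pass through unscaled and
flagged. The operation is idempotent against a fixed reference.

The detection-frequency filter keeps a peptide if at least 30% (inclusive)
of samples in *either* label group detect it; the filter is applied per
eGFR-equation labeling, since each equation defines its own groups.

## Differential screen

Per peptide, a two-sided Wilcoxon rank-sum test compares uncontrolled with
controlled samples on raw intensities (`stats::wilcox.test`: exact when
both groups are below 50 samples with no ties, normal approximation with
tie and continuity correction otherwise). The fold change is the ratio of
zero-inclusive group means -- zeros are real non-detections that belong in
mean abundance. When the controlled mean is zero the fold change is
undefined; the peptide is flagged and its direction taken from the rank
statistic instead of being dropped. No multiple-testing correction enters
selection (nominal significance is the screening contract at these sample
sizes); Benjamini--Hochberg q-values are attached as metadata only.

Peptide--slope association uses Spearman correlation with average-rank ties
and the t approximation. To compare equations, correlations significant at
p < 0.1 in both are regressed on one another (OLS) and r² reported.

## Panel selection and the SVM classifier

A peptide enters the concordance panel if it is nominally significant
(p < 0.05) with a shared direction of regulation under at least 3 of the 4
equation labelings. The selection is monotone in both thresholds (tested).
A separate consistency filter retains peptides whose direction replicates
across every supplied cohort and equation.

The classifier is a radial-kernel C-SVM (`e1071::svm`, the libsvm
implementation) with fixed hyperparameters C = 256 and gamma = 2e-5 -- no
hyperparameter search, by design. Features are `log(1 + intensity)` (zeros
map to 0) standardized per peptide; the classifier score is the signed
distance to the separating hyperplane, oriented so larger means
uncontrolled. Model development defaults to the EKFC cystatin labeling.

**Leave-one-out evaluation.** The LOO score of a sample is computed by
refitting the SVM without it. Two numerical choices matter:

* Standardization statistics are computed once on the full training set
  rather than inside each fold. With ~200 samples, fold-wise recomputation
  perturbs each z-score by O(1/n) and is statistically indistinguishable,
  while the global transform admits an *exact* shortcut: a training point
  with a zero dual coefficient leaves the SVM solution unchanged when
  removed, so its LOO score equals its full-model score. Only support
  vectors require refits. The fast path is tested for exact equality against
  the naive all-folds refit.
* Decision values in the LOO hot path are computed directly from the
  support-vector state (coefficients, kernel row, offset), bypassing
  per-call prediction overhead; also tested for equality.

**Take-one-out refinement** is implemented as greedy backward elimination
scored by LOO AUC: each round removes the single peptide whose removal
maximally increases the AUC, stopping when no removal strictly improves it
(ties break lexicographically by peptide id, making the procedure
deterministic). The refined panel never has a lower LOO AUC than its input,
and the full elimination trace (round, peptide, AUC before/after) is
attached to the result. The elimination criterion is this package's
documented interpretation of iterative panel refinement; nothing is claimed
about any proprietary implementation. `max_rounds` bounds the search; since
the AUC is non-decreasing over rounds, a bounded search is a conservative
version of the same procedure, useful where a full run (typically ~10
rounds at panel sizes near 60) is not worth its cost.

## ROC inference

AUC uses the Mann--Whitney identity with ties counted one half. The
confidence interval and the p-value against AUC = 0.5 use DeLong's
placement-variance method (Wald form, untransformed), implemented
in-package and cross-checked in the tests against an independent
implementation (pROC). With perfectly separated scores the DeLong variance
degenerates to zero; the CI then collapses to the point estimate rather
than fabricating width.

On *null* data, LOO AUC is known to fall slightly below 0.5 (removing a
sample tilts the training set toward the opposite class, anticorrelating
scores with labels); our permutation calibration puts the null mean near
0.43 with a per-replicate SD of ~0.065 at n ≈ 190. Chance-level checks in
the test suite therefore average over permutation replicates instead of
asserting on single draws.

## The synthetic cohort generator

`simulate_cohort()` produces cohorts with a known ground truth so that
every downstream stage has a parameter-recovery test surface. Defaults
describe the reference study conditions: 200 patients, 4 visits at
1 ± 0.2-year intervals, ages N(67.5, 8) truncated to [30, 90], 53% female,
baseline GFR N(63.3, 16.8) truncated to [20, 120] mL/min/1.73 m² -- a
cohort with a sizable CKD-stage-3 fraction, as is typical for diabetic
RASi-treated populations.

* **Latent trajectory.** Half the patients (configurable) decline at
  -15 %/yr, the rest are stable at 0 %/yr. The default shape is linear in
  time with annual change equal to the configured percent of the time-0
  value. A constant multiplicative ("log-linear") decline is also available,
  but note that OLS through a log-linear curve does *not* recover the
  nominal rate (-13.9 instead of -15 over three annual visits), so the
  linear-percent form is the default precisely because it makes the
  configured rate an exact target for the recovery tests.
* **Markers.** Creatinine and cystatin C are obtained by analytically
  inverting the CKD-EPI creatinine and cystatin equations at the true GFR,
  then multiplied by log-normal noise with a 5% CV (typical clinical assay
  imprecision). The combined and EKFC equations are *not* used for
  generation, so they disagree with truth through their functional form --
  deliberately reproducing the between-equation discordance phenomenon.
  Age is treated as fixed at baseline over the short follow-up.
* **Peptides.** 500 peptides (50 truly differential, 80% down-regulated in
  decliners) with per-peptide mean log-intensities N(12, 1.5) and SDs
  U(0.7, 1.3). Detection is Bernoulli with probability logistic in the
  peptide's mean log-intensity, intercept calibrated so the average
  detection frequency of null peptides equals the target (default 0.7).
  Differential peptides are shifted by `effect_size` SDs in decliners --
  and because detection follows the shifted mean, down-regulation also
  lowers detection frequency, as in real CE-MS data.
* One urine sample per patient (baseline), matching the design in which
  peptidomics predicts subsequent trajectory.

What the generator does *not* emulate: migration-time or mass drift,
batch effects, correlated peptide families (fragments of one protein),
informative dropout beyond the abundance--detection link, medication
changes mid-follow-up, or per-patient heterogeneity in the true decline
rate. Passing recovery tests on these cohorts demonstrates that the
pipeline's statistics behave as designed under its stated model -- not that
the pipeline would achieve comparable sensitivity on real cohorts.

```{r example, eval = FALSE}
co <- simulate_cohort(sim_config(seed = 1))
run <- run_pipeline(run_config(sim = sim_config(seed = 1), seed = 1))
run
```

## Orchestration and reproducibility

`run_pipeline()` chains simulate → eGFR → label → normalize → screen →
select → train → evaluate → concordance. With an `out_dir` it writes every
intermediate artifact (CSV/TSV/JSON) plus a manifest holding the resolved
configuration and an MD5 checksum per file; the manifest contains no
timestamps or absolute paths, so one configuration and seed reproduce all
outputs bit-identically (tested). All randomness flows from the single
configured seed. In-pipeline normalization uses the highest-detection
peptides as pseudo-standards (the simulator plants no designated internal
standards); with real data, pass the true internal-standard list to
`normalize_peptides()` directly.

Problem sizes used in the automated checks: module tests run cohorts of
25--80 patients; end-to-end property checks use the reference 200 × 500
conditions with five seeds, bounding panel refinement at two elimination
rounds (conservative, as above); the acceptance script runs the complete
unbounded refinement once.

## Known limitations

* Per-patient OLS slopes only -- no mixed-effects or shared-slope models.
* The screen is unadjusted for covariates, matching its screening purpose.
* The take-one-out criterion is an interpretation (see above); alternative
  elimination criteria would need their own calibration.
* DeLong inference assumes independent samples; clustered designs would
  need a different variance.
* Fold changes on zero-inflated intensities conflate abundance and
  detection; the package reports detection frequencies alongside so users
  can tell the two apart.
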