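---
title: "Methods: urinary-EV transcript panels for active surveillance monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: urinary-EV transcript panels for active surveillance monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uevpanel)
```

## The problem

Men with low- or early intermediate-risk prostate cancer on active
surveillance (AS) are monitored by serum PSA, MRI, and periodic control
biopsies. A control biopsy triggers a switch to radical treatment when the
tumor is *reclassified*: ISUP grading group 2 or higher at any PSA, or
persistent ISUP 1 with PSA above 10 ng/mL (a tumor-free biopsy is stable
regardless of PSA). Biopsies are invasive; a marker that reliably predicts
a negative biopsy could let patients skip it. This package implements, as a
tested and reusable pipeline, an analysis that combines transcript levels
measured by qPCR in urinary extracellular vesicles (uEV) with clinical
indices into binary risk-factor sum scores, and quantifies how many
biopsies such scores could spare at what miss rate.

## From crossing points to expression

Each sample x assay measurement consists of replicate qPCR crossing points
(CP). The quantification stage applies three bench rules before any
statistics:

* replicates are averaged; a replicate spread above `max_dev` (default 0.5
  cycles) flags the measurement as "would be repeated at the bench". A
  reanalysis cannot repeat a measurement, so flagged records are excluded
  by default (`keep_flagged = TRUE` retains them);
* an averaged CP at or above the detection limit (default 35 cycles,
  inclusive) is a negative call. Negative targets are recorded as missing
  by default; `negative_handling = "impute"` instead imputes expression at
  the detection limit, `2^-(35 - geoM)`. The default is the conservative
  choice because the source analysis does not state its handling;
* relative expression is `2^-(CP_target - geoM)` where `geoM` is the
  geometric mean CP of the three reference transcripts PPIA, RPLP0, and
  TBP. The geometric mean is taken of the CP values themselves, literally;
  this is unconventional (the standard reference-gene normalization
  averages Cq arithmetically), so `normalization = "arithmetic"` is
  offered as an alternative. On CP values around 24 with one-cycle spread
  the two baselines differ by under 0.03 cycles, i.e. about 2% in
  expression, which is far below the biological spread here. No calibrator
  sample is used: the reported expression magnitudes (around 10^-3 to
  10^-1) are consistent with plain `2^-dCP` values.

A patient whose reference assays fail (missing, flagged, or negative) has
no baseline; all of that patient's expression values are set missing with
a warning.

## Marker evaluation

Markers are evaluated against the binary reclassification label by
empirical ROC analysis. The AUC is the Mann-Whitney probability (ties
counted one half), identical to the trapezoidal area; its confidence
interval and the p-value for AUC = 0.5 use the DeLong placement-value
variance (`method = "hanley"` gives the Hanley-McNeil approximation).
Positivity is strict — `value > cutoff` for "greater", `value < cutoff`
for "less" — matching how the cutoffs are reported (e.g. "> 10 ng/mL",
"< 45.7 x 10^-3"). MALAT1 is oriented "less" (low expression indicates
reclassification); the other markers "greater". An "auto" mode orients a
marker so its AUC is at least 0.5.

Cutoffs for the clinical indices are fixed published values: PSA > 10
ng/mL and PSAD > 0.2 ng/mL² (PRIAS criteria), PSAV > 0 ng/mL/year,
maxPI-RADS >= 4. Transcript cutoffs maximize Youden's J = SNS + SPC - 1 by
exhaustive search over the observed values. Ties are broken toward higher
sensitivity (a screening context penalizes missed reclassification more
than overcalling), then toward the lower cutoff; neither tie-break is
stated in the source and both are package design choices. The search
maximizes the integer count score `TP*n0 + TN*n1` rather than the floating
sum of proportions, so mathematically tied cutoffs are treated as exact
ties.

Cutoffs are derived and evaluated on the same cohort, exactly as in the
source analysis; there is no optimism correction or cross-validation. The
reported accuracies are therefore in-sample and optimistic — a known
limitation of the design being reproduced, not of the implementation.

## 2x2 statistics

From a dichotomized marker the pipeline reports sensitivity, specificity,
PPV, NPV, likelihood ratios (pLR = SNS/(1-SPC), nLR = (1-SNS)/SPC), and
accuracy. Odds ratios use the cross-product with the Woolf/Wald interval
`exp(ln OR ± z * sqrt(1/a + 1/b + 1/c + 1/d))`; this reproduces all three
published score CIs from their counts, which is why it is the default
(exact conditional intervals would not). A zero cell makes the estimate
undefined unless the Haldane-Anscombe 0.5 correction is requested, in
which case the result is flagged. Internally everything is kept at full
precision; `round_half_up()` exists because the tables round half away
from zero while base R rounds half to even.

## Predictor selection

Univariate logistic screening fits one single-predictor model per
dichotomized marker. For a single binary predictor the maximum-likelihood
odds ratio equals the contingency cross-product and the Wald interval
equals the Woolf interval; the test suite asserts this equivalence to six
decimals, which pins the two routes (glm and 2x2 arithmetic) to each
other.

Forward-stepwise selection enters, at each step, the candidate with the
smallest Rao score-test p-value if it is below `entry_alpha` (0.05), and
after each entry removes entered terms whose likelihood-ratio p-value
exceeds `removal_alpha` (0.10), worst first. These are the default entry
and removal criteria of the statistical software named by the source,
whose exact stepwise flavor is unstated; the published multivariate table
even contains a retained predictor with p = 0.057 > 0.05, which shows that
its entry and reporting criteria were not identical. The trace (candidate,
statistic, p, action, log-likelihood) is returned and written out so every
run is replayable; ties resolve by candidate input order, making the
procedure deterministic.

## Sum scores

A panel is an ordered set of frozen dichotomization rules plus an "at
least X of Y" positivity threshold. Freezing the component cutoffs makes
the panel a pure function of new data — required for any reuse. The score
is the count of positive components; patients missing any component are
excluded listwise (the source is silent; its cohort appears complete). The
integer score is evaluated by the same ROC machinery; with `threshold =
"youden"` the positivity threshold X is chosen from the score's own ROC
curve (a strict cutoff c on an integer score means positivity at
`score >= c + 1`). The biopsy-avoidance summary expresses, as percentages
of the whole cohort: stable patients with a negative score (biopsies that
could have been skipped), reclassified patients with a negative score
(cancers that would have been missed), and stable patients with a positive
score (biopsies still recommended in vain).

## Cohort comparison tables

Group comparisons follow a fixed rule: two groups use the two-sided
Mann-Whitney U test for continuous variables (exact when the product of
group sizes is at most 400 and there are no ties, otherwise the
tie-corrected normal approximation — at the study's 41 x 31 the asymptotic
form applies, matching what standard software reports at this size) and
Fisher's exact test for 2x2 tables (two-sided by the probability-mass
method, the definition used by the common packages); three or more groups
use Kruskal-Wallis and Pearson chi-square without continuity correction.
No multiple-testing correction is applied, matching the source; a
Benjamini-Hochberg flag would be a labeled extension.

## The synthetic cohort generator

No patient-level data are deposited with the source, so the generator is
the package's test bed: it emulates the statistical structure the
analysis assumes, with defaults fixed at the study conditions.

* n = 72, 31/72 reclassified. Labels are assigned exactly (31 patients),
  then ISUP and PSA fields are drawn so the reclassification rule
  reproduces the labels: reclassified patients are ISUP 1 with PSA
  truncated above 10 ng/mL (4/31) or ISUP 2-5 (22, 1, 1, 3 of 27); stable
  patients are tumor-free with unconstrained PSA (25/41, so a stable
  patient can exceed 10 ng/mL, as in the published cohort) or ISUP 1 with
  PSA truncated at or below 10.
* Transcript expression is log-normal per group — the conventional qPCR
  model, and consistent with the source reporting medians and using rank
  tests — with planted fold changes: AMACR 1.4x up, MALAT1 1.5x down,
  PCAT29 1.7x up, HPN and PCA3 1.3x up ("up to 1.7-fold" is all the
  source states for the trend transcripts, so the intermediate values are
  the package's choice), plus three null transcripts. Stable-group
  medians sit at the published expression magnitudes (AMACR 0.150, HPN
  0.0455, PCAT29 0.0018, MALAT1 0.060, PCA3 0.45 on the 2^-dCP scale).
  The common log2 spread of 0.9 (0.86 for AMACR) is calibrated so the
  planted AMACR fold yields an AUC near 0.65 at n = 72, the order of
  magnitude of the published single-transcript AUCs.
* Crossing points are back-computed: reference CPs are drawn per patient
  (PPIA/RPLP0/TBP around 23.5-25.5 cycles, SD 1), the target's true CP is
  `geoM - log2(expression)`, and both replicates add N(0, 0.15) noise
  (about 2% of replicate pairs then exceed the 0.5-cycle spread rule, a
  realistic repeat rate). Low-abundance transcripts (PCAT29's true CP sits
  near 33-34 cycles) censor naturally at the 35-cycle detection limit; an
  additional dropout probability (`censor_rate`, default 0.02) pushes a
  measurement into the non-detectable range.
* Clinical variables are drawn group-wise at the published medians: PSA
  log-normal (4.82 / 7.54 ng/mL; log-SDs 0.50 / 0.62 chosen so the
  fraction above 10 ng/mL matches the published 3/41 and 10/31 splits),
  PSAV normal (-0.15 / 0.60 ng/mL/year, SD 1.8 from the published
  ranges), interval log-normal (1.4 / 1.6 years), prostate volume
  log-normal (median 45 mL, giving PSAD medians near 0.107 / 0.157
  ng/mL²), age normal (64 / 70 years), and maxPI-RADS categories at the
  published per-group frequencies (PI-RADS >= 4 in 29% stable vs 65%
  reclassified). The initial PSA is derived as `psa - psav * interval` so
  the three quantities are mutually consistent. PSAV is generated
  directly rather than from simulated longitudinal PSA trajectories.
* Markers are generated independently (no marker-marker correlation): the
  source gives no joint structure. Each component draws from its own
  substream derived from the master seed, so adding or removing a
  transcript never perturbs the others, and the same (spec, seed) is
  byte-identical.

What the generator does *not* emulate: real between-assay efficiency
differences and pre-amplification bias (assumed uniform, as nothing is
stated), marker-marker correlation (real AMACR and PCAT29 levels are
likely correlated, which would make the sum scores less additive than in
simulation), MRI reading variability, and longitudinal visit structure.
Passing tests therefore demonstrate that the pipeline's machinery is
correct and recovers planted effects — not that the published effect sizes
would replicate in new patients.

`plant_panel()` is a separate fixture builder: it constructs per-patient
component indicators whose confusion matrix at a given threshold equals
requested counts exactly, which is how the published score tables are
re-evaluated end-to-end through the scoring stage.

## Problem sizes and numerical choices

The test suite and the acceptance script use: exact recomputation of every
statistic derivable from printed 2x2 counts (n = 72, instantaneous);
oracle property suites on random instances up to n = 200 (all-pairs AUC,
exhaustive Youden, hypergeometric Fisher enumeration); fold recovery and
null-AUC checks on one generated cohort of n = 10,000; and 200 replicates
each for the stepwise null (n = 10,000) and planted-pair (n = 500)
studies. Logistic fits converge at an IRLS tolerance of 1e-12 (the
glm-vs-cross-product identity holds to ~1e-7 relative); coefficients
beyond ±15 on the log-odds scale flag separation. DeLong variance zero
(all placements tied, e.g. perfect separation) is flagged degenerate
rather than reported as a zero-width interval.

One measured property is worth stating plainly: with three independent
null candidates each tested at entry alpha 0.05, the probability that
forward stepwise selects nothing is about (1 - 0.05)^3 ~ 0.857, and the
probability that only a planted pair is selected is bounded by the same
multiplicity. The package's measured rates (~87% none selected under the
null; ~84% exactly the planted pair at n = 500) sit where that arithmetic
puts them. Stepwise selection at per-candidate alpha 0.05 admits noise
into roughly one model in seven — worth remembering when reading any
stepwise-selected panel, including the published one.

## Reproducing the published numbers

Every statistic derivable from the published contingency tables is
recomputed exactly by the accuracy and odds-ratio machinery (see
`scripts/acceptance.R`). Patient-level quantities (the published AUCs,
e.g. the combined score's 0.867, and the multivariate odds ratios) depend
on the undeposited joint patient data and cannot be recomputed; the
pipeline reproduces the procedure, and on default synthetic cohorts the
combined 2C-3T score lands in the same region (AUC ~ 0.87-0.90),
outperforming its components — the qualitative claim the analysis makes.
Two small print-level discrepancies are documented in the tests: the
published upper CI bound 123.76 arises from exponentiating around the
rounded OR (unrounded: 123.75), and printed values ending in 5 reflect
half-up rounding.
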