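---
title: "Modelling exam anxiety from stress and motivation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling exam anxiety from stress and motivation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(examfis)
```

## The problem

Exam anxiety in undergraduate students is commonly measured with short
psychometric instruments administered before and after an examination
period: the Perceived Stress Scale (PSS, 10 items, total 0–40), a revised
Achievement Motives Scale (AMS, 10 items, total 10–50), and an Academic
Anxiety Scale (AAS, 11 four-point items, total 11–44). Two analysis routes
are of interest:

1. **A Mamdani fuzzy inference system (FIS)** that maps a student's crisp
   (PSS, AMS) pair to an anxiety estimate on the AAS range through
   linguistic Low/Medium/High terms and If–Then rules. This mirrors how a
   practitioner reasons ("high stress and at least moderate motivation
   usually means high anxiety") and produces an interpretable surface.
2. **The conventional statistical pipeline**: medians and IQRs, Cronbach's
   alpha, Wilcoxon signed-rank pre/post comparisons, Kruskal–Wallis tests
   across study levels, Spearman correlations with magnitude bands, and
   Gaussian GLMs in which achievement motivation moderates the
   stress–anxiety relationship through a PSS×AMS product term.

The cohort this package is calibrated to (n = 389, one college, study
levels 55.5% / 28.0% / 16.5%) was never deposited, so the package ships a
synthetic generator that reproduces the cohort's *published summary
structure* — means, SDs, Spearman correlations, interaction coefficients,
and item-level internal consistency — and every pipeline stage is
validated by parameter recovery against it.

## The fuzzy system

### Membership functions and partitions

All terms are trapezoids `(a1, a2, a3, a4)` with triangles as the
`a2 == a3` special case; membership rises linearly on `[a1, a2]`, is 1 on
`[a2, a3]`, and falls on `[a3, a4]`. The published input ranges are:

| variable | Low | Medium | High |
|---|---|---|---|
| PSS (0–40) | 0–13 | 13–26 | 26–40 |
| AMS (10–50) | 10–25 | 25–36 | 36–50 |

Only term *ranges* are published, not apexes, so two partition layouts are
offered:

* **literal** (default, used when reproducing the original setup): each
  term is the triangle `(lo, (lo+hi)/2, hi)` over its published range.
  Adjacent triangles then meet at their feet, so membership vanishes at
  shared boundaries — a crisp PSS of exactly 13 activates *no* term, and
  inference returns the degenerate fallback.
* **overlap**: a Ruspini partition with apexes at the literal midpoints,
  feet at the neighbouring apexes, and flat shoulders at the domain edges.
  Grades sum to 1 everywhere, which is what the property suite exercises.

The output variable (AAS, 11–44) has no published term ranges at all; it
is partitioned into equal thirds (11–22, 22–33, 33–44), mirroring the
three-level treatment of the inputs.

### Rules and operators

The original rule table is not recoverable from the published material, so
the default base is a nine-rule reconstruction designed to reproduce the
qualitative findings — anxiety rises with stress, and the stress effect is
amplified when motivation is at least moderate (the positive pre-exam
PSS×AMS synergy):

| stress \\ motivation | Low | Medium | High |
|---|---|---|---|
| Low | Low | Low | Medium |
| Medium | Medium | Medium | Medium |
| High | Medium | High | High |

Operators are the classic Mamdani defaults implied by the original
MATLAB-toolbox setup: `min` AND across antecedent grades, `min`
(clipping) implication, `max` aggregation, numeric centroid
defuzzification on a grid of step 0.01 output units (3301 points over the
AAS range, giving centroid accuracy well below the 0.02-unit test
tolerance). `product` variants of AND and implication are available in
the config. Rule weights default to 1.

### Numerical choices and degenerate inputs

* Out-of-domain inputs are **clamped with a warning** rather than
  rejected: a survey total can only leave its instrument's range through a
  data error, and `validate_cohort()` reports those separately.
* If no rule fires (possible under the literal partition at term
  boundaries), the aggregated area is zero and `infer()` returns the
  output-domain midpoint (27.5) with `degenerate = TRUE`. Downstream,
  `fis_scores()` carries the flag and `agreement()` excludes degenerate
  records from confusion counts while reporting how many there were.
* Cohort scoring deduplicates identical (PSS, AMS) pairs, so
  integer-scored cohorts cost at most one inference per distinct pair.

### A known, deliberate limitation: non-monotonicity

One would like crisp anxiety to be non-decreasing in stress at fixed
motivation. Under max aggregation with clipping implication this is *not*
a theorem, and the default system genuinely violates it in two narrow
windows. At AMS = 20 (motivation mostly Low, grade 0.81, Medium grade
0.19), raising PSS from 26.5 to 30 strengthens the High-stress×Low-
motivation→Medium rule while the High-stress×Medium-motivation→High rule
stays capped at 0.19; Medium-anxiety mass grows, and the centroid slips
from 29.2 to 29.0 before recovering. The dip is structural: any monotone
rule table over three terms repeats a consequent within a row, and max
aggregation over a Ruspini partition then produces such dips whenever the
repeated-consequent cap exceeds 0.5 while another consequent is co-active.
Additive aggregation would remove it, but this package deliberately keeps
the faithful max-aggregation Mamdani semantics; the property test
documents the violation rather than hiding it (the dips are at most ~0.2
anxiety points on a 33-point range). Relatedly, uniform down-weighting of
all rules preserves crisp outputs exactly under *product* implication
(the shape scales, the centroid is invariant) but can swap near-tied
records under clipping implication.

## The statistical pipeline

* **Descriptives**: quartiles use linear interpolation between order
  statistics (R's default type 7). This matters: medians and IQRs of
  integer Likert totals depend on the convention.
* **Wilcoxon signed-rank** on post − pre differences: zero differences
  are dropped (and counted); with ≤ 25 non-zero differences and no tied
  magnitudes the exact null distribution is used, otherwise the
  tie-corrected normal approximation with continuity correction. The
  statistic is the positive-rank sum.
* **Kruskal–Wallis** with tie correction, chi-square reference on
  groups − 1 degrees of freedom, applied to pre-to-post *changes* across
  study levels.
* **Spearman correlations** are Pearson correlations of mid-ranks
  (tie-safe); the p-value uses the t approximation
  `t = R * sqrt((n-2)/(1-R^2))`. Magnitudes follow the published bands
  applied to |R| — weak 0.20–0.30, moderate 0.30–0.60, vital 0.60–0.80,
  very strong ≥ 0.80 — with boundaries going to the higher band and
  |R| < 0.20 labelled "negligible" (the published bands leave the floor
  undefined).
* **Moderation GLM**: Gaussian identity-link model of AAS on study-level
  dummies (Beginner reference), PSS, AMS, and the **raw, uncentered**
  PSS×AMS product, fitted separately per period. The published
  interaction scale (≈ 0.02 AAS points per PSS-point × AMS-point) is only
  meaningful uncentered, so no centering is applied. Confidence intervals
  are Wald intervals. College enters only when the cohort has more than
  one college (the calibration cohort had one). No multiple-testing
  correction is applied, matching the original analysis; users can adjust
  p-values themselves (e.g. `p.adjust(..., "holm")`).

## The synthetic cohort generator

### Why two modes

The published results contain both a correlation structure (Spearman
0.474 / 0.531 / 0.396 pre-exam; 0.116 / −0.063 / 0.011 post-exam) and a
regression structure (interaction 0.02 pre, 0.00 post). After clamping to
scale bounds and rounding to integers these cannot be satisfied exactly at
once, so each target family gets its own generator and each acceptance
check is attributable to exactly one mode:

* **copula mode** backs the correlation and marginal-moment targets. Per
  period it draws a trivariate Gaussian whose Pearson correlations are
  `2*sin(pi*rho_s/6)` of the Spearman targets (the exact bivariate-normal
  relationship), scales to the published means/SDs, rounds and clamps.
* **moderation mode** backs the interaction targets. It draws (PSS, AMS)
  as in copula mode and sets
  `AAS = b0 + bP*PSS + bA*AMS + b_int*PSS*AMS + e`.

`calibrate_betas()` chooses `b0`, `bP`, `bA` and the residual SD in closed
form by moment matching: given the fixed interaction coefficient, the
bivariate-normal moments of PSS, AMS and their product yield two linear
equations for the main effects (from the target covariances of AAS with
PSS and AMS), a variance identity for the residual SD, and the mean
identity for the intercept. The frozen pre-exam solution is
`b0 = 17.36, bP = -0.019, bA = -0.229, resid SD = 7.16`; post-exam
`b0 = 26.94, bP = -0.122, bA = 0.053, resid SD = 8.58`. The closed form
was verified against large-sample Monte-Carlo fits before freezing.

### Items mode

`generate_items()` targets a Cronbach's alpha under compound symmetry:
the identity `alpha = k*rbar / (1 + (k-1)*rbar)` gives the required
inter-item correlation `rbar`. Discretizing Gaussian items to a few Likert
categories *attenuates* correlations (for 4 equal-probability categories
by roughly 15%), so drawing at `rbar` itself would undershoot the alpha
target by ~0.025 — outside the recovery tolerance. The generator therefore
solves for the latent Gaussian correlation whose *discretized* correlation
equals `rbar`, computing discretized correlations exactly from
bivariate-normal cell probabilities and inverting by root finding. For the
published AAS alpha of 0.912 with k = 11 four-point items this gives
`rbar = 0.485` and a latent correlation of 0.551.

### Other generator decisions

* Pre- and post-exam draws are independent across periods: no pre–post
  within-student correlations were published, so none are imposed.
* Study levels are assigned independently of scores with the published
  proportions (55.5/28.0/16.5), consistent with the published null level
  effects in the moderation models.
* Scores are rounded to integers by default (Likert totals are integers)
  and clamped to scale bounds. At the frozen calibrations the prototype
  measurements put the resulting bias at < 0.07 points on the PSS/AMS
  means, < 0.004 on the Spearman targets, and ≈ −0.0013 on the fitted
  pre-exam interaction — all inside the recovery tolerances, so no
  compensation is applied.
* Determinism: each generator call seeds the RNG from its config, so equal
  (config, seed) gives byte-identical CSV output; replication studies
  derive per-replication seeds as base + index.
* One published-summary oddity is taken at face value: the post-exam AMS
  summary (mean 20.0, observed range 11–32) sits far below the pre-exam
  mean (35.6) on the same 10–50 instrument. The generator simply uses the
  published post-exam moments; it does not speculate about a different
  form. Likewise the post-exam correlation (−0.063 with PSS) and
  interaction (0.00) are approximated jointly rather than forced exactly.

### What the generator does and does not emulate

It reproduces the published *summary structure* under Gaussian latents:
marginal moments, rank correlations, the moderation coefficient scale,
level proportions, and item-level equicorrelation. It does not emulate
skewness, floor/ceiling pile-ups beyond what clamping induces, item-level
factor structure beyond one common factor, within-student pre/post
dependence, or nonresponse. Passing recovery tests therefore shows the
pipeline is correct and well-calibrated for data *of this structure* — not
that the original raw data would yield identical estimates.

## Concordance between the two routes

`fis_scores()` plus `agreement()` operationalize the fuzzy-vs-statistics
comparison: both the crisp fuzzy estimates and the observed AAS scores are
binned by the output term ranges (boundaries to the higher bin), and the
report carries the 3×3 confusion table, percent agreement, and the
Spearman correlation between the two series. Since no numeric agreement
statistic was ever published, "agreement" here is a property threshold,
not a reproduction: on pre-exam cohorts concordance should be positive and
clearly above the 33.3% three-bin chance level, and on post-exam cohorts
(where the stress–anxiety correlation is near zero) it should collapse
toward chance — the qualitative pre/post contrast.

## Problem sizes used in validation

The recovery suites use 200 cohorts of n = 389 for the interaction
targets, 20 cohorts of n = 5000 for the correlation targets, one cohort of
n = 100 000 for the marginal means, n = 5000 students for the item-level
alpha, 500 replications of n = 5000 for GLM confidence-interval coverage,
and exhaustive enumeration (all sign patterns to n = 8; all value
assignments over a 3-level grid for 6 observations) for the rank-test
oracles. These sizes keep every Monte-Carlo standard error an order of
magnitude below its tolerance.

## Worked example

```{r example}
cfg <- generator_config(n = 389, seed = 1)
cohort <- generate_copula(cfg)
describe(cohort)[1:2, ]

fit <- fit_moderation(generate_moderation(generator_config(
  n = 389, seed = 1, mode = "moderation")), "pre")
fit$coefficients[fit$coefficients$term == "PSS:AMS", ]

out <- infer(list(PSS = 29, AMS = 45), default_anxiety_config())
out$crisp
```
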