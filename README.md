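# examfis

Fuzzy inference and statistical modelling of academic exam anxiety from
perceived stress and achievement motivation.

## What this is for

Pre/post exam-anxiety questionnaire studies typically collect three
instruments per student: the Perceived Stress Scale (PSS, 10 items, total
0–40), a revised Achievement Motives Scale (AMS, 10 items, total 10–50),
and an Academic Anxiety Scale (AAS, 11 four-point items, total 11–44).
`examfis` implements two complementary analyses of such cohorts:

* **A Mamdani fuzzy inference system.** Each input is partitioned into
  Low/Medium/High triangular terms (PSS: 0–13 / 13–26 / 26–40; AMS:
  10–25 / 25–36 / 36–50), a nine-rule If–Then base links stress and
  motivation to anxiety, and the crisp estimate is the centroid of the
  max-aggregated, min-clipped consequents:

  `membership(x) = max(0, min((x−a1)/(a2−a1), (a3−x)/(a3−a2)))`

  `crisp = ∫ x·μ(x) dx / ∫ μ(x) dx` over the AAS range 11–44.

* **The conventional statistical pipeline.** Median (IQR) descriptives,
  Cronbach's alpha, Wilcoxon signed-rank pre/post tests, Kruskal–Wallis
  tests across study levels, Spearman correlations R with magnitude bands
  (weak 0.20–0.30, moderate 0.30–0.60, vital 0.60–0.80, very strong
  ≥ 0.80), and per-period Gaussian GLMs

  `AAS ~ study_level + PSS + AMS + PSS:AMS`

  in which the uncentered PSS×AMS coefficient β measures how motivation
  moderates the stress→anxiety relationship.

Because the underlying survey data were never deposited, the package
includes a synthetic cohort generator calibrated to the published summary
statistics (n = 389; pre-exam PSS 23.2 ± 5.8, AMS 35.6 ± 7.0, AAS
25.7 ± 8.8; Spearman 0.474/0.531/0.396 pre and 0.116/−0.063/0.011 post;
interaction β = 0.02 pre and 0.00 post; AAS alpha 0.912), so every stage
is validated by parameter recovery. A concordance module quantifies how
well the fuzzy estimates track observed anxiety scores.

## Worked example

```r
library(examfis)

cohort <- generate_copula(generator_config(n = 389, seed = 1))
describe(cohort)[1:3, ]
#>   scale period median q1 q3 mean   sd min max   n
#> 1   PSS    pre     23 20 27 23.4 5.67   6  39 389
#> 2   AMS    pre     35 30 40 35.3 7.14  16  50 389
#> 3   AAS    pre     25 19 31 25.6 8.37  11  44 389

spearman_cor(cohort$PSS_pre, cohort$AMS_pre, labels = c("PSS", "AMS"))
#> Spearman PSS ~ AMS: R = 0.407 (moderate), p = < 2.22e-16, n = 389

fit <- fit_moderation(generate_moderation(
  generator_config(n = 389, seed = 1, mode = "moderation")), "pre")
fit$coefficients[fit$coefficients$term == "PSS:AMS", ]
#>      term   estimate      ci_lo      ci_hi     p_value
#> 6 PSS:AMS 0.02699878 0.01053615 0.04346141 0.001294075

infer(list(PSS = 29, AMS = 45), default_anxiety_config())
#> crisp output: 38.5
#> fired rules:
#>   -> High at 0.4286
```

A single cohort of 389 reproduces the published structure up to sampling
noise: the pre-exam stress/motivation correlation lands at 0.41 (target
0.474), and the fitted interaction at 0.027 (target 0.02) with a CI of
the same width as the published 0.01–0.02 scale. The fuzzy probe shows a
student with high stress (29) and high motivation (45) firing the
High×High→High rule at grade 3/7 ≈ 0.43, giving a crisp anxiety of 38.5 —
the centre of the High anxiety band.

Concordance between the two routes on the same cohort:

```r
fs <- fis_scores(cohort, default_anxiety_config("overlap"), "pre")
agreement(fs, cohort$AAS_pre)
#> Concordance: Spearman R = 0.536, 3-bin agreement = 50.9% (n = 389)
```

— positive rank agreement and well above the 33.3% three-bin chance level
before the exam; on post-exam scores (where stress and anxiety decouple)
it collapses toward chance.

## Command line

A thin dispatcher over the same functions lives at `inst/cli/examfis.R`:

```sh
Rscript inst/cli/examfis.R generate --out cohort.csv --seed 1 --n 389
Rscript inst/cli/examfis.R analyze  --input cohort.csv --out report/
Rscript inst/cli/examfis.R infer    --pss 29 --ams 45
Rscript inst/cli/examfis.R validate --input cohort.csv
```

`analyze` writes `report.json`, `report.md` and per-period confusion
matrices; `generate` writes the cohort CSV plus a provenance sidecar with
the config hash and seed.

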