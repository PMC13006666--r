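Package: examfis
Title: Fuzzy Inference and Statistical Modelling of Academic Exam Anxiety
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models academic exam anxiety from perceived stress and
    achievement motivation with a Mamdani-style fuzzy inference system
    (triangular and trapezoidal membership functions, If-Then rule base,
    centroid defuzzification) alongside the conventional statistical
    pipeline for pre/post questionnaire studies: psychometric scale
    scoring with Cronbach's alpha, descriptive summaries, Wilcoxon
    signed-rank and Kruskal-Wallis tests, Spearman correlations with
    magnitude interpretation, and moderation analysis via Gaussian
    generalized linear models with a stress-by-motivation interaction.
    Includes a calibrated synthetic cohort generator (Gaussian copula,
    moderation-model, and equicorrelated Likert-item modes) for
    parameter-recovery validation, and a concordance module comparing
    fuzzy anxiety estimates with observed scale scores.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    mvtnorm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
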