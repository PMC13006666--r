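test_that("descriptive summaries match hand quartiles under linear interpolation", {
  cohort <- toy_cohort(n = 10)[1:5, ]
  cohort$PSS_pre <- 1:5
  cohort$AMS_pre <- rep(7, 5)
  d <- describe(cohort)
  pss <- d[d$scale == "PSS" & d$period == "pre", ]
  expect_equal(pss$median, 3)
  expect_equal(pss$q1, 2)
  expect_equal(pss$q3, 4)
  ams <- d[d$scale == "AMS" & d$period == "pre", ]
  expect_equal(c(ams$median, ams$mean, ams$min, ams$max), rep(7, 4))
  expect_equal(c(ams$q1, ams$q3), c(7, 7))
  expect_true(all(d$q1 <= d$median & d$median <= d$q3))
  expect_true(all(d$min <= d$mean & d$mean <= d$max))
  expect_error(describe(cohort[0, ]), "empty")
})

test_that("descriptives and alpha on a fixed-seed cohort are stable across runs", {
  a <- describe(toy_cohort(n = 200, seed = 123))
  b <- describe(toy_cohort(n = 200, seed = 123))
  expect_identical(a, b)
  i1 <- generate_items(builtin_scale("AAS"), 0.912, n = 300, seed = 123)
  i2 <- generate_items(builtin_scale("AAS"), 0.912, n = 300, seed = 123)
  expect_identical(cronbach_alpha(i1), cronbach_alpha(i2))
})

test_that("signed-rank test: degenerate, shifted and hand-ranked cases", {
  x <- c(10, 12, 15, 11, 9)
  res <- wilcoxon_prepost(x, x)
  expect_true(res$degenerate)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$n_zero, 5)

  set.seed(6)
  pre <- rnorm(50, 20, 4)
  res <- wilcoxon_prepost(pre, pre + 3)
  expect_lt(res$p_value, 0.001)
  # positive shift: statistic above its null mean n(n+1)/4
  expect_gt(res$statistic, 50 * 51 / 4)

  # differences (+1, +2, -3): positive ranks 1 + 2
  res <- wilcoxon_prepost(c(0, 0, 0), c(1, 2, -3))
  expect_equal(unname(res$statistic), 3)
})

test_that("signed-rank statistic and exact p match full sign enumeration", {
  set.seed(14)
  for (n in c(4, 6, 8)) {
    for (rep in 1:8) {
      d <- round(runif(n, 0.5, 9.5), 1)
      d <- d * sample(c(-1, 1), n, replace = TRUE)
      d <- d[d != 0]
      if (anyDuplicated(abs(d))) next
      oracle <- oracle_signed_rank(d)
      res <- wilcoxon_prepost(rep(0, length(d)), d)
      expect_equal(unname(res$statistic), oracle$statistic)
      expect_equal(res$p_value, oracle$p_value, tolerance = 1e-12)
    }
  }
})

test_that("Kruskal-Wallis matches the hand-ranked example and brute-force H on small cases", {
  res <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b", "c"), each = 2))
  expect_equal(unname(res$statistic), 32 / 7, tolerance = 1e-12)

  # identical group distributions: H = 0
  res0 <- kruskal_wallis(rep(c(1, 2), 3), rep(c("a", "b", "c"), each = 2))
  expect_equal(unname(res0$statistic), 0)

  # exhaustive small cases with ties vs the from-scratch oracle
  grid <- expand.grid(rep(list(1:3), 6))
  groups <- rep(c("g1", "g2", "g3"), each = 2)
  set.seed(2)
  for (i in sample(nrow(grid), 400)) {
    v <- as.numeric(grid[i, ])
    if (length(unique(v)) == 1) next  # H undefined (0/0) when all tie
    expect_equal(unname(kruskal_wallis(v, groups)$statistic),
                 oracle_kw_h(v, groups), tolerance = 1e-12)
  }
})

test_that("Kruskal-Wallis H is non-negative and shift-invariant", {
  set.seed(15)
  for (rep in 1:20) {
    v <- sample(1:5, 12, replace = TRUE)
    g <- rep(c("a", "b", "c"), each = 4)
    if (length(unique(v)) == 1) next
    h <- unname(kruskal_wallis(v, g)$statistic)
    expect_gte(h, 0)
    expect_equal(unname(kruskal_wallis(v + 100, g)$statistic), h)
  }
  expect_error(kruskal_wallis(1:5, rep("a", 5)), "at least 2 groups")
})

test_that("Spearman correlation matches hand ranks, with a t-approximation p", {
  expect_equal(spearman_cor(1:10, (1:10)^3)$R, 1)
  expect_equal(spearman_cor(1:10, -(1:10))$R, -1)
  res <- spearman_cor(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(res$R, 0.8)
  tt <- 0.8 * sqrt(2 / (1 - 0.64))
  expect_equal(res$p_value, 2 * pt(-tt, 2))
  expect_error(spearman_cor(rep(1, 6), 1:6), "zero rank variance")
  expect_error(spearman_cor(1:3, 3:1), "at least 4")
})

test_that("Spearman R is invariant to strictly monotone transforms and tie-safe", {
  set.seed(16)
  for (rep in 1:15) {
    x <- sample(1:8, 30, replace = TRUE)  # heavy ties
    y <- sample(1:8, 30, replace = TRUE)
    r <- spearman_cor(x, y)$R
    expect_equal(spearman_cor(exp(x / 2), y)$R, r, tolerance = 1e-12)
    expect_equal(spearman_cor(x, y^3)$R, r, tolerance = 1e-12)
    expect_equal(r, oracle_spearman(x, y), tolerance = 1e-12)
  }
})

test_that("correlation magnitudes follow the published bands", {
  expect_equal(interpret_magnitude(0.474), "moderate")
  expect_equal(interpret_magnitude(0.116), "negligible")
  expect_equal(interpret_magnitude(-0.85), "very strong")
  expect_equal(interpret_magnitude(0.25), "weak")
  expect_equal(interpret_magnitude(0.65), "vital")
  # boundaries go to the higher band
  expect_equal(interpret_magnitude(0.2), "weak")
  expect_equal(interpret_magnitude(0.3), "moderate")
  expect_equal(interpret_magnitude(0.6), "vital")
  expect_equal(interpret_magnitude(0.8), "very strong")
})

test_that("moderation GLM recovers a noiseless linear law exactly", {
  cohort <- toy_cohort(n = 200, seed = 33)
  cohort$AAS_pre <- 1 + 0.5 * cohort$PSS_pre + 0.1 * cohort$AMS_pre +
    0.02 * cohort$PSS_pre * cohort$AMS_pre
  fit <- fit_moderation(cohort, "pre")
  est <- fit$coefficients
  expect_equal(est$estimate[est$term == "(Intercept)"], 1, tolerance = 1e-8)
  expect_equal(est$estimate[est$term == "PSS"], 0.5, tolerance = 1e-8)
  expect_equal(est$estimate[est$term == "AMS"], 0.1, tolerance = 1e-8)
  expect_equal(interaction_coef(fit), 0.02, tolerance = 1e-8)
  expect_equal(est$estimate[grepl("study_level", est$term)],
               c(0, 0), tolerance = 1e-8)
  expect_true(all(est$ci_lo <= est$estimate & est$estimate <= est$ci_hi))
})

test_that("with pure-noise anxiety the interaction CI usually covers zero", {
  covers <- vapply(1:5, function(s) {
    cohort <- toy_cohort(n = 5000, seed = 33 + s)
    set.seed(1000 + s)
    cohort$AAS_pre <- pmin(pmax(round(rnorm(5000, 25, 8)), 11), 44)
    fit <- fit_moderation(cohort, "pre")
    ci <- fit$coefficients[fit$coefficients$term == "PSS:AMS", ]
    ci$ci_lo <= 0 && 0 <= ci$ci_hi
  }, logical(1))
  expect_gte(sum(covers), 4)
})

test_that("moderation fit rejects degenerate designs", {
  cohort <- toy_cohort(n = 100, seed = 35)
  cohort$PSS_pre <- 20
  expect_error(fit_moderation(cohort, "pre"), "non-constant")
  expect_error(fit_moderation(toy_cohort(n = 20), "pre"), "at least 30")
})
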