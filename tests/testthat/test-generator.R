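test_that("spearman_to_pearson matches the closed form and its limits", {
  expect_equal(spearman_to_pearson(0), 0)
  expect_equal(spearman_to_pearson(0.474), 2 * sin(pi * 0.474 / 6))
  expect_equal(spearman_to_pearson(0.474), 0.4913, tolerance = 1e-4)
  expect_equal(spearman_to_pearson(1 - 1e-9), 1, tolerance = 1e-6)
  expect_equal(spearman_to_pearson(-0.5), -spearman_to_pearson(0.5))
  expect_error(spearman_to_pearson(1), "rho_s")
  expect_error(spearman_to_pearson(-1.2), "rho_s")
})

test_that("equal seeds reproduce cohorts exactly, different seeds do not", {
  cfg <- generator_config(n = 100, seed = 77)
  expect_identical(generate_copula(cfg), generate_copula(cfg))
  cfg2 <- generator_config(n = 100, seed = 78)
  expect_false(identical(generate_copula(cfg), generate_copula(cfg2)))
  mcfg <- generator_config(n = 100, seed = 77, mode = "moderation")
  expect_identical(generate_moderation(mcfg), generate_moderation(mcfg))
  expect_identical(generate_cohort(mcfg), generate_moderation(mcfg))
})

test_that("generated scores always respect the scale bounds", {
  for (mode in c("copula", "moderation")) {
    cohort <- generate_cohort(generator_config(n = 2000, seed = 5, mode = mode))
    expect_true(all(cohort$PSS_pre >= 0 & cohort$PSS_pre <= 40))
    expect_true(all(cohort$PSS_post >= 0 & cohort$PSS_post <= 40))
    expect_true(all(cohort$AMS_pre >= 10 & cohort$AMS_pre <= 50))
    expect_true(all(cohort$AAS_pre >= 11 & cohort$AAS_pre <= 44))
    expect_true(all(cohort$AAS_post >= 11 & cohort$AAS_post <= 44))
    expect_equal(nrow(validate_cohort(cohort)), 0)
  }
})

test_that("zero correlation targets yield near-independent scores", {
  cal <- period_calibration("pre", means = c(20, 30, 25), sds = c(5, 6, 7),
                            spearman = c(0, 0, 0))
  cfg <- generator_config(n = 5000, seed = 31, pre = cal)
  cohort <- generate_copula(cfg)
  expect_lt(abs(cor(cohort$PSS_pre, cohort$AMS_pre, method = "spearman")), 0.05)
  expect_lt(abs(cor(cohort$PSS_pre, cohort$AAS_pre, method = "spearman")), 0.05)
})

test_that("infeasible correlation targets are rejected as non-positive-definite", {
  expect_error(
    generate_copula(generator_config(
      n = 50, seed = 1,
      pre = period_calibration("pre", means = c(20, 30, 25),
                               sds = c(5, 6, 7),
                               spearman = c(0.9, 0.9, -0.9)))),
    "positive-definite")
})

test_that("calibrate_betas reproduces textbook regression coefficients when the interaction is zero", {
  cal <- period_calibration("post", means = c(18, 22, 26), sds = c(5, 4, 8),
                            spearman = c(0.3, 0.4, 0.2),
                            beta_interaction = 0)
  # oracle: OLS on a huge unclamped, unrounded sample from the same latents
  cfg <- generator_config(n = 2e5, seed = 13, mode = "moderation",
                          pre = cal, post = cal,
                          rounding = "none", clamp = FALSE)
  cohort <- generate_moderation(cfg)
  fit <- lm(AAS_post ~ PSS_post + AMS_post, data = cohort)
  expect_equal(unname(coef(fit)),
               unname(c(cal$betas["b0"], cal$betas["bP"], cal$betas["bA"])),
               tolerance = 0.05)
  expect_equal(sd(cohort$AAS_post), 8, tolerance = 0.05)
  expect_equal(mean(cohort$AAS_post), 26, tolerance = 0.05)
})

test_that("degenerate moderation settings produce a constant anxiety score", {
  cal <- period_calibration("pre", means = c(20, 30, 25), sds = c(5, 6, 7),
                            spearman = c(0.3, 0.4, 0.3),
                            beta_interaction = 0,
                            betas = c(b0 = 25, bP = 0, bA = 0), resid_sd = 0)
  cfg <- generator_config(n = 50, seed = 2, mode = "moderation",
                          pre = cal, post = cal, rounding = "none")
  cohort <- generate_moderation(cfg)
  expect_true(all(cohort$AAS_pre == 25))
})

test_that("with zero residual noise the downstream fit recovers the betas to machine precision", {
  cal <- period_calibration("pre", means = c(20, 30, 25), sds = c(5, 6, 7),
                            spearman = c(0.3, 0.4, 0.3),
                            beta_interaction = 0.02,
                            betas = c(b0 = 1, bP = 0.5, bA = 0.1),
                            resid_sd = 0)
  cfg <- generator_config(n = 500, seed = 8, mode = "moderation",
                          pre = cal, post = cal,
                          rounding = "none", clamp = FALSE)
  cohort <- generate_moderation(cfg)
  fit <- fit_moderation(cohort, "pre")
  est <- fit$coefficients
  expect_equal(est$estimate[est$term == "(Intercept)"], 1, tolerance = 1e-8)
  expect_equal(est$estimate[est$term == "PSS"], 0.5, tolerance = 1e-8)
  expect_equal(est$estimate[est$term == "AMS"], 0.1, tolerance = 1e-8)
  expect_equal(interaction_coef(fit), 0.02, tolerance = 1e-8)
})

test_that("infeasible moment targets raise a calibration error", {
  # a large interaction coefficient forces more systematic variance than a
  # tiny AAS SD can absorb, even though the correlation targets are valid
  expect_error(
    period_calibration("pre", means = c(20, 30, 25), sds = c(5, 6, 0.5),
                       spearman = c(0.3, 0.1, 0.1),
                       beta_interaction = 0.5),
    "infeasible")
})

test_that("the compound-symmetry identity inversion matches hand values", {
  expect_equal(alpha_to_rbar(0.912, 11), 0.912 / (11 - 0.912 * 10))
  expect_equal(alpha_to_rbar(0.912, 11), 0.485, tolerance = 1e-3)
  # alpha -> 0 implies rbar -> 0
  expect_lt(alpha_to_rbar(1e-4, 11), 1e-4)
  expect_error(alpha_to_rbar(1.2, 11), "alpha")
  expect_error(alpha_to_rbar(0, 11), "alpha")
})

test_that("generated item matrices live on the Likert range and reproduce a mid-range alpha", {
  aas <- builtin_scale("AAS")
  items <- generate_items(aas, target_alpha = 0.7, n = 2000, seed = 19)
  expect_s3_class(items, "likert_matrix")
  expect_true(all(items$values %in% 1:4))
  expect_equal(cronbach_alpha(items), 0.7, tolerance = 0.03)
  # determinism
  again <- generate_items(aas, target_alpha = 0.7, n = 2000, seed = 19)
  expect_identical(items$values, again$values)
})

test_that("generator configurations round-trip through JSON and YAML", {
  cfg <- generator_config(n = 123, seed = 9, mode = "moderation")
  for (ext in c(".json", ".yml")) {
    path <- withr::local_tempfile(fileext = ext)
    write_generator_config(cfg, path)
    back <- read_generator_config(path)
    expect_identical(generate_cohort(back), generate_cohort(cfg))
  }
})

test_that("study levels follow the configured proportions", {
  cohort <- generate_copula(generator_config(n = 20000, seed = 44))
  props <- table(cohort$study_level) / nrow(cohort)
  expect_equal(unname(props[["Beginner"]]), 0.555, tolerance = 0.02)
  expect_equal(unname(props[["Intermediate"]]), 0.280, tolerance = 0.02)
  expect_equal(unname(props[["Seniors"]]), 0.165, tolerance = 0.02)
})
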