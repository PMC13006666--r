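#' Convert a Spearman target to a Gaussian-latent Pearson correlation
#'
#' For a bivariate normal vector, the population Spearman correlation
#' `rho_s` and the Pearson correlation `rho` are linked by
#' `rho = 2 * sin(pi * rho_s / 6)`. Latent draws at the converted Pearson
#' value therefore hit the requested Spearman target.
#'
#' @param rho_s Spearman correlation target, `|rho_s| < 1`.
#' @return The Pearson correlation of the Gaussian latent.
#' @export
spearman_to_pearson <- function(rho_s) {
  if (any(!is.finite(rho_s)) || any(abs(rho_s) >= 1)) {
    stop("Spearman targets must satisfy |rho_s| < 1")
  }
  2 * sin(pi * rho_s / 6)
}

#' Per-period generator calibration
#'
#' Bundles the marginal moments, Spearman correlation targets and
#' moderation-model coefficients for one measurement period. The scale
#' order throughout is PSS, AMS, AAS.
#'
#' @param period `"pre"` or `"post"`.
#' @param means,sds length-3 numeric vectors named PSS, AMS, AAS.
#' @param spearman length-3 numeric targets named `PSS_AMS`, `PSS_AAS`,
#'   `AMS_AAS`.
#' @param beta_interaction the PSS-by-AMS moderation coefficient used by
#'   the moderation-mode generator.
#' @param betas optional named vector `(b0, bP, bA)`; filled in by
#'   [calibrate_betas()] when `NULL`.
#' @param resid_sd optional residual SD of the moderation model; filled in
#'   by [calibrate_betas()] when `NULL`.
#' @return An object of class `period_calibration`.
#' @export
period_calibration <- function(period, means, sds, spearman,
                               beta_interaction = 0,
                               betas = NULL, resid_sd = NULL) {
  period <- match.arg(period, c("pre", "post"))
  stopifnot(length(means) == 3, length(sds) == 3, length(spearman) == 3)
  if (any(sds <= 0)) stop("calibration SDs must be positive")
  if (any(abs(spearman) >= 1)) stop("Spearman targets must lie in (-1, 1)")
  r12 <- spearman_to_pearson(spearman[[1]])
  if (abs(r12) >= 1) {
    stop("latent (PSS, AMS) correlation from target '",
         spearman[[1]], "' is not positive-definite")
  }
  cal <- structure(
    list(period = period,
         means = stats::setNames(as.numeric(means), c("PSS", "AMS", "AAS")),
         sds = stats::setNames(as.numeric(sds), c("PSS", "AMS", "AAS")),
         spearman = stats::setNames(as.numeric(spearman),
                                    c("PSS_AMS", "PSS_AAS", "AMS_AAS")),
         beta_interaction = beta_interaction,
         betas = betas, resid_sd = resid_sd),
    class = "period_calibration")
  latent_corr_matrix(cal)  # reject non-positive-definite target triples
  if (is.null(betas) || is.null(resid_sd)) cal <- calibrate_betas(cal)
  cal
}

#' Frozen default calibrations
#'
#' The published cohort summaries the generator is calibrated to:
#' pre-exam PSS 23.2 (SD 5.8), AMS 35.6 (7.0), AAS 25.7 (8.8) with
#' Spearman correlations 0.474 (PSS-AMS), 0.531 (PSS-AAS), 0.396 (AMS-AAS)
#' and interaction coefficient 0.02; post-exam PSS 18.8 (4.8), AMS 20.0
#' (3.2), AAS 25.7 (8.6) with Spearman 0.116, -0.063, 0.011 and
#' interaction 0.00. Moderation betas and the residual SD are derived by
#' [calibrate_betas()].
#'
#' @param period `"pre"` or `"post"`.
#' @return A [period_calibration()].
#' @export
default_calibration <- function(period = c("pre", "post")) {
  period <- match.arg(period)
  if (period == "pre") {
    period_calibration("pre",
                       means = c(23.2, 35.6, 25.7),
                       sds = c(5.8, 7.0, 8.8),
                       spearman = c(0.474, 0.531, 0.396),
                       beta_interaction = 0.02)
  } else {
    period_calibration("post",
                       means = c(18.8, 20.0, 25.7),
                       sds = c(4.8, 3.2, 8.6),
                       spearman = c(0.116, -0.063, 0.011),
                       beta_interaction = 0.00)
  }
}

#' Derive moderation betas by moment matching
#'
#' Given the marginal moments, the (PSS, AMS) correlation and a fixed
#' interaction coefficient, solves in closed form for `b0`, `bP`, `bA` and
#' the residual SD of `AAS = b0 + bP*PSS + bA*AMS + b_int*PSS*AMS + e` such
#' that the anxiety score reproduces the target mean and SD and its
#' Pearson covariances with PSS and AMS match the (latent-converted)
#' Spearman targets. Uses the exact bivariate-normal moments of the
#' product term, so the solution is deterministic.
#'
#' @param cal a [period_calibration()].
#' @return The calibration with `betas` and `resid_sd` filled in.
#' @export
calibrate_betas <- function(cal) {
  stopifnot(inherits(cal, "period_calibration"))
  mup <- cal$means[["PSS"]]; mua <- cal$means[["AMS"]]
  muy <- cal$means[["AAS"]]
  sp <- cal$sds[["PSS"]]; sa <- cal$sds[["AMS"]]; sy <- cal$sds[["AAS"]]
  r <- spearman_to_pearson(cal$spearman[["PSS_AMS"]])
  ryp <- spearman_to_pearson(cal$spearman[["PSS_AAS"]])
  rya <- spearman_to_pearson(cal$spearman[["AMS_AAS"]])
  bint <- cal$beta_interaction

  cpa <- r * sp * sa                       # Cov(P, A)
  cov_pa_p <- mua * sp^2 + mup * cpa       # Cov(P*A, P)
  cov_pa_a <- mup * sa^2 + mua * cpa       # Cov(P*A, A)
  var_pa <- mup^2 * sa^2 + mua^2 * sp^2 + sp^2 * sa^2 + cpa^2 +
    2 * mup * mua * cpa                    # Var(P*A)

  A <- rbind(c(sp^2, cpa), c(cpa, sa^2))
  b <- c(ryp * sy * sp - bint * cov_pa_p,
         rya * sy * sa - bint * cov_pa_a)
  beta <- solve(A, b)

  v_sys <- beta[1]^2 * sp^2 + beta[2]^2 * sa^2 + bint^2 * var_pa +
    2 * beta[1] * beta[2] * cpa +
    2 * beta[1] * bint * cov_pa_p + 2 * beta[2] * bint * cov_pa_a
  resid_var <- sy^2 - v_sys
  if (resid_var < 0) {
    stop("infeasible calibration: systematic variance exceeds the target ",
         "AAS variance by ", format(-resid_var))
  }
  b0 <- muy - beta[1] * mup - beta[2] * mua - bint * (mup * mua + cpa)
  cal$betas <- c(b0 = unname(b0), bP = unname(beta[1]), bA = unname(beta[2]))
  cal$resid_sd <- sqrt(resid_var)
  cal
}

#' Generator configuration
#'
#' @param n cohort size (default 389, the published sample).
#' @param seed integer RNG seed.
#' @param mode `"copula"` (backs the correlation targets) or
#'   `"moderation"` (backs the interaction targets); see the package
#'   vignette for why the two structures are generated separately.
#' @param pre,post [period_calibration()] objects.
#' @param rounding `"integer"` (Likert totals are integers) or `"none"`.
#' @param clamp clamp generated scores to the scale bounds (default TRUE).
#' @param level_probs study-level proportions, default 55.5/28.0/16.5
#'   percent for Beginner/Intermediate/Seniors.
#' @param college single college label (the published cohort had one).
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n = 389, seed = 1,
                             mode = c("copula", "moderation"),
                             pre = default_calibration("pre"),
                             post = default_calibration("post"),
                             rounding = c("integer", "none"),
                             clamp = TRUE,
                             level_probs = c(Beginner = 0.555,
                                             Intermediate = 0.280,
                                             Seniors = 0.165),
                             college = "College of Health and Rehabilitation Sciences") {
  mode <- match.arg(mode)
  rounding <- match.arg(rounding)
  if (n < 10) stop("cohort size n must be at least 10")
  stopifnot(inherits(pre, "period_calibration"),
            inherits(post, "period_calibration"))
  structure(list(n = as.integer(n), seed = as.integer(seed), mode = mode,
                 pre = pre, post = post, rounding = rounding, clamp = clamp,
                 level_probs = level_probs, college = college),
            class = "generator_config")
}

finish_scores <- function(x, scale, config) {
  if (config$rounding == "integer") x <- round(x)
  if (config$clamp) x <- pmin(pmax(x, scale$score_min), scale$score_max)
  x
}

latent_corr_matrix <- function(cal) {
  r <- spearman_to_pearson(cal$spearman)
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- r[["PSS_AMS"]]
  R[1, 3] <- R[3, 1] <- r[["PSS_AAS"]]
  R[2, 3] <- R[3, 2] <- r[["AMS_AAS"]]
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop("Spearman targets (", paste(cal$spearman, collapse = ", "),
         ") imply a non-positive-definite latent correlation matrix")
  }
  R
}

draw_levels <- function(n, config) {
  sample(names(config$level_probs), n, replace = TRUE,
         prob = config$level_probs)
}

cohort_frame <- function(n, config, scores_pre, scores_post) {
  data.frame(
    student_id = sprintf("S%04d", seq_len(n)),
    study_level = draw_levels(n, config),
    college = config$college,
    PSS_pre = scores_pre[, 1], AMS_pre = scores_pre[, 2],
    AAS_pre = scores_pre[, 3],
    PSS_post = scores_post[, 1], AMS_post = scores_post[, 2],
    AAS_post = scores_post[, 3],
    stringsAsFactors = FALSE
  )
}

draw_trivariate <- function(n, cal) {
  R <- latent_corr_matrix(cal)
  z <- matrix(stats::rnorm(3 * n), n, 3) %*% chol(R)
  sweep(sweep(z, 2, cal$sds, "*"), 2, cal$means, "+")
}

scale_triplet <- function() {
  list(builtin_scale("PSS"), builtin_scale("AMS"), builtin_scale("AAS"))
}

#' Generate a cohort from the Gaussian copula calibration
#'
#' Per period, draws a trivariate Gaussian latent whose Pearson
#' correlations are the latent-converted Spearman targets
#' ([spearman_to_pearson()]), scales to the target means/SDs, optionally
#' rounds to integers and clamps to the scale bounds. Pre- and post-exam
#' draws are independent across periods. Study levels are assigned
#' independently of scores.
#'
#' @param config a [generator_config()].
#' @return A cohort data frame (see [as_cohort()]).
#' @export
generate_copula <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  scales <- scale_triplet()
  period_scores <- lapply(list(config$pre, config$post), function(cal) {
    x <- draw_trivariate(config$n, cal)
    for (j in 1:3) x[, j] <- finish_scores(x[, j], scales[[j]], config)
    x
  })
  cohort_frame(config$n, config, period_scores[[1]], period_scores[[2]])
}

#' Generate a cohort from the moderation-model calibration
#'
#' Per period, draws (PSS, AMS) as a bivariate Gaussian at the
#' latent-converted correlation target, then sets
#' `AAS = b0 + bP*PSS + bA*AMS + b_int*PSS*AMS + e` with Gaussian residual
#' at the calibrated SD ([calibrate_betas()]), then rounds/clamps. The
#' default interaction coefficients are 0.02 (pre-exam) and 0.00
#' (post-exam).
#'
#' @param config a [generator_config()].
#' @return A cohort data frame.
#' @export
generate_moderation <- function(config = generator_config(mode = "moderation")) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  scales <- scale_triplet()
  period_scores <- lapply(list(config$pre, config$post), function(cal) {
    if (is.null(cal$betas)) cal <- calibrate_betas(cal)
    r <- spearman_to_pearson(cal$spearman[["PSS_AMS"]])
    z1 <- stats::rnorm(config$n)
    z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(config$n)
    P <- cal$means[["PSS"]] + cal$sds[["PSS"]] * z1
    A <- cal$means[["AMS"]] + cal$sds[["AMS"]] * z2
    Y <- cal$betas[["b0"]] + cal$betas[["bP"]] * P + cal$betas[["bA"]] * A +
      cal$beta_interaction * P * A +
      stats::rnorm(config$n, 0, cal$resid_sd)
    x <- cbind(P, A, Y)
    for (j in 1:3) x[, j] <- finish_scores(x[, j], scales[[j]], config)
    x
  })
  cohort_frame(config$n, config, period_scores[[1]], period_scores[[2]])
}

#' Generate a cohort
#'
#' Dispatches on `config$mode` to [generate_copula()] or
#' [generate_moderation()].
#'
#' @param config a [generator_config()].
#' @return A cohort data frame.
#' @export
generate_cohort <- function(config = generator_config()) {
  switch(config$mode,
         copula = generate_copula(config),
         moderation = generate_moderation(config))
}

#' Inter-item correlation implied by a Cronbach's alpha target
#'
#' Inverts the compound-symmetry identity
#' `alpha = k * rbar / (1 + (k - 1) * rbar)`.
#'
#' @param alpha target alpha in (0, 1).
#' @param k number of items.
#' @return The common inter-item correlation `rbar`.
#' @export
alpha_to_rbar <- function(alpha, k) {
  if (alpha <= 0 || alpha >= 1) stop("target alpha must lie in (0, 1)")
  rbar <- alpha / (k - alpha * (k - 1))
  if (rbar <= 0 || rbar >= 1) {
    stop("implied inter-item correlation ", format(rbar),
         " is outside (0, 1)")
  }
  rbar
}

# Pearson correlation of two equal-probability discretized standard
# normals as a function of their latent correlation (exact, via
# bivariate-normal cell probabilities).
discretized_corr <- function(rho, n_cats) {
  th <- stats::qnorm(seq(0, 1, length.out = n_cats + 1))
  S <- matrix(c(1, rho, rho, 1), 2)
  exy <- 0
  for (i in seq_len(n_cats)) {
    for (j in seq_len(n_cats)) {
      p <- mvtnorm::pmvnorm(lower = c(th[i], th[j]),
                            upper = c(th[i + 1], th[j + 1]), sigma = S)
      exy <- exy + i * j * as.numeric(p)
    }
  }
  cats <- seq_len(n_cats)
  (exy - mean(cats)^2) / (mean(cats^2) - mean(cats)^2)
}

# Latent Gaussian correlation whose discretized correlation equals the
# requested value; discretizing attenuates correlations, so the latent
# value is solved for rather than used directly.
latent_item_rho <- function(target_r, n_cats) {
  # attenuation guarantees f(target_r) < 0, so the root lies above target_r
  f <- function(r) discretized_corr(r, n_cats) - target_r
  if (f(0.999) < 0) {
    stop("inter-item correlation ", format(target_r),
         " is not reachable after discretizing to ", n_cats, " categories")
  }
  stats::uniroot(f, interval = c(target_r, 0.999), tol = 1e-7)$root
}

#' Generate equicorrelated Likert items for a target alpha
#'
#' Solves the compound-symmetry identity for the inter-item correlation
#' implied by the target alpha, finds the latent Gaussian correlation whose
#' equal-probability discretization yields that correlation (discretizing
#' to few categories attenuates correlations, so the latent value is
#' calibrated exactly via bivariate-normal cell probabilities), draws
#' equicorrelated Gaussian items per student, and cuts them into the
#' item's Likert range at equal-probability thresholds.
#'
#' @param scale a [scale_definition()]; the number of response categories
#'   is `item_max - item_min + 1`.
#' @param target_alpha Cronbach's alpha the item matrix should exhibit.
#' @param n number of students.
#' @param seed integer RNG seed.
#' @return A [likert_matrix()].
#' @export
generate_items <- function(scale, target_alpha, n, seed = 1) {
  stopifnot(inherits(scale, "scale_definition"))
  k <- scale$n_items
  n_cats <- scale$item_max - scale$item_min + 1
  rbar <- alpha_to_rbar(target_alpha, k)
  rho <- latent_item_rho(rbar, n_cats)
  set.seed(seed)
  common <- sqrt(rho) * stats::rnorm(n)
  z <- common + sqrt(1 - rho) * matrix(stats::rnorm(n * k), n, k)
  th <- stats::qnorm(seq_len(n_cats - 1) / n_cats)
  vals <- matrix(findInterval(z, th), n, k) + scale$item_min
  likert_matrix(scale, vals)
}

generator_config_to_list <- function(config) {
  # named numeric vectors become named lists so JSON keeps the names
  cal_list <- function(cal) {
    cal <- unclass(cal)
    for (f in c("means", "sds", "spearman", "betas")) {
      if (!is.null(cal[[f]])) cal[[f]] <- as.list(cal[[f]])
    }
    cal
  }
  l <- config
  class(l) <- NULL
  l$pre <- cal_list(l$pre)
  l$post <- cal_list(l$post)
  l$level_probs <- as.list(l$level_probs)
  l
}

#' Read / write a generator configuration
#'
#' Serializes a [generator_config()] with its embedded period calibrations
#' to JSON or YAML (chosen by extension).
#'
#' @param config a [generator_config()].
#' @param path file path ending in `.json`, `.yaml` or `.yml`.
#' @return `read_generator_config` returns a [generator_config()];
#'   `write_generator_config` returns `path` invisibly.
#' @export
write_generator_config <- function(config, path) {
  stopifnot(inherits(config, "generator_config"))
  l <- generator_config_to_list(config)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(l, path)
  } else {
    jsonlite::write_json(l, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  l <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  cal <- function(p) {
    period_calibration(p$period,
                       means = unlist(p$means), sds = unlist(p$sds),
                       spearman = unlist(p$spearman),
                       beta_interaction = p$beta_interaction,
                       betas = if (!is.null(p$betas)) unlist(p$betas),
                       resid_sd = p$resid_sd)
  }
  generator_config(n = l$n, seed = l$seed, mode = l$mode,
                   pre = cal(l$pre), post = cal(l$post),
                   rounding = l$rounding, clamp = l$clamp,
                   level_probs = unlist(l$level_probs), college = l$college)
}
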