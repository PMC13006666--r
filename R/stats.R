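#' Descriptive summaries per scale and period
#'
#' Median, interquartile range, mean, SD, min and max for each of the six
#' scale-by-period score columns. Quartiles use linear interpolation
#' between order statistics (R quantile type 7); medians and IQRs of
#' integer Likert totals depend on this convention, so it is fixed and
#' documented.
#'
#' @param cohort a cohort data frame (see [as_cohort()]).
#' @return A data frame with one row per scale x period: columns `scale`,
#'   `period`, `median`, `q1`, `q3`, `mean`, `sd`, `min`, `max`, `n`.
#' @export
describe <- function(cohort) {
  cohort <- as_cohort(cohort)
  if (nrow(cohort) == 0) stop("cannot describe an empty cohort")
  rows <- lapply(cohort_score_cols(), function(col) {
    v <- cohort[[col]]
    v <- v[!is.na(v)]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(scale = sub("_(pre|post)$", "", col),
               period = sub("^.*_", "", col),
               median = q[2], q1 = q[1], q3 = q[3],
               mean = mean(v), sd = stats::sd(v),
               min = min(v), max = max(v), n = length(v),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

test_result <- function(test, statistic, p_value, n, grouping = NA_character_,
                        degenerate = FALSE) {
  structure(list(test = test, statistic = unname(statistic),
                 p_value = unname(p_value), n = n, grouping = grouping,
                 degenerate = degenerate),
            class = "examfis_test")
}

#' @export
print.examfis_test <- function(x, ...) {
  cat(x$test, ": statistic = ", format(x$statistic),
      ", p = ", format.pval(x$p_value), ", n = ", x$n,
      if (x$degenerate) " (degenerate)" else "", "\n", sep = "")
  invisible(x)
}

#' Wilcoxon signed-rank test on pre/post differences
#'
#' Paired signed-rank test on `post - pre`. Zero differences are dropped
#' before ranking (the count is reported in the result). The statistic is
#' the sum of ranks of the positive differences. With 25 or fewer non-zero
#' differences and no ties among their absolute values the exact null
#' distribution is used; otherwise the tie-corrected normal approximation
#' with continuity correction.
#'
#' @param pre,post paired numeric score vectors of equal length.
#' @return An `examfis_test` with fields `statistic`, `p_value`, `n` (the
#'   non-zero-difference count), `n_zero`, `degenerate` (TRUE when every
#'   difference is zero: statistic 0, p 1).
#' @export
wilcoxon_prepost <- function(pre, post) {
  if (length(pre) != length(post)) {
    stop("pre and post must have equal length (paired design)")
  }
  keep <- !is.na(pre) & !is.na(post)
  d <- post[keep] - pre[keep]
  nz <- d[d != 0]
  n <- length(nz)
  res <- if (n == 0) {
    test_result("Wilcoxon signed-rank", statistic = 0, p_value = 1,
                n = 0, degenerate = TRUE)
  } else {
    use_exact <- n <= 25 && !anyDuplicated(abs(nz))
    wt <- suppressWarnings(
      stats::wilcox.test(nz, mu = 0, exact = use_exact,
                         correct = !use_exact)
    )
    test_result("Wilcoxon signed-rank", statistic = wt$statistic,
                p_value = wt$p.value, n = n)
  }
  res$n_zero <- sum(d == 0)
  res
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H statistic with a chi-square reference on
#' `groups - 1` degrees of freedom.
#'
#' @param values numeric scores.
#' @param groups group labels, same length as `values`.
#' @return An `examfis_test`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) {
    stop("Kruskal-Wallis needs at least 2 groups")
  }
  if (any(table(droplevels(groups)) < 2)) {
    stop("every group needs at least 2 members")
  }
  kt <- stats::kruskal.test(values, groups)
  test_result("Kruskal-Wallis", statistic = kt$statistic,
              p_value = kt$p.value, n = length(values),
              grouping = paste(levels(droplevels(groups)), collapse = "/"))
}

#' Interpret the magnitude of a correlation
#'
#' Bands applied to `|R|`: below 0.20 "negligible" (the published bands
#' start at 0.20 and leave the floor undefined), 0.20-0.30 "weak",
#' 0.30-0.60 "moderate", 0.60-0.80 "vital", 0.80 and above "very strong".
#' Boundary values go to the higher band.
#'
#' @param R correlation in `[-1, 1]`.
#' @return A character label.
#' @export
interpret_magnitude <- function(R) {
  stopifnot(abs(R) <= 1)
  a <- abs(R)
  if (a >= 0.8) "very strong"
  else if (a >= 0.6) "vital"
  else if (a >= 0.3) "moderate"
  else if (a >= 0.2) "weak"
  else "negligible"
}

#' Spearman correlation with magnitude label
#'
#' Tie-safe Spearman R (Pearson correlation of mid-ranks) with a p-value
#' from the t approximation `t = R * sqrt((n-2) / (1-R^2))` on `n - 2`
#' degrees of freedom.
#'
#' @param x,y numeric vectors of equal length, at least 4 complete pairs.
#' @param labels optional variable-name pair for reporting.
#' @return A list of class `correlation_result`: `R`, `p_value`, `n`,
#'   `magnitude`, `pair`.
#' @export
spearman_cor <- function(x, y, labels = c("x", "y")) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) stop("Spearman correlation needs at least 4 complete pairs")
  if (stats::var(rank(x)) == 0 || stats::var(rank(y)) == 0) {
    stop("undefined correlation: zero rank variance in '",
         labels[which.min(c(stats::var(rank(x)), stats::var(rank(y))))], "'")
  }
  R <- stats::cor(x, y, method = "spearman")
  p <- if (abs(R) >= 1) 0 else {
    tt <- R * sqrt((n - 2) / (1 - R^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  structure(list(pair = labels, R = unname(R), p_value = p, n = n,
                 magnitude = interpret_magnitude(R)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman %s ~ %s: R = %.3f (%s), p = %s, n = %d\n",
              x$pair[1], x$pair[2], x$R, x$magnitude,
              format.pval(x$p_value), x$n))
  invisible(x)
}

#' Moderation model: anxiety on stress, motivation and their product
#'
#' Gaussian identity-link GLM of the period's anxiety score on study-level
#' dummies (Beginner reference), PSS, AMS and the raw (uncentered) PSS-by-
#' AMS product. The interaction coefficient is only interpretable on this
#' uncentered scale. College is included as a factor only when the cohort
#' has more than one college. Confidence intervals are Wald (normal)
#' intervals.
#'
#' @param cohort a cohort data frame.
#' @param period `"pre"` or `"post"`.
#' @return A list of class `moderation_fit`: `period`, `coefficients` (data
#'   frame with `term`, `estimate`, `ci_lo`, `ci_hi`, `p_value`), `n`, and
#'   the underlying `glm` object as `model`.
#' @export
fit_moderation <- function(cohort, period = c("pre", "post")) {
  period <- match.arg(period)
  cohort <- as_cohort(cohort)
  if (nrow(cohort) < 30) stop("moderation fit needs at least 30 records")
  df <- data.frame(
    AAS = cohort[[paste0("AAS_", period)]],
    PSS = cohort[[paste0("PSS_", period)]],
    AMS = cohort[[paste0("AMS_", period)]],
    study_level = factor(cohort$study_level, levels = study_levels()),
    college = factor(cohort$college)
  )
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (stats::var(df$PSS) == 0 || stats::var(df$AMS) == 0) {
    stop("PSS and AMS must be non-constant to fit the moderation model")
  }
  form <- if (nlevels(droplevels(df$college)) > 1) {
    AAS ~ study_level + college + PSS + AMS + PSS:AMS
  } else {
    AAS ~ study_level + PSS + AMS + PSS:AMS
  }
  fit <- stats::glm(form, family = stats::gaussian(), data = df)
  if (fit$rank < length(stats::coef(fit))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient moderation design; collinear term(s): ",
         paste(aliased, collapse = ", "))
  }
  sm <- stats::summary.glm(fit)$coefficients
  ci <- suppressMessages(stats::confint.default(fit))
  coefs <- data.frame(term = rownames(sm), estimate = sm[, 1],
                      ci_lo = ci[, 1], ci_hi = ci[, 2],
                      p_value = sm[, 4], row.names = NULL,
                      stringsAsFactors = FALSE)
  structure(list(period = period, coefficients = coefs, n = nrow(df),
                 model = fit),
            class = "moderation_fit")
}

#' @export
print.moderation_fit <- function(x, ...) {
  cat("Moderation GLM (", x$period, "-exam), n = ", x$n, "\n", sep = "")
  print(transform(x$coefficients,
                  estimate = round(estimate, 3),
                  ci_lo = round(ci_lo, 3), ci_hi = round(ci_hi, 3),
                  p_value = signif(p_value, 3)), row.names = FALSE)
  invisible(x)
}

#' Interaction coefficient of a moderation fit
#'
#' Convenience accessor for the PSS-by-AMS product term.
#'
#' @param fit a [fit_moderation()] result.
#' @return The interaction estimate as a single number.
#' @export
interaction_coef <- function(fit) {
  stopifnot(inherits(fit, "moderation_fit"))
  fit$coefficients$estimate[fit$coefficients$term == "PSS:AMS"]
}
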