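#' Fuzzy anxiety scores for a cohort
#'
#' Runs the fuzzy system over each student's (PSS, AMS) pair for the given
#' period. Records sharing a (PSS, AMS) pair are inferred once and reused,
#' so integer-scored cohorts of any size cost at most one inference per
#' distinct pair.
#'
#' @param cohort a cohort data frame.
#' @param config a [fis_config()]; default the literal-partition anxiety
#'   system.
#' @param period `"pre"` or `"post"`.
#' @return A data frame with columns `student_id`, `crisp`, `degenerate`.
#' @export
fis_scores <- function(cohort, config = default_anxiety_config(),
                       period = c("pre", "post")) {
  period <- match.arg(period)
  cohort <- as_cohort(cohort)
  if (nrow(cohort) == 0) {
    return(data.frame(student_id = character(), crisp = numeric(),
                      degenerate = logical(), stringsAsFactors = FALSE))
  }
  pss <- cohort[[paste0("PSS_", period)]]
  ams <- cohort[[paste0("AMS_", period)]]
  key <- paste(pss, ams)
  uk <- !duplicated(key)
  out <- lapply(which(uk), function(i) {
    infer(list(PSS = pss[i], AMS = ams[i]), config)
  })
  idx <- match(key, key[uk])
  data.frame(
    student_id = cohort$student_id,
    crisp = vapply(out, `[[`, numeric(1), "crisp")[idx],
    degenerate = vapply(out, `[[`, logical(1), "degenerate")[idx],
    stringsAsFactors = FALSE
  )
}

#' Bin scores by the output term ranges
#'
#' Assigns each score to the Low/Medium/High bin given by the literal term
#' ranges of the output variable (boundary values go to the higher bin).
#'
#' @param x numeric scores.
#' @param breaks interior bin boundaries (default `c(22, 33)`, the
#'   equal-thirds anxiety partition).
#' @param labels bin labels.
#' @return A factor of bin labels.
#' @export
bin_scores <- function(x, breaks = c(22, 33),
                       labels = c("Low", "Medium", "High")) {
  cut(x, breaks = c(-Inf, breaks, Inf), labels = labels, right = FALSE)
}

#' Agreement between fuzzy and observed anxiety
#'
#' Bins both series by the output term ranges, then reports the percent of
#' records landing in the same bin, the 3x3 confusion counts, and the
#' Spearman correlation between the two series. Degenerate fuzzy outputs
#' (no rule fired) are excluded from the confusion counts and reported
#' separately.
#'
#' @param fis fuzzy crisp scores — a numeric vector or the data frame from
#'   [fis_scores()].
#' @param observed observed anxiety scores, same length.
#' @param output_var the output [linguistic_variable()] (used for bin
#'   boundaries); default the literal equal-thirds anxiety partition.
#' @return A list of class `concordance_report`: `spearman_R`, `p_value`,
#'   `percent_agreement`, `confusion` (3x3 table, fuzzy in rows),
#'   `n`, `n_degenerate`, `degenerate_binning` (TRUE when all observed
#'   scores fall in one bin).
#' @export
agreement <- function(fis, observed,
                      output_var = default_anxiety_config()$output) {
  degenerate <- NULL
  if (is.data.frame(fis)) {
    degenerate <- fis$degenerate
    fis <- fis$crisp
  }
  if (length(fis) != length(observed)) {
    stop("fuzzy and observed score vectors must have equal length")
  }
  if (length(fis) < 10) stop("agreement needs at least 10 records")
  if (is.null(degenerate)) degenerate <- rep(FALSE, length(fis))
  keep <- !degenerate & !is.na(fis) & !is.na(observed)

  # interior boundaries from the term ranges (apexes of the middle term's
  # neighbours coincide with the literal range boundaries)
  feet <- vapply(output_var$terms, function(mf) mf$a1, numeric(1))
  breaks <- sort(unique(feet))[-1]
  bf <- bin_scores(fis[keep], breaks = breaks)
  bo <- bin_scores(observed[keep], breaks = breaks)
  confusion <- table(fuzzy = bf, observed = bo)
  pct <- 100 * sum(diag(confusion)) / sum(confusion)
  sp <- spearman_cor(fis[keep], observed[keep],
                     labels = c("fuzzy", "observed"))
  structure(list(
    spearman_R = sp$R, p_value = sp$p_value,
    percent_agreement = pct, confusion = confusion,
    n = length(fis), n_degenerate = sum(degenerate, na.rm = TRUE),
    degenerate_binning = length(unique(bo)) == 1
  ), class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf(
    "Concordance: Spearman R = %.3f, 3-bin agreement = %.1f%% (n = %d",
    x$spearman_R, x$percent_agreement, x$n))
  if (x$n_degenerate > 0) cat(",", x$n_degenerate, "degenerate")
  cat(")\n")
  print(x$confusion)
  if (x$degenerate_binning) {
    cat("note: all observed scores fall in a single bin\n")
  }
  invisible(x)
}
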