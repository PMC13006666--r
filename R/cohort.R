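cohort_score_cols <- function() {
  c("PSS_pre", "AMS_pre", "AAS_pre", "PSS_post", "AMS_post", "AAS_post")
}

cohort_cols <- function() {
  c("student_id", "study_level", "college", cohort_score_cols())
}

study_levels <- function() c("Beginner", "Intermediate", "Seniors")

#' Coerce a data frame to a cohort
#'
#' A cohort is a plain data frame with one row per student and columns
#' `student_id`, `study_level`, `college`, and pre/post total scores
#' `PSS_pre, AMS_pre, AAS_pre, PSS_post, AMS_post, AAS_post`.
#'
#' @param df a data frame with the cohort columns.
#' @return The data frame, column-checked.
#' @export
as_cohort <- function(df) {
  missing <- setdiff(cohort_cols(), names(df))
  if (length(missing)) {
    stop("cohort is missing column(s): ", paste(missing, collapse = ", "))
  }
  df[, cohort_cols(), drop = FALSE]
}

#' Validate a cohort against the instruments
#'
#' Report-only check: flags every score outside its scale bounds, unknown
#' study-level labels, and missing values in required columns. A clean
#' cohort yields a zero-row report.
#'
#' @param cohort a cohort data frame (see [as_cohort()]).
#' @return A data frame with columns `student_id`, `field`, `value`,
#'   `problem`; attribute `empty_cohort` is `TRUE` when the cohort has no
#'   rows (also raised as a warning).
#' @export
validate_cohort <- function(cohort) {
  cohort <- as_cohort(cohort)
  report <- data.frame(student_id = character(), field = character(),
                       value = character(), problem = character(),
                       stringsAsFactors = FALSE)
  add <- function(id, field, value, problem) {
    rbind(report, data.frame(student_id = as.character(id), field = field,
                             value = as.character(value), problem = problem,
                             stringsAsFactors = FALSE))
  }
  if (nrow(cohort) == 0) {
    warning("empty cohort")
    attr(report, "empty_cohort") <- TRUE
    return(report)
  }
  scales <- builtin_scale()
  for (col in cohort_score_cols()) {
    sc <- scales[[sub("_(pre|post)$", "", col)]]
    v <- cohort[[col]]
    for (i in which(is.na(v))) {
      report <- add(cohort$student_id[i], col, NA, "missing score")
    }
    for (i in which(!is.na(v) & v < sc$score_min)) {
      report <- add(cohort$student_id[i], col, v[i],
                    paste0(sc$name, " below ", sc$score_min))
    }
    for (i in which(!is.na(v) & v > sc$score_max)) {
      report <- add(cohort$student_id[i], col, v[i],
                    paste0(sc$name, " above ", sc$score_max))
    }
  }
  bad_lvl <- which(!cohort$study_level %in% study_levels())
  for (i in bad_lvl) {
    report <- add(cohort$student_id[i], "study_level",
                  cohort$study_level[i], "unknown study level")
  }
  attr(report, "empty_cohort") <- FALSE
  report
}

#' Read / write a cohort CSV
#'
#' One fixed dialect: UTF-8, comma-separated, header required, `NA` for
#' missing, header `student_id,study_level,college,PSS_pre,AMS_pre,AAS_pre,
#' PSS_post,AMS_post,AAS_post`. Scores are parsed as numbers; validation is
#' a separate, explicit step ([validate_cohort()]).
#'
#' @param cohort a cohort data frame.
#' @param path file path.
#' @return `read_cohort_csv` returns the cohort data frame;
#'   `write_cohort_csv` returns `path` invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  cohort <- as_cohort(cohort)
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8", na = "NA")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8", na.strings = "NA")
  as_cohort(df)
}
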