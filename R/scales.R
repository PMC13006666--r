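#' Psychometric scale definition
#'
#' A scale is a fixed number of Likert items sharing one response range;
#' the total score is the sum of (possibly reverse-coded) item responses,
#' so the score bounds are `n_items * item_min` and `n_items * item_max`.
#'
#' @param name scale identifier, e.g. `"PSS"`.
#' @param n_items number of items.
#' @param item_min,item_max integer per-item response bounds.
#' @param reverse_items integer indices of reverse-scored items (may be
#'   empty). A reversed response `r` is recoded as `item_min + item_max - r`.
#' @return An object of class `scale_definition` with fields `score_min`,
#'   `score_max` derived from the item bounds.
#' @export
scale_definition <- function(name, n_items, item_min, item_max,
                             reverse_items = integer()) {
  stopifnot(is.character(name), n_items >= 1, item_min < item_max)
  reverse_items <- as.integer(reverse_items)
  if (length(reverse_items) &&
      (any(reverse_items < 1) || any(reverse_items > n_items))) {
    stop("reverse_items indices must lie in 1..n_items")
  }
  structure(list(name = name, n_items = as.integer(n_items),
                 item_min = as.integer(item_min),
                 item_max = as.integer(item_max),
                 score_min = as.integer(n_items * item_min),
                 score_max = as.integer(n_items * item_max),
                 reverse_items = reverse_items),
            class = "scale_definition")
}

#' Built-in instruments
#'
#' The three instruments of the pre/post exam-anxiety design:
#' \describe{
#'   \item{PSS}{Perceived Stress Scale, 10 items scored 0-4, total 0-40.
#'     The standard short form reverse-scores items 4, 5, 7 and 8; the set
#'     is configurable via [scale_definition()] since all downstream stages
#'     operate on total scores.}
#'   \item{AMS}{Revised Achievement Motives Scale, 10 items scored 1-5,
#'     total 10-50.}
#'   \item{AAS}{Academic Anxiety Scale, 11 four-point Likert items scored
#'     1-4, total 11-44.}
#' }
#'
#' @param name one of `"PSS"`, `"AMS"`, `"AAS"`.
#' @return A [scale_definition()] (or a named list of all three if `name`
#'   is missing).
#' @export
builtin_scale <- function(name) {
  scales <- list(
    PSS = scale_definition("PSS", 10, 0, 4, reverse_items = c(4, 5, 7, 8)),
    AMS = scale_definition("AMS", 10, 1, 5),
    AAS = scale_definition("AAS", 11, 1, 4)
  )
  if (missing(name)) return(scales)
  if (!name %in% names(scales)) {
    stop("unknown scale '", name, "'; built-ins are PSS, AMS, AAS")
  }
  scales[[name]]
}

#' Item-level response matrix
#'
#' @param scale a [scale_definition()].
#' @param values numeric matrix, students in rows and items in columns;
#'   `NA` marks a missing response.
#' @param student_ids ordered identifiers, one per row.
#' @return An object of class `likert_matrix`.
#' @export
likert_matrix <- function(scale, values, student_ids = NULL) {
  stopifnot(inherits(scale, "scale_definition"))
  values <- as.matrix(values)
  if (ncol(values) != scale$n_items) {
    stop("expected ", scale$n_items, " item columns for scale '",
         scale$name, "', got ", ncol(values))
  }
  if (is.null(student_ids)) student_ids <- seq_len(nrow(values))
  if (length(student_ids) != nrow(values)) {
    stop("student_ids length must equal the number of rows")
  }
  bad <- which(!is.na(values) &
                 (values < scale$item_min | values > scale$item_max),
               arr.ind = TRUE)
  if (nrow(bad)) {
    stop("out-of-range response for student '", student_ids[bad[1, 1]],
         "', item ", bad[1, 2], ": ", values[bad[1, , drop = FALSE]],
         " (allowed ", scale$item_min, "..", scale$item_max, ")")
  }
  structure(list(scale = scale, values = values,
                 student_ids = student_ids),
            class = "likert_matrix")
}

#' Reverse-code listed items
#'
#' Recoding is `item_min + item_max - response` on the scale's
#' `reverse_items`; applying it twice restores the raw responses.
#'
#' @param values item response matrix.
#' @param scale a [scale_definition()].
#' @return The recoded matrix.
#' @export
reverse_code <- function(values, scale) {
  for (j in scale$reverse_items) {
    values[, j] <- scale$item_min + scale$item_max - values[, j]
  }
  values
}

#' Score a scale from item responses
#'
#' Total score per student: the sum of item responses after reverse-coding
#' the scale's listed items. Students with any missing item are excluded
#' (listwise deletion) and reported in the `excluded` attribute.
#'
#' @param items a [likert_matrix()].
#' @return A data frame with columns `student_id` and `score`; attribute
#'   `excluded` holds the ids dropped for missing responses.
#' @export
score_scale <- function(items) {
  stopifnot(inherits(items, "likert_matrix"))
  vals <- reverse_code(items$values, items$scale)
  complete <- stats::complete.cases(vals)
  excluded <- items$student_ids[!complete]
  if (length(excluded)) {
    message(length(excluded), " student(s) excluded from scoring of '",
            items$scale$name, "' for missing items")
  }
  out <- data.frame(
    student_id = items$student_ids[complete],
    score = rowSums(vals[complete, , drop = FALSE]),
    stringsAsFactors = FALSE
  )
  attr(out, "excluded") <- excluded
  out
}

#' Cronbach's alpha
#'
#' Internal consistency `k/(k-1) * (1 - sum(item variances) / variance of
#' the total score)`, with the unbiased (n-1) variance convention. Rows
#' with any missing item are dropped listwise.
#'
#' @param items a [likert_matrix()] or a numeric matrix (students x items).
#' @return Alpha as a single number (always `<= 1`).
#' @export
cronbach_alpha <- function(items) {
  vals <- if (inherits(items, "likert_matrix")) items$values else
    as.matrix(items)
  vals <- vals[stats::complete.cases(vals), , drop = FALSE]
  k <- ncol(vals)
  if (k < 2) stop("Cronbach's alpha needs at least 2 items")
  if (nrow(vals) < 3) stop("Cronbach's alpha needs at least 3 complete rows")
  total_var <- stats::var(rowSums(vals))
  if (total_var <= .Machine$double.eps) {
    stop("total-score variance is zero; alpha is undefined")
  }
  item_var <- sum(apply(vals, 2, stats::var))
  k / (k - 1) * (1 - item_var / total_var)
}
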