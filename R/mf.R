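#' Trapezoidal membership function
#'
#' The package's membership-function primitive is the trapezoid with feet
#' `a1`, `a4` and plateau `[a2, a3]`; a triangle is the special case
#' `a2 == a3`. Membership rises linearly on `[a1, a2]`, is 1 on `[a2, a3]`,
#' and falls linearly on `[a3, a4]`. A degenerate flat edge (`a1 == a2` or
#' `a3 == a4`) has grade 1 at the shared point, so left/right shoulder
#' functions can be expressed directly.
#'
#' @param a1,a2,a3,a4 numeric breakpoints, `a1 <= a2 <= a3 <= a4`.
#' @return An object of class `examfis_mf`.
#' @seealso [trimf()], [membership()]
#' @export
trapmf <- function(a1, a2, a3, a4) {
  pts <- c(a1, a2, a3, a4)
  if (any(!is.finite(pts))) {
    stop("membership function breakpoints must be finite numbers")
  }
  if (is.unsorted(pts)) {
    stop("membership function breakpoints must satisfy a1 <= a2 <= a3 <= a4")
  }
  structure(list(a1 = unname(a1), a2 = unname(a2), a3 = unname(a3),
                 a4 = unname(a4)), class = "examfis_mf")
}

#' Triangular membership function
#'
#' Piecewise-linear membership rising from foot `a1` to apex `a2` and
#' falling to foot `a3`.
#'
#' @param a1,a2,a3 numeric left foot, apex and right foot, `a1 <= a2 <= a3`.
#' @return An object of class `examfis_mf`.
#' @examples
#' mf <- trimf(26, 33, 40)
#' membership(33, mf) # 1 at the apex
#' membership(29, mf) # 3/7 on the rising edge
#' @export
trimf <- function(a1, a2, a3) trapmf(a1, a2, a2, a3)

is_triangular <- function(mf) isTRUE(mf$a2 == mf$a3)

mf_apex <- function(mf) (mf$a2 + mf$a3) / 2

#' Evaluate a membership function
#'
#' @param x numeric vector of crisp values.
#' @param mf an `examfis_mf` from [trimf()] or [trapmf()].
#' @return Membership grades in `[0, 1]`, same length as `x`.
#' @export
membership <- function(x, mf) {
  stopifnot(inherits(mf, "examfis_mf"))
  rise <- if (mf$a2 > mf$a1) (x - mf$a1) / (mf$a2 - mf$a1) else
    as.numeric(x >= mf$a2)
  fall <- if (mf$a4 > mf$a3) (mf$a4 - x) / (mf$a4 - mf$a3) else
    as.numeric(x <= mf$a3)
  g <- pmin(rise, 1, fall)
  g[x < mf$a1 | x > mf$a4] <- 0
  pmax(g, 0)
}

#' Linguistic variable
#'
#' A named variable over a crisp domain, partitioned into ordered
#' Low/Medium/High terms with one membership function each.
#'
#' @param name variable name (e.g. `"PSS"`).
#' @param domain length-2 numeric `c(min, max)`.
#' @param terms named list of `examfis_mf`, ordered by apex.
#' @return An object of class `linguistic_variable`.
#' @export
linguistic_variable <- function(name, domain, terms) {
  stopifnot(is.character(name), length(domain) == 2, domain[1] < domain[2])
  if (is.null(names(terms)) || any(!nzchar(names(terms)))) {
    stop("terms must be a named list of membership functions")
  }
  for (tn in names(terms)) {
    mf <- terms[[tn]]
    if (!inherits(mf, "examfis_mf")) stop("term '", tn, "' is not an examfis_mf")
    if (mf$a1 < domain[1] - 1e-9 || mf$a4 > domain[2] + 1e-9) {
      stop("support of term '", tn, "' of '", name,
           "' lies outside the domain [", domain[1], ", ", domain[2], "]")
    }
  }
  apexes <- vapply(terms, mf_apex, numeric(1))
  if (is.unsorted(apexes)) {
    stop("terms of '", name, "' must be ordered by apex (Low <= Medium <= High)")
  }
  structure(list(name = name, domain = domain, terms = terms),
            class = "linguistic_variable")
}

#' @export
print.linguistic_variable <- function(x, ...) {
  cat("Linguistic variable '", x$name, "' on [",
      x$domain[1], ", ", x$domain[2], "]\n", sep = "")
  for (tn in names(x$terms)) {
    mf <- x$terms[[tn]]
    cat(sprintf("  %-8s (%g, %g, %g, %g)\n", tn, mf$a1, mf$a2, mf$a3, mf$a4))
  }
  invisible(x)
}

#' Build a Low/Medium/High partition from term ranges
#'
#' Two layouts are supported. `"literal"` takes each term range `(lo, hi)`
#' at face value: the triangle `(lo, (lo+hi)/2, hi)`. Adjacent literal
#' triangles meet only at their feet, so membership is 0 at shared range
#' boundaries. `"overlap"` builds a Ruspini partition (grades sum to 1
#' everywhere): apexes sit at the literal midpoints, each triangle's feet at
#' the neighbouring apexes, and the boundary terms become flat shoulders out
#' to the domain edges.
#'
#' @param name variable name.
#' @param domain length-2 numeric domain.
#' @param ranges named list of length-2 term ranges, in Low/Medium/High order.
#' @param style `"literal"` or `"overlap"`.
#' @return A [linguistic_variable()].
#' @export
make_partition <- function(name, domain, ranges,
                           style = c("literal", "overlap")) {
  style <- match.arg(style)
  mids <- unname(vapply(ranges, function(r) mean(r), numeric(1)))
  k <- length(ranges)
  terms <- vector("list", k)
  names(terms) <- names(ranges)
  if (style == "literal") {
    for (i in seq_len(k)) {
      r <- ranges[[i]]
      terms[[i]] <- trimf(r[1], mids[i], r[2])
    }
  } else {
    for (i in seq_len(k)) {
      lo <- if (i == 1) domain[1] else mids[i - 1]
      hi <- if (i == k) domain[2] else mids[i + 1]
      terms[[i]] <- if (i == 1) {
        trapmf(domain[1], domain[1], mids[i], hi)
      } else if (i == k) {
        trapmf(lo, mids[i], domain[2], domain[2])
      } else {
        trimf(lo, mids[i], hi)
      }
    }
  }
  linguistic_variable(name, domain, terms)
}

#' Fuzzify a crisp value
#'
#' Maps a crisp value to membership grades over all terms of a linguistic
#' variable. Values outside the domain are clamped to the nearest edge with
#' a warning: survey totals can only leave the instrument's range through a
#' data error, which [validate_cohort()] reports separately.
#'
#' @param value crisp numeric scalar.
#' @param var a [linguistic_variable()].
#' @return Named numeric vector of grades, one per term.
#' @export
fuzzify <- function(value, var) {
  stopifnot(inherits(var, "linguistic_variable"))
  if (!is.numeric(value) || length(value) != 1 || !is.finite(value)) {
    stop("fuzzify expects a single finite numeric value for '", var$name, "'")
  }
  if (value < var$domain[1] || value > var$domain[2]) {
    warning("value ", value, " outside the domain of '", var$name,
            "'; clamped to [", var$domain[1], ", ", var$domain[2], "]")
    value <- min(max(value, var$domain[1]), var$domain[2])
  }
  vapply(var$terms, function(mf) membership(value, mf), numeric(1))
}
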