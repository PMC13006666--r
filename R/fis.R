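#' Fuzzy If-Then rule
#'
#' @param antecedent named character vector mapping input-variable names to
#'   term labels, e.g. `c(PSS = "High", AMS = "Low")`.
#' @param consequent output term label.
#' @param weight rule weight in `(0, 1]`.
#' @return An object of class `fuzzy_rule`.
#' @export
fuzzy_rule <- function(antecedent, consequent, weight = 1) {
  if (is.null(names(antecedent)) || any(!nzchar(names(antecedent)))) {
    stop("rule antecedent must be a named vector of term labels")
  }
  if (!is.numeric(weight) || length(weight) != 1 ||
      weight <= 0 || weight > 1) {
    stop("rule weight must lie in (0, 1]")
  }
  structure(list(antecedent = as.list(antecedent),
                 consequent = as.character(consequent),
                 weight = weight),
            class = "fuzzy_rule")
}

#' Mamdani fuzzy-system configuration
#'
#' Bundles the input and output linguistic variables, the rule base and the
#' operator choices of a Mamdani-style system: a T-norm for AND across
#' antecedent grades, an implication operator clipping (min) or scaling
#' (product) each consequent, max aggregation across rules, and numeric
#' centroid defuzzification on a regular grid.
#'
#' @param inputs list of [linguistic_variable()] inputs.
#' @param output the output [linguistic_variable()].
#' @param rules list of [fuzzy_rule()].
#' @param and_op `"min"` or `"product"`.
#' @param implication `"min"` or `"product"`.
#' @param aggregation `"max"`.
#' @param defuzzifier `"centroid"`.
#' @param grid_step spacing of the centroid grid over the output domain.
#' @return An object of class `fis_config`.
#' @export
fis_config <- function(inputs, output, rules,
                       and_op = c("min", "product"),
                       implication = c("min", "product"),
                       aggregation = "max",
                       defuzzifier = "centroid",
                       grid_step = 0.01) {
  and_op <- match.arg(and_op)
  implication <- match.arg(implication)
  aggregation <- match.arg(aggregation)
  defuzzifier <- match.arg(defuzzifier)
  stopifnot(is.numeric(grid_step), grid_step > 0)
  if (length(rules) == 0) stop("the rule base is empty")
  stopifnot(inherits(output, "linguistic_variable"))
  in_names <- vapply(inputs, function(v) v$name, character(1))
  for (r in rules) {
    stopifnot(inherits(r, "fuzzy_rule"))
    for (vn in names(r$antecedent)) {
      if (!vn %in% in_names) {
        stop("rule references undeclared input variable '", vn, "'")
      }
      term <- r$antecedent[[vn]]
      if (!term %in% names(inputs[[match(vn, in_names)]]$terms)) {
        stop("rule references unknown term '", term, "' of input '", vn, "'")
      }
    }
    if (!r$consequent %in% names(output$terms)) {
      stop("rule consequent '", r$consequent, "' is not an output term")
    }
  }
  structure(list(inputs = inputs, output = output, rules = rules,
                 and_op = and_op, implication = implication,
                 aggregation = aggregation, defuzzifier = defuzzifier,
                 grid_step = grid_step, schema_version = 1L),
            class = "fis_config")
}

#' @export
print.fis_config <- function(x, ...) {
  cat("Mamdani fuzzy system:",
      paste(vapply(x$inputs, function(v) v$name, character(1)),
            collapse = " + "),
      "->", x$output$name, "\n")
  cat(length(x$rules), "rules; AND =", x$and_op, "; implication =",
      x$implication, "; aggregation =", x$aggregation,
      "; defuzzifier =", x$defuzzifier, "(grid_step", x$grid_step, ")\n")
  invisible(x)
}

and_fun <- function(op) if (op == "min") min else prod

imp_fun <- function(op) if (op == "min") pmin else function(s, m) s * m

#' Run Mamdani inference on one record
#'
#' Fuzzifies each input, fires every rule (AND over antecedent grades times
#' the rule weight), clips or scales the consequent membership functions,
#' aggregates by max, and defuzzifies by the centroid of the aggregated
#' shape on a grid of spacing `grid_step`. If no rule fires (zero aggregated
#' area) the output-domain midpoint is returned with `degenerate = TRUE`.
#'
#' @param record named list or vector supplying a crisp value for every
#'   declared input variable.
#' @param config a [fis_config()].
#' @return An object of class `fuzzy_output`: fields `crisp`, `fired_rules`
#'   (data frame of consequents and firing strengths), `input_memberships`,
#'   `degenerate`.
#' @examples
#' cfg <- default_anxiety_config()
#' infer(list(PSS = 19.5, AMS = 30.5), cfg)$crisp # Medium apex: 27.5
#' @export
infer <- function(record, config) {
  stopifnot(inherits(config, "fis_config"))
  record <- as.list(record)
  in_names <- vapply(config$inputs, function(v) v$name, character(1))
  missing <- setdiff(in_names, names(record))
  if (length(missing)) {
    stop("record is missing input(s): ", paste(missing, collapse = ", "))
  }
  grades <- lapply(config$inputs, function(v) fuzzify(record[[v$name]], v))
  names(grades) <- in_names

  strengths <- rule_strengths(grades, config)
  grid <- output_grid(config)
  mu <- aggregate_rules(strengths, grid$term_grades, config)
  res <- centroid_from_grid(grid$x, mu, config$output$domain)

  fired <- data.frame(
    consequent = vapply(config$rules, function(r) r$consequent, character(1)),
    strength = strengths,
    stringsAsFactors = FALSE
  )
  structure(list(crisp = res$crisp, fired_rules = fired,
                 input_memberships = grades, degenerate = res$degenerate),
            class = "fuzzy_output")
}

#' @export
print.fuzzy_output <- function(x, ...) {
  cat("crisp output:", format(x$crisp), if (x$degenerate)
    "(degenerate: no rule fired; domain midpoint)" else "", "\n")
  act <- x$fired_rules[x$fired_rules$strength > 0, , drop = FALSE]
  if (nrow(act)) {
    cat("fired rules:\n")
    for (i in seq_len(nrow(act))) {
      cat(sprintf("  -> %s at %.4f\n", act$consequent[i], act$strength[i]))
    }
  }
  invisible(x)
}

rule_strengths <- function(grades, config) {
  af <- and_fun(config$and_op)
  vapply(config$rules, function(r) {
    g <- mapply(function(vn, term) grades[[vn]][[term]],
                names(r$antecedent), unlist(r$antecedent))
    af(g) * r$weight
  }, numeric(1))
}

output_grid <- function(config) {
  dom <- config$output$domain
  x <- seq(dom[1], dom[2], by = config$grid_step)
  term_grades <- vapply(config$output$terms, function(mf) membership(x, mf),
                        numeric(length(x)))
  list(x = x, term_grades = term_grades)
}

aggregate_rules <- function(strengths, term_grades, config) {
  impf <- imp_fun(config$implication)
  mu <- numeric(nrow(term_grades))
  cons <- vapply(config$rules, function(r) r$consequent, character(1))
  for (i in seq_along(strengths)) {
    if (strengths[i] <= 0) next
    mu <- pmax(mu, impf(strengths[i], term_grades[, cons[i]]))
  }
  mu
}

centroid_from_grid <- function(x, mu, domain) {
  total <- sum(mu)
  if (total <= .Machine$double.eps * length(mu)) {
    list(crisp = mean(domain), degenerate = TRUE)
  } else {
    list(crisp = sum(x * mu) / total, degenerate = FALSE)
  }
}

# Table-1 input term ranges and the equal-thirds output partition.
anxiety_term_ranges <- function() {
  list(
    PSS = list(Low = c(0, 13), Medium = c(13, 26), High = c(26, 40)),
    AMS = list(Low = c(10, 25), Medium = c(25, 36), High = c(36, 50)),
    AAS = list(Low = c(11, 22), Medium = c(22, 33), High = c(33, 44))
  )
}

#' Default academic-anxiety fuzzy system
#'
#' Two inputs — perceived stress (PSS, 0-40; Low 0-13, Medium 13-26,
#' High 26-40) and achievement motivation (AMS, 10-50; Low 10-25,
#' Medium 25-36, High 36-50) — and one output, academic anxiety (AAS,
#' 11-44, partitioned into equal thirds). Nine rules: anxiety rises with
#' stress, and high motivation amplifies the effect of high stress while
#' raising anxiety slightly under low stress. Operators are the classic
#' Mamdani defaults: min AND, min implication, max aggregation, centroid
#' defuzzification at grid step 0.01.
#'
#' @param partition `"literal"` takes each published term range as a
#'   triangle over that range (adjacent terms then meet at membership 0);
#'   `"overlap"` converts the same ranges into a Ruspini partition whose
#'   grades sum to 1 across the domain. See [make_partition()].
#' @return A [fis_config()].
#' @export
default_anxiety_config <- function(partition = c("literal", "overlap")) {
  partition <- match.arg(partition)
  rng <- anxiety_term_ranges()
  pss <- make_partition("PSS", c(0, 40), rng$PSS, style = partition)
  ams <- make_partition("AMS", c(10, 50), rng$AMS, style = partition)
  aas <- make_partition("AAS", c(11, 44), rng$AAS, style = partition)
  tab <- list(
    c("Low", "Low", "Low"),       c("Low", "Medium", "Low"),
    c("Low", "High", "Medium"),   c("Medium", "Low", "Medium"),
    c("Medium", "Medium", "Medium"), c("Medium", "High", "Medium"),
    c("High", "Low", "Medium"),   c("High", "Medium", "High"),
    c("High", "High", "High")
  )
  rules <- lapply(tab, function(r) {
    fuzzy_rule(c(PSS = r[1], AMS = r[2]), r[3])
  })
  fis_config(inputs = list(pss, ams), output = aas, rules = rules)
}

mf_to_list <- function(mf) list(a1 = mf$a1, a2 = mf$a2, a3 = mf$a3, a4 = mf$a4)

var_to_list <- function(v) {
  list(name = v$name, domain = v$domain,
       terms = lapply(v$terms, mf_to_list))
}

var_from_list <- function(l) {
  terms <- lapply(l$terms, function(m) trapmf(m$a1, m$a2, m$a3, m$a4))
  linguistic_variable(l$name, as.numeric(unlist(l$domain)), terms)
}

fis_to_list <- function(config) {
  list(
    schema_version = config$schema_version,
    inputs = lapply(config$inputs, var_to_list),
    output = var_to_list(config$output),
    rules = lapply(config$rules, function(r) {
      list(`if` = r$antecedent, then = r$consequent, weight = r$weight)
    }),
    operators = list(and_op = config$and_op, implication = config$implication,
                     aggregation = config$aggregation,
                     defuzzifier = config$defuzzifier,
                     grid_step = config$grid_step)
  )
}

fis_from_list <- function(l) {
  rules <- lapply(l$rules, function(r) {
    fuzzy_rule(unlist(r$`if`), r$then,
               weight = if (is.null(r$weight)) 1 else r$weight)
  })
  ops <- l$operators
  fis_config(inputs = lapply(l$inputs, var_from_list),
             output = var_from_list(l$output),
             rules = rules,
             and_op = ops$and_op, implication = ops$implication,
             aggregation = ops$aggregation, defuzzifier = ops$defuzzifier,
             grid_step = ops$grid_step)
}

#' Read / write a fuzzy-system configuration
#'
#' Configurations serialize to JSON or YAML (chosen by file extension) with
#' a `schema_version` field; variables carry their domain and per-term
#' breakpoints, rules serialize as `{"if": {...}, "then": ..., "weight": ...}`.
#'
#' @param config a [fis_config()].
#' @param path file path ending in `.json`, `.yaml` or `.yml`.
#' @return `read_fis` returns a [fis_config()]; `write_fis` returns `path`
#'   invisibly.
#' @export
write_fis <- function(config, path) {
  stopifnot(inherits(config, "fis_config"))
  l <- fis_to_list(config)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(l, path)
  } else {
    jsonlite::write_json(l, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_fis
#' @export
read_fis <- function(path) {
  l <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path)
  }
  fis_from_list(l)
}
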