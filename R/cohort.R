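#' Disorder classes and clinical attribute state sets
#'
#' The cohort model uses one categorical disorder label and seven binary
#' clinical attributes per exam record. Each attribute has an ordered state
#' pair; the first state listed in [exam_attribute_states()] is the "risk"
#' state whose class-conditional frequency the generator is parameterised by
#' (man, age >= 39, overweight, variable sleep, no physical activity, smoker,
#' alcohol user).
#'
#' @return `disorder_classes()`: character vector of the six class labels.
#' @export
disorder_classes <- function() {
  c("none", "musculoskeletal", "ophthalmological", "nervous",
    "cardiovascular", "other")
}

#' @rdname disorder_classes
#' @return `exam_attribute_states()`: named list; for each attribute an
#'   ordered character pair `c(risk_state, other_state)`.
#' @export
exam_attribute_states <- function() {
  list(
    sex      = c("man", "woman"),
    age_ge39 = c("yes", "no"),
    bmi      = c("overweight", "normal"),
    sleep    = c("variable", "good"),
    activity = c("no", "yes"),
    smoker   = c("yes", "no"),
    alcohol  = c("yes", "no")
  )
}

#' Construct a cohort population specification
#'
#' A population specification holds the generative parameters of the synthetic
#' exam-record cohort: a prior over the six disorder classes and, for every
#' (class, attribute) pair, the Bernoulli probability of the attribute's risk
#' state conditional on the class. Attributes are conditionally independent
#' given the disorder class, the maximum-entropy completion of a table of
#' class-conditional marginals.
#'
#' @param class_prior Named numeric vector over [disorder_classes()]; must sum
#'   to 1 (tolerance 1e-9).
#' @param conditionals Numeric matrix of risk-state probabilities with one row
#'   per disorder class and one column per attribute (dimnames required).
#' @param n_records Default cohort size used by [generate_cohort()].
#' @return An object of class `vdt_population_spec`.
#' @seealso [default_population_spec()] for the calibrated study population.
#' @export
population_spec <- function(class_prior, conditionals, n_records = 2453) {
  spec <- structure(
    list(n_records = n_records,
         class_prior = class_prior,
         conditionals = conditionals,
         attribute_states = exam_attribute_states()),
    class = "vdt_population_spec"
  )
  validate_population_spec(spec)
  spec
}

#' Validate a population specification
#'
#' Checks every invariant of the generative model and fails with a message
#' naming the offending field.
#'
#' @param spec A `vdt_population_spec`.
#' @return `spec`, invisibly, if valid.
#' @export
validate_population_spec <- function(spec) {
  if (!inherits(spec, "vdt_population_spec")) {
    abort("`spec` must be a vdt_population_spec object")
  }
  cls <- disorder_classes()
  attrs <- names(exam_attribute_states())
  if (!is.numeric(spec$n_records) || length(spec$n_records) != 1 ||
      spec$n_records < 1 || spec$n_records != round(spec$n_records)) {
    abort("field `n_records`: must be a single positive integer")
  }
  p <- spec$class_prior
  if (!setequal(names(p), cls) || length(p) != length(cls)) {
    abort("field `class_prior`: names must be exactly the six disorder classes")
  }
  if (any(p < 0 | p > 1)) {
    abort("field `class_prior`: probabilities must lie in [0, 1]")
  }
  if (abs(sum(p) - 1) > 1e-9) {
    abort("field `class_prior`: probabilities must sum to 1 (tolerance 1e-9)")
  }
  cm <- spec$conditionals
  if (!is.matrix(cm) || !setequal(rownames(cm), cls) ||
      !setequal(colnames(cm), attrs)) {
    abort(paste("field `conditionals`: must be a class-by-attribute matrix",
                "covering every (class, attribute) pair"))
  }
  if (any(cm < 0 | cm > 1)) {
    abort("field `conditionals`: probabilities must lie in [0, 1]")
  }
  invisible(spec)
}

#' Study-calibrated population specification
#'
#' Returns the generative parameters calibrated to the surveyed VDT-user
#' population: 1942 of 2453 employees with no disorder; within the disordered
#' fraction, class shares of 29.08% musculoskeletal, 14.66% ophthalmological,
#' 10.92% nervous and 9.97% cardiovascular, the remainder pooled as "other";
#' and the published class-conditional risk-state frequencies for the seven
#' clinical attributes. Classes without published conditionals ("other")
#' default to the no-disorder column.
#'
#' @param n_records Default cohort size; defaults to the study's 2453 exams.
#' @return A `vdt_population_spec`.
#' @examples
#' spec <- default_population_spec()
#' spec$conditionals["musculoskeletal", "age_ge39"]  # 0.7181
#' @export
default_population_spec <- function(n_records = 2453) {
  p_none <- 1942 / 2453
  p_dis <- 1 - p_none
  shares <- c(musculoskeletal = 0.2908, ophthalmological = 0.1466,
              nervous = 0.1092, cardiovascular = 0.0997)
  prior <- c(none = p_none, p_dis * shares)
  prior <- c(prior, other = 1 - sum(prior))

  attrs <- names(exam_attribute_states())
  cm <- rbind(
    none             = c(0.6443, 0.5640, 0.4928, 0.1673, 0.3458, 0.1668, 0.6776),
    musculoskeletal  = c(0.6711, 0.7181, 0.5503, 0.2081, 0.6036, 0.1544, 0.6309),
    ophthalmological = c(0.6286, 0.6671, 0.4571, 0.2286, 0.2857, 0.2002, 0.6857),
    nervous          = c(0.5536, 0.6553, 0.5357, 0.3236, 0.4762, 0.2143, 0.6964),
    cardiovascular   = c(0.8140, 0.6786, 0.6279, 0.1628, 0.6341, 0.2326, 0.6981)
  )
  colnames(cm) <- attrs
  cm <- rbind(cm, other = cm["none", ])
  population_spec(class_prior = prior[disorder_classes()],
                  conditionals = cm[disorder_classes(), ],
                  n_records = n_records)
}

#' Generate a synthetic exam-record cohort
#'
#' Samples `n` independent exam records: a disorder class from the spec's
#' class prior, then each clinical attribute from an independent Bernoulli
#' with its class-conditional risk-state probability. The same
#' `(spec, n, seed)` triple reproduces an identical cohort; the caller's RNG
#' state is left untouched.
#'
#' @param spec A `vdt_population_spec`.
#' @param n Number of records; defaults to `spec$n_records`.
#' @param seed Integer seed controlling all sampling.
#' @param couple Optional attribute-attribute coupling injected on top of the
#'   conditional-independence model, as `list(from =, to =, agreement =)`:
#'   after sampling, attribute `to` is overwritten to match the state of
#'   attribute `from` with probability `agreement` (mapped through the two
#'   attributes' ordered state pairs). Used to plant a known dependency when
#'   exercising structure learning; `NULL` (default) keeps the naive model.
#' @return A tibble with one row per record and columns
#'   `sex, age_ge39, bmi, sleep, activity, smoker, alcohol, disorder`.
#' @examples
#' cohort <- generate_cohort(default_population_spec(), n = 500, seed = 1)
#' dplyr::count(cohort, disorder)
#' @export
generate_cohort <- function(spec, n = spec$n_records, seed = 1, couple = NULL) {
  validate_population_spec(spec)
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    abort("`n` must be a single integer >= 1")
  }
  n <- as.integer(n)
  states <- spec$attribute_states
  cls <- disorder_classes()
  withr::with_seed(as.integer(seed), {
    disorder <- sample(cls, n, replace = TRUE, prob = spec$class_prior[cls])
    cond <- spec$conditionals[disorder, , drop = FALSE]
    cols <- purrr::imap(states, function(pair, attr) {
      unname(ifelse(runif(n) < cond[, attr], pair[[1]], pair[[2]]))
    })
    if (!is.null(couple)) {
      if (!all(c(couple$from, couple$to) %in% names(states))) {
        abort("`couple`: `from` and `to` must name clinical attributes")
      }
      agree <- if (is.null(couple$agreement)) 1 else couple$agreement
      from_risk <- cols[[couple$from]] == states[[couple$from]][[1]]
      to_pair <- states[[couple$to]]
      copied <- ifelse(from_risk, to_pair[[1]], to_pair[[2]])
      keep <- runif(n) < agree
      cols[[couple$to]] <- ifelse(keep, copied, cols[[couple$to]])
    }
    tibble::as_tibble(c(cols, list(disorder = disorder)))
  })
}

#' Tabulate the risk-factor profile of one disorder class
#'
#' Computes, over the records carrying a given disorder label, the empirical
#' proportion of each attribute's risk state — the tabulation that a
#' class-conditional frequency table of clinical variables reports.
#'
#' @param records Cohort tibble as produced by [generate_cohort()].
#' @param class Disorder-class label present in `records`.
#' @return A tibble with columns `attribute`, `risk_state`, `proportion`, `n`
#'   (`n` is the class denominator).
#' @export
tabulate_profile <- function(records, class) {
  check_cohort(records)
  if (!class %in% disorder_classes()) {
    abort(paste0("unknown disorder class '", class, "'"))
  }
  sub <- dplyr::filter(records, .data$disorder == class)
  if (nrow(sub) == 0) {
    abort(paste0("no records of class '", class, "': empty-class profile is undefined"))
  }
  states <- exam_attribute_states()
  purrr::imap(states, function(pair, attr) {
    tibble::tibble(attribute = attr, risk_state = pair[[1]],
                   proportion = mean(sub[[attr]] == pair[[1]]),
                   n = nrow(sub))
  }) %>% bind_rows()
}

# Internal: assert a data frame is a well-formed cohort.
check_cohort <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    abort("`records` must be a non-empty data frame of exam records")
  }
  states <- exam_attribute_states()
  needed <- c(names(states), "disorder")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0) {
    abort(paste0("`records` is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  invisible(records)
}

#' Read or write a population specification as JSON
#'
#' @param spec A `vdt_population_spec`.
#' @param path File path.
#' @return `read_population_spec()` returns a `vdt_population_spec`;
#'   `write_population_spec()` returns `path` invisibly.
#' @export
write_population_spec <- function(spec, path) {
  validate_population_spec(spec)
  x <- list(
    n_records = spec$n_records,
    class_prior = as.list(spec$class_prior),
    conditionals = purrr::map(
      setNames(rownames(spec$conditionals), rownames(spec$conditionals)),
      function(cl) as.list(spec$conditionals[cl, ])
    ),
    attribute_states = spec$attribute_states
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_population_spec
#' @export
read_population_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cm <- do.call(rbind, purrr::map(x$conditionals, unlist))
  cls <- disorder_classes()
  population_spec(class_prior = unlist(x$class_prior)[cls],
                  conditionals = cm[cls, names(exam_attribute_states())],
                  n_records = x$n_records)
}

#' @export
print.vdt_population_spec <- function(x, ...) {
  cat("<vdt_population_spec>\n")
  cat("  default cohort size:", x$n_records, "\n")
  cat("  class prior:\n")
  print(round(x$class_prior, 4))
  cat("  risk-state conditionals (rows = classes):\n")
  print(round(x$conditionals, 4))
  invisible(x)
}
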