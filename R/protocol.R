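#' Canonical diagnostic-test table for VDT health surveillance
#'
#' The ten protocol tests with the specialist who performs each, the time cost
#' (minutes per employee) and the monetary cost (USD per employee, salaries
#' already folded in). `perform_probability` is the probability that the test
#' is actually carried out in the influence diagram's probabilistic test node;
#' it defaults to 1 (deterministic protocol).
#'
#' @return Tibble with columns `test`, `specialist`, `time_cost`,
#'   `money_cost`, `perform_probability`.
#' @export
canonical_tests <- function() {
  tibble::tribble(
    ~test,                               ~specialist, ~time_cost, ~money_cost,
    "employment history",                "doctor",    2.5,        1.0509,
    "personal and family history",       "doctor",    3,          1.2610,
    "guided exploration",                "doctor",    4,          1.6814,
    "electrocardiogram",                 "doctor",    3.5,        1.4712,
    "final report",                      "doctor",    4.5,        1.8916,
    "eye test",                          "nurse",     3,          0.9194,
    "blood count",                       "nurse",     4,          5.2376,
    "anthropometrics and blood pressure","nurse",     3.5,        1.0726,
    "spirometry",                        "nurse",     3,          0.9194,
    "audiometry",                        "nurse",     4,          1.2258
  ) %>% mutate(perform_probability = 1)
}

#' Canonical protocol strategies A-F
#'
#' The six strategies of the protocol decision node: A is the extensive
#' protocol (all ten tests), B-E are flexible protocols that successively drop
#' the blood count, audiometry, spirometry and anthropometrics/blood pressure,
#' and F is the optimized protocol of the five tests directly tied to the
#' occupational risks of VDT work (employment history, personal and family
#' history, guided exploration, final report, eye test).
#'
#' @return Long tibble with columns `strategy` and `test` (one row per
#'   included test).
#' @export
canonical_strategies <- function() {
  all_tests <- canonical_tests()$test
  sets <- list(A = all_tests)
  sets$B <- setdiff(sets$A, "blood count")
  sets$C <- setdiff(sets$B, "audiometry")
  sets$D <- setdiff(sets$C, "spirometry")
  sets$E <- setdiff(sets$D, "anthropometrics and blood pressure")
  sets$F <- c("employment history", "personal and family history",
              "guided exploration", "final report", "eye test")
  purrr::imap(sets, ~ tibble::tibble(strategy = .y, test = .x)) %>% bind_rows()
}

check_strategy_tests <- function(tests, include) {
  unknown <- setdiff(include, tests$test)
  if (length(unknown) > 0) {
    abort(paste0("unknown test name(s): ", paste(unknown, collapse = ", ")))
  }
  invisible(include)
}

#' Evaluate the utility of one protocol strategy
#'
#' Additive linear utilities: the time utility is the sum of the included
#' tests' time costs, the money utility the sum of their monetary costs, and
#' the total utility values each minute at `minute_value` USD:
#' `total = money + minute_value * time`.
#'
#' @param tests Test table (see [canonical_tests()]).
#' @param include Character vector of included test names (may be empty).
#' @param id Strategy label for the report.
#' @param minute_value USD value of one minute of specialist time (default 1,
#'   under which total utility is numerically money + minutes).
#' @return One-row tibble: `strategy`, `n_tests`, `time_utility`,
#'   `money_utility`, `total_utility`.
#' @examples
#' evaluate_strategy(canonical_tests(), canonical_tests()$test, id = "A")
#' @export
evaluate_strategy <- function(tests, include, id = "custom", minute_value = 1) {
  check_strategy_tests(tests, include)
  sub <- dplyr::filter(tests, .data$test %in% include)
  time <- sum(sub$time_cost)
  money <- sum(sub$money_cost)
  tibble::tibble(strategy = id, n_tests = nrow(sub), time_utility = time,
                 money_utility = money,
                 total_utility = money + minute_value * time)
}

#' Evaluate several strategies at once
#'
#' @param tests Test table.
#' @param strategies Long tibble of (`strategy`, `test`) rows, e.g.
#'   [canonical_strategies()].
#' @inheritParams evaluate_strategy
#' @return Tibble with one row per strategy (columns as
#'   [evaluate_strategy()]), in first-appearance order.
#' @export
evaluate_strategies <- function(tests, strategies = canonical_strategies(),
                                minute_value = 1) {
  ids <- unique(strategies$strategy)
  purrr::map(ids, function(id) {
    evaluate_strategy(tests, strategies$test[strategies$strategy == id],
                      id = id, minute_value = minute_value)
  }) %>% bind_rows()
}

#' Expected utility of a strategy with probabilistic test nodes
#'
#' Each included test is a probabilistic node performed with its
#' `perform_probability`; by linearity of expectation it contributes
#' `perform_probability * cost` to each utility axis. With all probabilities
#' 1 this equals [evaluate_strategy()] exactly.
#'
#' @inheritParams evaluate_strategy
#' @return One-row tibble as [evaluate_strategy()].
#' @export
expected_utility <- function(tests, include, id = "custom", minute_value = 1) {
  check_strategy_tests(tests, include)
  pp <- tests$perform_probability %||% rep(1, nrow(tests))
  if (any(pp < 0 | pp > 1)) {
    abort("`perform_probability` must lie in [0, 1]")
  }
  sub <- dplyr::filter(mutate(tests, .pp = pp), .data$test %in% include)
  time <- sum(sub$.pp * sub$time_cost)
  money <- sum(sub$.pp * sub$money_cost)
  tibble::tibble(strategy = id, n_tests = nrow(sub), time_utility = time,
                 money_utility = money,
                 total_utility = money + minute_value * time)
}

#' Cost-reduction report of strategies against a reference
#'
#' Evaluates every strategy and reports, for each, the percent reduction of
#' total utility and of time utility relative to the reference strategy:
#' `100 * (ref - s) / ref`. Raw percentages are kept alongside
#' integer-rounded display columns.
#'
#' @param tests Test table.
#' @param strategies Long (`strategy`, `test`) tibble.
#' @param reference Reference strategy id (default `"A"`, the extensive
#'   protocol).
#' @param minute_value USD per minute.
#' @return Tibble: utilities per strategy plus `reduction_total`,
#'   `reduction_time` (raw percent) and `reduction_total_pct`,
#'   `reduction_time_pct` (rounded to integer percent).
#' @export
reduction_report <- function(tests, strategies = canonical_strategies(),
                             reference = "A", minute_value = 1) {
  if (!reference %in% strategies$strategy) {
    abort(paste0("reference strategy '", reference, "' not among strategies"))
  }
  ev <- evaluate_strategies(tests, strategies, minute_value = minute_value)
  ref <- dplyr::filter(ev, .data$strategy == reference)
  if (ref$total_utility == 0 || ref$time_utility == 0) {
    abort("reference strategy has zero utility; reductions undefined")
  }
  ev %>%
    mutate(
      reduction_total = 100 * (ref$total_utility - .data$total_utility) /
        ref$total_utility,
      reduction_time = 100 * (ref$time_utility - .data$time_utility) /
        ref$time_utility,
      reduction_total_pct = round(.data$reduction_total),
      reduction_time_pct = round(.data$reduction_time)
    )
}

#' Tabular replica of the strategy cost table
#'
#' Builds the full protocol-strategy summary: the test-inclusion checkmark
#' matrix, the time/money/total utility rows and both reduction rows
#' (total-utility and time-utility percent vs the extensive strategy A).
#'
#' @param tests Test table (default [canonical_tests()]).
#' @param strategies Strategy tibble (default [canonical_strategies()]).
#' @param minute_value USD per minute.
#' @return Tibble with a `row` column followed by one column per strategy;
#'   checkmark cells hold `"x"`/`""`, utility cells formatted numbers.
#' @export
strategy_cost_table <- function(tests = canonical_tests(),
                                strategies = canonical_strategies(),
                                minute_value = 1) {
  ids <- unique(strategies$strategy)
  marks <- purrr::map(tests$test, function(tn) {
    vals <- purrr::map_chr(ids, function(id) {
      if (tn %in% strategies$test[strategies$strategy == id]) "x" else ""
    })
    tibble::as_tibble(c(list(row = tn), stats::setNames(as.list(vals), ids)))
  }) %>% bind_rows()
  rep_tbl <- reduction_report(tests, strategies, reference = ids[[1]],
                              minute_value = minute_value)
  num_row <- function(label, values) {
    tibble::as_tibble(c(list(row = label),
                        stats::setNames(as.list(format(values, trim = TRUE)),
                                        ids)))
  }
  bind_rows(
    marks,
    num_row("time utility (min)", rep_tbl$time_utility),
    num_row("money utility (USD)", rep_tbl$money_utility),
    num_row("total utility (USD)", rep_tbl$total_utility),
    num_row("total cost reduction (%)", rep_tbl$reduction_total_pct),
    num_row("time cost reduction (%)", rep_tbl$reduction_time_pct)
  )
}

#' Plot strategy utilities
#'
#' Side-by-side time and money utilities per strategy, the trade-off view of
#' the protocol decision.
#'
#' @param report Output of [reduction_report()] or [evaluate_strategies()].
#' @return A ggplot object.
#' @export
plot_strategy_utilities <- function(report) {
  long <- report %>%
    dplyr::select(dplyr::all_of(c("strategy", "time_utility",
                                  "money_utility"))) %>%
    tidyr::pivot_longer(-"strategy", names_to = "axis", values_to = "utility") %>%
    mutate(axis = dplyr::recode(.data$axis,
                                time_utility = "time (min)",
                                money_utility = "money (USD)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$strategy, y = .data$utility,
                                     fill = .data$axis)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "protocol strategy", y = "utility (cost per employee)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
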