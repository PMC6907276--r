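#' Pooled two-sample proportion z-test
#'
#' Two-sided test of equality of two binomial proportions using the pooled
#' standard error: `z = (p1 - p2) / sqrt(p(1-p)(1/n1 + 1/n2))` with `p` the
#' pooled proportion; no continuity correction. When the pooled proportion is
#' degenerate (0 or 1) the two sample proportions are necessarily equal and
#' the result is `z = 0, p = 1`; a degenerate pooled proportion with unequal
#' sample proportions cannot occur but is reported as an infinite statistic
#' for completeness.
#'
#' @param k1,n1 Successes and trials in group 1.
#' @param k2,n2 Successes and trials in group 2.
#' @return One-row tibble: `estimate1`, `estimate2`, `statistic` (z),
#'   `p_value` (two-sided).
#' @examples
#' two_proportion_test(30, 100, 10, 100)
#' @export
two_proportion_test <- function(k1, n1, k2, n2) {
  if (n1 < 1 || n2 < 1) abort("`n1` and `n2` must be >= 1")
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2) {
    abort("counts must satisfy 0 <= k <= n")
  }
  p1 <- k1 / n1
  p2 <- k2 / n2
  pooled <- (k1 + k2) / (n1 + n2)
  if (pooled <= 0 || pooled >= 1) {
    z <- if (p1 == p2) 0 else sign(p1 - p2) * Inf
  } else {
    z <- (p1 - p2) / sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  }
  tibble::tibble(estimate1 = p1, estimate2 = p2, statistic = z,
                 p_value = if (is.infinite(z)) 0 else 2 * pnorm(-abs(z)))
}

#' Screen clinical variables for association with a disorder class
#'
#' For each clinical attribute, compares the risk-state proportion among
#' records of `class_label` against the reference class with a pooled
#' two-proportion z-test, flagging significance at `alpha`. No multiplicity
#' adjustment is applied by default; `adjust = "bonferroni"` is available.
#'
#' @param records Cohort tibble (see [generate_cohort()]).
#' @param class_label Disorder class under study.
#' @param reference_label Comparison class, default `"none"` (no disorder).
#' @param alpha Significance level (default 0.05).
#' @param adjust `"none"` (default) or `"bonferroni"` across the seven
#'   attributes.
#' @return Tibble with columns `class`, `variable`, `statistic`, `p_value`,
#'   `significant`.
#' @export
screen_risk_factors <- function(records, class_label, reference_label = "none",
                                alpha = 0.05, adjust = c("none", "bonferroni")) {
  check_cohort(records)
  adjust <- match.arg(adjust)
  case <- dplyr::filter(records, .data$disorder == class_label)
  ref <- dplyr::filter(records, .data$disorder == reference_label)
  if (nrow(case) == 0) abort(paste0("no records of class '", class_label, "'"))
  if (nrow(ref) == 0) abort(paste0("no records of class '", reference_label, "'"))
  states <- exam_attribute_states()
  out <- purrr::imap(states, function(pair, attr) {
    res <- two_proportion_test(sum(case[[attr]] == pair[[1]]), nrow(case),
                               sum(ref[[attr]] == pair[[1]]), nrow(ref))
    tibble::tibble(class = class_label, variable = attr,
                   statistic = res$statistic, p_value = res$p_value)
  }) %>% bind_rows()
  out$p_value <- stats::p.adjust(out$p_value, method = adjust)
  out$significant <- out$p_value <= alpha
  out
}

#' Plot a risk-factor screening result
#'
#' Bar chart of |z| per clinical attribute with the significance cut-off shown
#' as a dashed line.
#'
#' @param screening Output of [screen_risk_factors()].
#' @param alpha Significance level used for the reference line.
#' @return A ggplot object.
#' @export
plot_screening <- function(screening, alpha = 0.05) {
  cut <- stats::qnorm(1 - alpha / 2)
  ggplot2::ggplot(screening,
                  ggplot2::aes(x = stats::reorder(.data$variable,
                                                  abs(.data$statistic)),
                               y = abs(.data$statistic),
                               fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = cut, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "|z| statistic",
                  title = paste("Risk-factor screening:",
                                unique(screening$class), "vs reference")) +
    ggplot2::theme_minimal()
}
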