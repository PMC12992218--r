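# ggplot2 views of score tables, response archives and comparisons.

bind_grouped_scores <- function(scores, group) {
  if (!"group" %in% names(scores)) {
    scores <- dplyr::mutate(scores, group = group %||% "cohort")
  }
  scores
}

#' Violin plots of complementarity deviations
#'
#' Distributions of per-participant marginal and joint complementarity
#' deviations, optionally split by cohort via a `group` column in `scores`.
#'
#' @param scores A [score_cohort()] table (or several, row-bound with a
#'   `group` column).
#' @param group Label used when `scores` has no `group` column.
#' @return A ggplot object.
#' @export
plot_complementarity <- function(scores, group = NULL) {
  long <- bind_grouped_scores(as_tibble(scores), group) |>
    tidyr::pivot_longer(c("marginal_comp", "joint_comp"),
                        names_to = "constraint", values_to = "deviation") |>
    dplyr::mutate(constraint = dplyr::recode(.data$constraint,
                                             marginal_comp = "marginal",
                                             joint_comp = "joint"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$deviation,
                                     fill = .data$group)) +
    ggplot2::geom_violin(scale = "width", alpha = 0.7) +
    ggplot2::facet_wrap(~constraint, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "complementarity deviation",
                  title = "Deviations from binary complementarity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Violin plots of fallacy-score distributions
#'
#' Participant-mean single and double conjunction/disjunction fallacy
#' scores, optionally split by cohort.
#'
#' @inheritParams plot_complementarity
#' @return A ggplot object.
#' @export
plot_fallacies <- function(scores, group = NULL) {
  long <- bind_grouped_scores(as_tibble(scores), group) |>
    tidyr::pivot_longer(c("cf_mean", "dcf_mean", "df_mean", "ddf_mean"),
                        names_to = "metric", values_to = "score") |>
    dplyr::mutate(
      family = ifelse(.data$metric %in% c("cf_mean", "dcf_mean"),
                      "conjunction", "disjunction"),
      type = ifelse(.data$metric %in% c("cf_mean", "df_mean"),
                    "single (CF/DF)", "double (DCF/DDF)")
    )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$type, y = .data$score,
                                     fill = .data$group)) +
    ggplot2::geom_violin(scale = "width", alpha = 0.7,
                         position = ggplot2::position_dodge(width = 0.8)) +
    ggplot2::facet_wrap(~family) +
    ggplot2::labs(x = NULL, y = "participant mean fallacy score",
                  title = "Conjunction and disjunction fallacy scores") +
    ggplot2::theme_minimal()
}

#' Violin plots of marginal win-probability judgments by state
#'
#' The political-sensitivity view: the distribution of raw 0-100 marginal
#' judgments for each candidate within each state.
#'
#' @param responses A response archive with marginal items and a `raw`
#'   column.
#' @return A ggplot object.
#' @export
plot_political_sensitivity <- function(responses) {
  m <- dplyr::filter(as_tibble(responses),
                     .data$kind == "marginal", !is.na(.data$raw))
  ggplot2::ggplot(m, ggplot2::aes(x = .data$state1, y = .data$raw,
                                  fill = .data$candidate1)) +
    ggplot2::geom_violin(scale = "width", alpha = 0.7,
                         position = ggplot2::position_dodge(width = 0.8)) +
    ggplot2::labs(x = NULL, y = "judged win probability (0-100)",
                  fill = NULL,
                  title = "Marginal win-probability judgments by state") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.coherence_scores <- function(object, ...) {
  plot_fallacies(object)
}

#' Plot a cohort comparison
#'
#' Group means per metric, side by side for the two cohorts.
#'
#' @param object A [compare_cohorts()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cohort_comparison <- function(object, ...) {
  long <- object$comparison |>
    dplyr::select("metric", "mean_a", "mean_b") |>
    tidyr::pivot_longer(c("mean_a", "mean_b"),
                        names_to = "cohort", values_to = "mean") |>
    dplyr::mutate(cohort = dplyr::recode(.data$cohort,
                                         mean_a = object$names[1],
                                         mean_b = object$names[2]))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$mean,
                                     fill = .data$cohort)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "cohort mean", fill = NULL,
                  title = "Cohort comparison: coherence metrics") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
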