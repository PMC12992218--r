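# Coherence scoring: conjunction/disjunction fallacy scores (single and
# double) and marginal/joint binary-complementarity deviations, computed
# per participant from a response set.
#
# For a conjunction judged p_ab with constituent marginals p_a, p_b:
#   CF  = max(p_ab - p_a, 0) + max(p_ab - p_b, 0)
#   DCF = max(p_ab - max(p_a, p_b), 0)
# For a disjunction judged p_avb:
#   DF  = max(p_a - p_avb, 0) + max(p_b - p_avb, 0)
#   DDF = max(min(p_a, p_b) - p_avb, 0)
# Marginal complementarity deviation: |P(A wins s) + P(B wins s) - 1|,
# averaged over the three states. Joint complementarity deviation: the four
# sign-combination conjunctions of a state pair (per presentation order)
# should sum to 1; the deviation is |sum - 1| averaged over the six
# pair-by-order configurations. Violations are strict: ties score zero.

check_prob <- function(x, unit = 1, what = "probability") {
  if (!is.numeric(x)) abort(paste0("`", what, "` must be numeric."))
  bad <- !is.na(x) & (x < 0 | x > unit)
  if (any(bad)) {
    abort(
      sprintf("%s out of range [0, %s]: %s", what, format(unit),
              paste(format(utils::head(x[bad], 3L)), collapse = ", ")),
      class = "probcoherence_validation_error"
    )
  }
  invisible(x)
}

#' Conjunction fallacy scores for judged triples
#'
#' @param p_a,p_b Judged constituent (marginal) probabilities.
#' @param p_ab Judged conjunction probability.
#' @param unit Scale maximum: 1 for normalized values, 100 for raw slider
#'   values. Scores come back on the same scale.
#' @return A tibble with columns `cf` (single-or-double score, in
#'   `[0, 2 * unit]`) and `dcf` (double score, in `[0, unit]`); `cf >= dcf`
#'   always, and both are 0 when no constituent is strictly exceeded.
#' @export
#' @examples
#' conjunction_scores(0.4, 0.7, 0.8)  # cf = 0.5, dcf = 0.1
conjunction_scores <- function(p_a, p_b, p_ab, unit = 1) {
  check_prob(p_a, unit, "p_a")
  check_prob(p_b, unit, "p_b")
  check_prob(p_ab, unit, "p_ab")
  tibble(
    cf = pmax(p_ab - p_a, 0) + pmax(p_ab - p_b, 0),
    dcf = pmax(p_ab - pmax(p_a, p_b), 0)
  )
}

#' Disjunction fallacy scores for judged triples
#'
#' @inheritParams conjunction_scores
#' @param p_avb Judged disjunction probability.
#' @return A tibble with columns `df` and `ddf` (see
#'   [conjunction_scores()] for the mirror-image conventions).
#' @export
#' @examples
#' disjunction_scores(0.6, 0.4, 0.3)  # df = 0.4, ddf = 0.1
disjunction_scores <- function(p_a, p_b, p_avb, unit = 1) {
  check_prob(p_a, unit, "p_a")
  check_prob(p_b, unit, "p_b")
  check_prob(p_avb, unit, "p_avb")
  tibble(
    df = pmax(p_a - p_avb, 0) + pmax(p_b - p_avb, 0),
    ddf = pmax(pmin(p_a, p_b) - p_avb, 0)
  )
}

marginal_lookup <- function(responses, value_col = "prob") {
  m <- responses[responses$kind == "marginal", ]
  stats::setNames(m[[value_col]], paste0(m$code1, ":", m$state1))
}

#' Marginal binary-complementarity deviation
#'
#' Mean over the battery's three states of
#' `|P(candidate A wins s) + P(candidate B wins s) - unit|`. States with a
#' missing marginal are excluded with a warning; if no state is complete,
#' an error is raised.
#'
#' @param responses A response set (rows with item metadata and a `prob`
#'   column, as produced by the responders or
#'   [responses_from_transcripts()]).
#' @param unit Scale maximum (1 for normalized, 100 for raw values; pass
#'   raw values through a `prob` column to score on that scale).
#' @return A single nonnegative deviation on the `unit` scale.
#' @export
marginal_complementarity <- function(responses, unit = 1) {
  m <- responses[responses$kind == "marginal", ]
  if (nrow(m) == 0L) {
    abort("No marginal responses present.",
          class = "probcoherence_validation_error")
  }
  check_prob(m$prob, unit, "marginal response")
  states <- unique(m$state1)
  dev <- vapply(states, function(s) {
    a <- m$prob[m$code1 == "A" & m$state1 == s]
    b <- m$prob[m$code1 == "B" & m$state1 == s]
    if (length(a) != 1L || length(b) != 1L || is.na(a) || is.na(b)) {
      NA_real_
    } else {
      abs(a + b - unit)
    }
  }, numeric(1))
  if (all(is.na(dev))) {
    abort("No state has both marginals; cannot score complementarity.",
          class = "probcoherence_validation_error")
  }
  if (anyNA(dev)) {
    warn(paste0("State(s) excluded from marginal complementarity: ",
                paste(states[is.na(dev)], collapse = ", ")),
         class = "probcoherence_flagged_items")
  }
  mean(dev, na.rm = TRUE)
}

#' Joint binary-complementarity deviation
#'
#' For each of the 3 state pairs and 2 presentation orders (6
#' configurations), the four sign-combination conjunction responses should
#' sum to `unit`; the deviation is the mean of `|sum - unit|` over the
#' complete configurations. Incomplete configurations are excluded with a
#' warning.
#'
#' @inheritParams marginal_complementarity
#' @return A single nonnegative deviation on the `unit` scale.
#' @export
joint_complementarity <- function(responses, unit = 1) {
  cj <- responses[responses$kind == "conjunction", ]
  if (nrow(cj) == 0L) {
    abort("No conjunction responses present.",
          class = "probcoherence_validation_error")
  }
  check_prob(cj$prob, unit, "conjunction response")
  pair <- ifelse(cj$reversed,
                 paste(cj$state2, cj$state1, sep = "-"),
                 paste(cj$state1, cj$state2, sep = "-"))
  cfg <- paste0(pair, ifelse(cj$reversed, ":r", ":f"))
  sums <- tapply(cj$prob, cfg, function(v) {
    if (length(v) != 4L || anyNA(v)) NA_real_ else abs(sum(v) - unit)
  })
  if (all(is.na(sums))) {
    abort("No complete four-term conjunction configuration present.",
          class = "probcoherence_validation_error")
  }
  if (anyNA(sums)) {
    warn(paste0("Incomplete configuration(s) excluded from joint ",
                "complementarity: ",
                paste(names(sums)[is.na(sums)], collapse = ", ")),
         class = "probcoherence_flagged_items")
  }
  mean(sums, na.rm = TRUE)
}

# Per-item fallacy scores for one participant's composite items.
composite_item_scores <- function(responses, unit = 1) {
  mv <- marginal_lookup(responses)
  comp <- responses[responses$kind %in% c("conjunction", "disjunction"), ]
  p_a <- unname(mv[paste0(comp$code1, ":", comp$state1)])
  p_b <- unname(mv[paste0(comp$code2, ":", comp$state2)])
  is_cj <- comp$kind == "conjunction"
  score <- double_score <- rep(NA_real_, nrow(comp))
  ok <- !is.na(p_a) & !is.na(p_b) & !is.na(comp$prob)
  okc <- ok & is_cj
  okd <- ok & !is_cj
  score[okc] <- pmax(comp$prob[okc] - p_a[okc], 0) +
    pmax(comp$prob[okc] - p_b[okc], 0)
  double_score[okc] <- pmax(comp$prob[okc] - pmax(p_a[okc], p_b[okc]), 0)
  score[okd] <- pmax(p_a[okd] - comp$prob[okd], 0) +
    pmax(p_b[okd] - comp$prob[okd], 0)
  double_score[okd] <- pmax(pmin(p_a[okd], p_b[okd]) - comp$prob[okd], 0)
  tibble(
    persona_id = if ("persona_id" %in% names(comp)) {
      as.character(comp$persona_id)
    } else {
      NA_character_
    },
    item_id = comp$item_id,
    family = comp$kind,
    score = score,
    double_score = double_score
  )
}

#' Per-item fallacy scores across an archive
#'
#' Scores every ordered conjunction and disjunction item of every
#' participant against that participant's own marginals. Used for pooled
#' (item-level) prevalence; participant-level summaries come from
#' [score_participant()].
#'
#' @param archive A response archive covering one or more personas.
#' @param unit Scale maximum of the `prob` column.
#' @return A tibble with `persona_id`, `item_id`, `family`
#'   (conjunction/disjunction), `score` and `double_score`.
#' @export
item_fallacy_scores <- function(archive, unit = 1) {
  check_prob(archive$prob, unit, "response")
  archive |>
    dplyr::group_split(.data$persona_id) |>
    purrr::map(composite_item_scores, unit = unit) |>
    dplyr::bind_rows()
}

#' Score one participant's coherence
#'
#' Assembles the full per-participant summary: marginal and joint
#' complementarity deviations, means of the per-item conjunction and
#' disjunction fallacy scores (single and double) over the 24 ordered
#' conjunction and 24 ordered disjunction items, prevalence (fraction of
#' eligible items with a strictly positive score) and the single/double
#' split among violating items.
#'
#' @param responses One participant's response set.
#' @param battery Optional battery used to check coverage; when supplied,
#'   responses are aligned to its items.
#' @param unit Scale maximum of the values being scored (1 or 100).
#'   Deviations and scores are reported on the same scale, so scoring raw
#'   0-100 values with `unit = 100` and dividing by 100 equals scoring
#'   normalized values.
#' @param min_coverage Minimum fraction of scorable composite items; below
#'   this an error lists the missing items rather than silently imputing.
#' @return A one-row tibble of class `coherence_scores`.
#' @export
score_participant <- function(responses, battery = NULL, unit = 1,
                              min_coverage = 0.9) {
  responses <- as_tibble(responses)
  if (!is.null(battery)) {
    keep <- c("persona_id", "item_id", "prob", "raw")
    responses <- dplyr::left_join(
      as_tibble(battery)[, c("item_id", "kind", "reversed", "code1",
                             "candidate1", "state1", "code2", "candidate2",
                             "state2")],
      responses[, intersect(keep, names(responses))],
      by = "item_id"
    )
  }
  check_prob(responses$prob, unit, "response")
  pid <- if ("persona_id" %in% names(responses)) {
    as.character(responses$persona_id[1])
  } else {
    NA_character_
  }

  items <- composite_item_scores(responses, unit)
  cjs <- items[items$family == "conjunction", ]
  djs <- items[items$family == "disjunction", ]
  n_items <- nrow(cjs) + nrow(djs)
  scorable <- sum(!is.na(items$score))
  if (n_items == 0L || scorable / n_items < min_coverage) {
    missing_ids <- items$item_id[is.na(items$score)]
    abort(
      paste0("Composite coverage below ", format(min_coverage),
             "; unscorable item(s): ",
             paste(utils::head(missing_ids, 12L), collapse = ", ")),
      class = "probcoherence_validation_error"
    )
  }

  split_frac <- function(score, double_score) {
    v <- !is.na(score) & score > 0
    if (!any(v)) {
      c(single = NA_real_, double = NA_real_)
    } else {
      c(single = mean(double_score[v] == 0),
        double = mean(double_score[v] > 0))
    }
  }
  cf_split <- split_frac(cjs$score, cjs$double_score)
  df_split <- split_frac(djs$score, djs$double_score)

  tibble(
    persona_id = pid,
    n_conjunctions_scored = sum(!is.na(cjs$score)),
    n_disjunctions_scored = sum(!is.na(djs$score)),
    marginal_comp = marginal_complementarity(responses, unit),
    joint_comp = joint_complementarity(responses, unit),
    cf_mean = mean(cjs$score, na.rm = TRUE),
    dcf_mean = mean(cjs$double_score, na.rm = TRUE),
    df_mean = mean(djs$score, na.rm = TRUE),
    ddf_mean = mean(djs$double_score, na.rm = TRUE),
    cf_prevalence = mean(cjs$score > 0, na.rm = TRUE),
    df_prevalence = mean(djs$score > 0, na.rm = TRUE),
    cf_single_share = cf_split[["single"]],
    cf_double_share = cf_split[["double"]],
    df_single_share = df_split[["single"]],
    df_double_share = df_split[["double"]]
  )
}

#' Score every participant in an archive
#'
#' @param archive A response archive (stacked response sets with
#'   `persona_id`).
#' @inheritParams score_participant
#' @return A `coherence_scores` tibble, one row per persona.
#' @export
score_cohort <- function(archive, unit = 1, min_coverage = 0.9) {
  out <- archive |>
    dplyr::group_split(.data$persona_id) |>
    purrr::map(score_participant, unit = unit, min_coverage = min_coverage) |>
    dplyr::bind_rows()
  class(out) <- c("coherence_scores", class(out))
  out
}

#' Pooled and participant-averaged fallacy prevalence
#'
#' Prevalence can be computed by pooling items across participants or by
#' averaging participant-level rates; both are reported and labelled, along
#' with the single/double split among pooled violating items.
#'
#' @inheritParams item_fallacy_scores
#' @return A tibble with one row per fallacy family.
#' @export
prevalence_summary <- function(archive, unit = 1) {
  items <- item_fallacy_scores(archive, unit)
  items |>
    dplyr::filter(!is.na(.data$score)) |>
    dplyr::group_by(family = .data$family) |>
    dplyr::summarise(
      n_items = dplyr::n(),
      pooled_prevalence = mean(.data$score > 0),
      single_share = {
        v <- .data$score > 0
        if (any(v)) mean(.data$double_score[v] == 0) else NA_real_
      },
      double_share = {
        v <- .data$score > 0
        if (any(v)) mean(.data$double_score[v] > 0) else NA_real_
      },
      .groups = "drop"
    ) |>
    dplyr::left_join(
      items |>
        dplyr::filter(!is.na(.data$score)) |>
        dplyr::group_by(.data$persona_id, family = .data$family) |>
        dplyr::summarise(rate = mean(.data$score > 0), .groups = "drop") |>
        dplyr::group_by(.data$family) |>
        dplyr::summarise(participant_mean_prevalence = mean(.data$rate),
                         .groups = "drop"),
      by = "family"
    )
}

#' Per-state political sensitivity of marginal judgments
#'
#' Within each state, compares every persona's raw 0-100 judgment for
#' candidate A against candidate B with a paired t-test. Positive mean
#' differences favour candidate A (Trump under the default labels).
#'
#' @param responses A response archive containing marginal items with a
#'   `raw` column on the 0-100 scale.
#' @return A tibble with one row per state: `n`, `mean_diff` (A - B),
#'   `sd_diff`, `t`, `df`, `p_value` and a `note` flagging degenerate
#'   (zero-variance) states, where `t` is undefined.
#' @export
political_sensitivity <- function(responses) {
  m <- responses[responses$kind == "marginal" & !is.na(responses$raw), ]
  if (nrow(m) == 0L) {
    abort("No marginal responses present.",
          class = "probcoherence_validation_error")
  }
  wide <- m |>
    dplyr::select("persona_id", "state1", "code1", "raw") |>
    tidyr::pivot_wider(names_from = "code1", values_from = "raw") |>
    dplyr::filter(!is.na(.data$A) & !is.na(.data$B))
  if (min(table(wide$state1)) < 2L) {
    abort("Need at least 2 personas per state for a paired comparison.",
          class = "probcoherence_validation_error")
  }
  wide |>
    dplyr::group_split(.data$state1) |>
    purrr::map(function(g) {
      d <- g$A - g$B
      degenerate <- sd(d) == 0
      tt <- if (!degenerate) t.test(g$A, g$B, paired = TRUE)
      tibble(
        state = g$state1[1],
        n = nrow(g),
        mean_diff = mean(d),
        sd_diff = sd(d),
        t = if (degenerate) NA_real_ else unname(tt$statistic),
        df = nrow(g) - 1L,
        p_value = if (degenerate) NA_real_ else tt$p.value,
        note = if (degenerate) "zero variance: t undefined" else ""
      )
    }) |>
    dplyr::bind_rows()
}
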