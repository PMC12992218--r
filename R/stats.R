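# Group-comparison layer: paired and Welch t contrasts on participant
# score tables, plus the CF-DF coupling correlation.

#' Paired-samples t-test
#'
#' Classical paired t on matched vectors: t = mean(d) / (sd(d) / sqrt(n))
#' with d = x - y and df = n - 1, two-sided p. Zero difference variance is
#' a degenerate comparison and raises an explicit error.
#'
#' @param x,y Equal-length, persona-matched numeric vectors. If `y` is
#'   omitted, `x` is taken to be the vector of differences.
#' @return A one-row tibble: `estimate` (mean difference), `t`, `df`,
#'   `p_value`, `n`.
#' @export
#' @examples
#' paired_t(c(1, 2, 3), c(0, 0, 0))  # t = 3.464, df = 2
paired_t <- function(x, y = NULL) {
  d <- if (is.null(y)) x else {
    if (length(x) != length(y)) {
      abort("`x` and `y` must have equal length (matched pairs).",
            class = "probcoherence_validation_error")
    }
    x - y
  }
  d <- as.numeric(d)
  if (anyNA(d)) abort("Missing values in paired differences.",
                      class = "probcoherence_validation_error")
  n <- length(d)
  if (n < 2L) abort("Need at least 2 pairs.",
                    class = "probcoherence_validation_error")
  if (sd(d) == 0) {
    abort("Degenerate comparison: paired differences have zero variance.",
          class = "probcoherence_degenerate_variance")
  }
  tt <- tryCatch(
    t.test(d),
    error = function(e) {
      abort("Degenerate comparison: paired differences are essentially constant.",
            class = "probcoherence_degenerate_variance", parent = e)
    }
  )
  tibble(
    estimate = mean(d),
    t = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    n = n
  )
}

#' Welch two-sample t-test
#'
#' Unequal-variance t with Welch-Satterthwaite (possibly fractional)
#' degrees of freedom, two-sided. One constant group is allowed (the other
#' group's variance carries the test); both constant is degenerate.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return A one-row tibble: `estimate` (mean(x) - mean(y)), `t`, `df`,
#'   `p_value`, `n_x`, `n_y`.
#' @export
welch_t <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (anyNA(x) || anyNA(y)) abort("Missing values in inputs.",
                                  class = "probcoherence_validation_error")
  if (length(x) < 2L || length(y) < 2L) {
    abort("Need at least 2 observations per group.",
          class = "probcoherence_validation_error")
  }
  if (sd(x) == 0 && sd(y) == 0) {
    abort("Degenerate comparison: both groups have zero variance.",
          class = "probcoherence_degenerate_variance")
  }
  tt <- tryCatch(
    t.test(x, y, var.equal = FALSE),
    error = function(e) {
      abort("Degenerate comparison: data are essentially constant.",
            class = "probcoherence_degenerate_variance", parent = e)
    }
  )
  tibble(
    estimate = mean(x) - mean(y),
    t = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    n_x = length(x),
    n_y = length(y)
  )
}

#' Coupling between conjunction and disjunction fallacy rates
#'
#' Pearson correlation between participants' mean conjunction-fallacy and
#' mean disjunction-fallacy scores. A strong positive coupling is the
#' signature of a single sequential mechanism driving both fallacy types;
#' independent mechanisms predict a near-zero correlation.
#'
#' @param scores A [score_cohort()] table with `cf_mean` and `df_mean`.
#' @return A one-row tibble: `r`, `p_value`, `n`, `note` (flags undefined
#'   correlations when either rate has zero variance).
#' @export
fallacy_coupling <- function(scores) {
  if (!all(c("cf_mean", "df_mean") %in% names(scores))) {
    abort("`scores` must contain cf_mean and df_mean columns.")
  }
  ok <- !is.na(scores$cf_mean) & !is.na(scores$df_mean)
  x <- scores$cf_mean[ok]
  y <- scores$df_mean[ok]
  if (length(x) < 3L) {
    abort("Need at least 3 participants with both means defined.",
          class = "probcoherence_validation_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    warn("Zero variance in a fallacy rate; correlation undefined.",
         class = "probcoherence_degenerate_variance")
    return(tibble(r = NA_real_, p_value = NA_real_, n = length(x),
                  note = "zero variance: r undefined"))
  }
  ct <- cor.test(x, y)
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(x),
         note = "")
}

comparison_metrics <- c("marginal_comp", "joint_comp", "cf_mean", "dcf_mean",
                        "df_mean", "ddf_mean")

#' Compare two scored cohorts
#'
#' Runs the six core contrasts (marginal and joint complementarity, mean
#' CF, DCF, DF, DDF) between two participant score tables, paired on
#' `persona_id` or unpaired via Welch's t, and attaches each cohort's
#' prevalence and CF-DF coupling summaries. Metrics whose contrast is
#' degenerate (e.g. a cohort compared with itself) are reported with `NA`
#' statistics and an explanatory note rather than dropped.
#'
#' @param a,b [score_cohort()] tables.
#' @param paired If `TRUE` (default) rows are matched on `persona_id`; a
#'   mismatch between the two tables is an error listing the offending ids.
#' @param names Length-2 labels for the two cohorts.
#' @return A `cohort_comparison` object with `tidy()`, `glance()`,
#'   `autoplot()` and `print()` methods.
#' @export
compare_cohorts <- function(a, b, paired = TRUE, names = c("a", "b")) {
  a <- as_tibble(a); b <- as_tibble(b)
  missing_cols <- setdiff(comparison_metrics, intersect(names(a), names(b)))
  if (length(missing_cols) > 0L) {
    abort(paste0("Score tables missing metric column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (paired) {
    mismatch <- c(setdiff(a$persona_id, b$persona_id),
                  setdiff(b$persona_id, a$persona_id))
    if (length(mismatch) > 0L) {
      abort(paste0("Paired comparison requires matched personas; ",
                   "unmatched id(s): ",
                   paste(utils::head(unique(mismatch), 10L), collapse = ", ")),
            class = "probcoherence_validation_error")
    }
    b <- b[match(a$persona_id, b$persona_id), ]
  }

  rows <- purrr::map(comparison_metrics, function(m) {
    x <- a[[m]]; y <- b[[m]]
    base <- tibble(
      metric = m,
      mean_a = mean(x, na.rm = TRUE), sd_a = sd(x),
      mean_b = mean(y, na.rm = TRUE), sd_b = sd(y)
    )
    res <- tryCatch(
      if (paired) paired_t(x, y) else welch_t(x, y),
      probcoherence_degenerate_variance = function(e) NULL,
      probcoherence_validation_error = function(e) NULL
    )
    if (is.null(res)) {
      dplyr::mutate(base,
                    estimate = if (paired) mean(x - y) else
                      mean(x, na.rm = TRUE) - mean(y, na.rm = TRUE),
                    t = NA_real_,
                    df = NA_real_, p_value = NA_real_,
                    note = "degenerate variance: t undefined")
    } else {
      dplyr::mutate(base, estimate = res$estimate, t = res$t, df = res$df,
                    p_value = res$p_value, note = "")
    }
  }) |>
    dplyr::bind_rows()

  coupling <- dplyr::bind_rows(
    dplyr::mutate(suppressWarnings(fallacy_coupling(a)), cohort = names[1],
                  .before = 1),
    dplyr::mutate(suppressWarnings(fallacy_coupling(b)), cohort = names[2],
                  .before = 1)
  )
  prevalence <- dplyr::bind_rows(
    dplyr::mutate(prevalence_from_scores(a), cohort = names[1], .before = 1),
    dplyr::mutate(prevalence_from_scores(b), cohort = names[2], .before = 1)
  )

  structure(
    list(comparison = rows, coupling = coupling, prevalence = prevalence,
         paired = paired, names = names,
         n = c(nrow(a), nrow(b))),
    class = "cohort_comparison"
  )
}

# Participant-mean prevalence and single/double splits from a score table.
prevalence_from_scores <- function(scores) {
  tibble(
    family = c("conjunction", "disjunction"),
    prevalence = c(mean(scores$cf_prevalence, na.rm = TRUE),
                   mean(scores$df_prevalence, na.rm = TRUE)),
    single_share = c(mean(scores$cf_single_share, na.rm = TRUE),
                     mean(scores$df_single_share, na.rm = TRUE)),
    double_share = c(mean(scores$cf_double_share, na.rm = TRUE),
                     mean(scores$df_double_share, na.rm = TRUE))
  )
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat("<cohort_comparison> ", x$names[1], " (n = ", x$n[1], ") vs ",
      x$names[2], " (n = ", x$n[2], "), ",
      if (x$paired) "paired" else "Welch", "\n\n", sep = "")
  print(as.data.frame(x$comparison), digits = 4)
  cat("\nCF-DF coupling:\n")
  print(as.data.frame(x$coupling), digits = 4)
  cat("\nPrevalence (participant means):\n")
  print(as.data.frame(x$prevalence), digits = 4)
  invisible(x)
}

#' Tidy a cohort comparison
#'
#' @param x A [compare_cohorts()] result.
#' @param ... Unused.
#' @return The per-metric contrast tibble.
#' @export
tidy.cohort_comparison <- function(x, ...) {
  x$comparison
}

#' One-row summary of a cohort comparison
#'
#' @param x A [compare_cohorts()] result.
#' @param ... Unused.
#' @return A one-row tibble with cohort sizes, pairing and the number of
#'   metrics showing a significant contrast at 0.05.
#' @export
glance.cohort_comparison <- function(x, ...) {
  tibble(
    n_a = x$n[1], n_b = x$n[2], paired = x$paired,
    n_metrics = nrow(x$comparison),
    n_significant = sum(x$comparison$p_value < 0.05, na.rm = TRUE)
  )
}
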