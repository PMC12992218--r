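# Archive formats: transcripts as JSONL (one record per item, preceded by a
# session-metadata header line), scores as CSV, cohort summaries as JSON.

#' Write and read transcript archives as JSONL
#'
#' One JSON record per transcript row; the first line is a header object
#' with session-level metadata (persona count, item count, window
#' convention is recorded per row in `context_size_at_query`).
#'
#' @param transcripts A [run_session()] or [run_cohort()] result.
#' @param path Output `.jsonl` path.
#' @return `write_transcripts()` returns `path` invisibly;
#'   `read_transcripts()` returns the archive tibble.
#' @export
write_transcripts <- function(transcripts, path) {
  header <- list(
    type = "probcoherence_transcripts",
    n_personas = dplyr::n_distinct(transcripts$persona_id),
    n_records = nrow(transcripts)
  )
  lines <- c(
    jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA),
    vapply(seq_len(nrow(transcripts)), function(i) {
      jsonlite::toJSON(as.list(transcripts[i, ]), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_transcripts
#' @export
read_transcripts <- function(path) {
  lines <- readLines(path)
  records <- lapply(lines[-1L], jsonlite::fromJSON)
  out <- dplyr::bind_rows(lapply(records, function(r) {
    as_tibble(lapply(r, function(v) if (is.null(v)) NA else v))
  }))
  out$parsed_value <- suppressWarnings(as.integer(out$parsed_value))
  out
}

#' Write a participant score table to CSV
#'
#' @param scores A [score_cohort()] table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  readr::write_csv(as_tibble(scores), path)
  invisible(path)
}

#' Cohort summary as JSON
#'
#' Writes the cohort-level aggregates of a score table (means of the six
#' core metrics, participant-mean prevalence and splits, CF-DF coupling)
#' to a JSON file.
#'
#' @param scores A [score_cohort()] table.
#' @param path Output JSON path.
#' @return The summary list, invisibly.
#' @export
write_cohort_summary <- function(scores, path) {
  coupling <- suppressWarnings(fallacy_coupling(scores))
  summary <- list(
    n_participants = nrow(scores),
    metric_means = as.list(colMeans(
      as_tibble(scores)[, comparison_metrics], na.rm = TRUE
    )),
    prevalence = prevalence_from_scores(scores),
    cf_df_coupling = coupling
  )
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(summary)
}
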