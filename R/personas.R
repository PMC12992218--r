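# Persona tables: the demographic records that initialise each session.

education_levels <- c(
  "high school or less", "some college",
  "bachelor's degree", "postgraduate education"
)

#' Simulate a demographic persona table
#'
#' Generates synthetic persona records carrying the four demographic fields
#' used to initialise sessions (age, gender, education on the four-level
#' scale, U.S. state of residence) plus a triplet assignment. The defaults
#' mirror the composition of the study cohort the battery was designed for:
#' 553 personas, 284 assigned to triplet T1 and 269 to T2.
#'
#' @param n Number of personas.
#' @param seed Integer seed.
#' @param t1_share Fraction assigned to triplet `"T1"` (the rest get
#'   `"T2"`); the default reproduces the 284/269 split at `n = 553`.
#' @return A tibble with columns `persona_id`, `age`, `gender`, `education`,
#'   `state`, `triplet`.
#' @export
#' @examples
#' simulate_personas(4, seed = 2)
simulate_personas <- function(n = 553L, seed = 1L, t1_share = 284 / 553) {
  n <- as.integer(n)
  if (is.na(n) || n < 0L) abort("`n` must be a nonnegative integer.")
  if (n == 0L) {
    return(tibble(
      persona_id = character(), age = integer(), gender = character(),
      education = character(), state = character(), triplet = character()
    ))
  }
  n1 <- min(n, round(n * t1_share))
  withr::with_seed(as.integer(seed), {
    triplet <- sample(c(rep("T1", n1), rep("T2", n - n1)))
    tibble(
      persona_id = sprintf("P%04d", seq_len(n)),
      age = sample(18:89, n, replace = TRUE),
      gender = sample(c("female", "male"), n, replace = TRUE),
      education = sample(education_levels, n, replace = TRUE,
                         prob = c(0.28, 0.30, 0.27, 0.15)),
      state = sample(datasets::state.name, n, replace = TRUE),
      triplet = triplet
    )
  })
}

#' Read or write a persona CSV
#'
#' Persona files are plain CSV with columns `persona_id`, `age`, `gender`,
#' `education`, `state` and (optionally) `triplet`.
#'
#' @param path File path.
#' @param personas Persona tibble to write.
#' @return `read_personas()` returns a tibble; `write_personas()` returns
#'   `path` invisibly.
#' @export
read_personas <- function(path) {
  p <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_personas(p, require_triplet = FALSE)
  p
}

#' @rdname read_personas
#' @export
write_personas <- function(personas, path) {
  readr::write_csv(as_tibble(personas), path)
  invisible(path)
}

validate_personas <- function(personas, require_triplet = TRUE) {
  needed <- c("persona_id", "age", "gender", "education", "state")
  if (require_triplet) needed <- c(needed, "triplet")
  missing <- setdiff(needed, names(personas))
  if (length(missing) > 0L) {
    abort(paste0("Persona table missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  ids <- personas$persona_id
  if (anyNA(ids) || any(!nzchar(as.character(ids)))) {
    abort("Persona ids must be non-missing and non-empty.")
  }
  if (anyDuplicated(ids)) {
    abort(paste0("Duplicate persona_id(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (require_triplet && !all(personas$triplet %in% names(.triplets))) {
    abort("Persona `triplet` must be one of T1, T2.",
          class = "probcoherence_config_error")
  }
  invisible(personas)
}
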