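# Battery construction: the 78-item probability-judgment protocol.
#
# Each participant judges, for one triplet of U.S. states, every marginal
# event ("candidate c wins state s") plus every conjunction, disjunction and
# conditional over pairs of different states, with each composite also
# presented in reversed order. Marginals always come first; composites are
# grouped into thematic blocks by state pair and composite kind.

.triplets <- list(
  T1 = c("Ohio", "Missouri", "Michigan"),
  T2 = c("Georgia", "Montana", "Nevada")
)

#' States of a battery triplet
#'
#' The battery is defined over one of two fixed triplets of U.S. states:
#' `"T1"` (Ohio, Missouri, Michigan) or `"T2"` (Georgia, Montana, Nevada).
#'
#' @param triplet Triplet id, `"T1"` or `"T2"`.
#' @return Character vector of three state names.
#' @export
#' @examples
#' triplet_states("T1")
triplet_states <- function(triplet) {
  if (!(is.character(triplet) && length(triplet) == 1L &&
        !is.na(triplet) && triplet %in% names(.triplets))) {
    abort(
      paste0("Unknown triplet id: ", paste(format(triplet), collapse = ", "),
             ". Available triplets: ", paste(names(.triplets), collapse = ", ")),
      class = "probcoherence_config_error"
    )
  }
  .triplets[[triplet]]
}

item_ids <- function(kind, code1, state1, code2, state2, reversed) {
  tag <- c(marginal = "M", conjunction = "CJ",
           disjunction = "DJ", conditional = "CD")[kind]
  ifelse(
    kind == "marginal",
    paste0(tag, ":", code1, ".", state1),
    paste0(tag, ":", code1, ".", state1, "+", code2, ".", state2,
           ifelse(reversed, ":r", ":f"))
  )
}

#' Build the 78-item probability-judgment battery
#'
#' Enumerates all events of the low-complexity protocol for one state
#' triplet: 6 marginals (2 candidates x 3 states), and for each of the 3
#' unordered state pairs all 4 candidate sign combinations of conjunctions,
#' disjunctions and conditionals (36 composites), each composite duplicated
#' with its two events swapped (`reversed = TRUE`), for 78 items in total.
#' Marginals are always presented first in their own block; composite blocks
#' (one per state pair x kind) and the items within every block are permuted
#' by `seed`, so the item multiset is seed-invariant while the presentation
#' order is not.
#'
#' @param triplet Triplet id, `"T1"` or `"T2"` (see [triplet_states()]).
#' @param candidate_labels Length-2 character vector naming candidate A and
#'   candidate B in prompts. The default is the 2020 framing
#'   `c("Trump", "Biden")`; pass e.g.
#'   `c("Republican candidate", "Democratic candidate")` for a hypothetical
#'   future-election framing.
#' @param seed Integer seed controlling block and within-block order.
#' @return A `battery` tibble with one row per item, ordered by presentation
#'   `position`, and columns `item_id`, `position`, `block_id`, `kind`,
#'   `reversed`, `code1`, `candidate1`, `state1`, `code2`, `candidate2`,
#'   `state2`, `prompt_text`. The triplet, labels and seed are stored as
#'   attributes.
#' @export
#' @examples
#' b <- build_battery("T1", seed = 1)
#' dplyr::count(b, kind, reversed)
build_battery <- function(triplet = "T1",
                          candidate_labels = c("Trump", "Biden"),
                          seed = 1L) {
  states <- triplet_states(triplet)
  if (!(is.character(candidate_labels) && length(candidate_labels) == 2L &&
        all(nzchar(candidate_labels)) && !anyNA(candidate_labels) &&
        candidate_labels[1] != candidate_labels[2])) {
    abort("`candidate_labels` must be two distinct non-empty names.",
          class = "probcoherence_config_error")
  }
  seed <- as.integer(seed)

  marginals <- tidyr::expand_grid(state1 = states, code1 = c("A", "B")) |>
    dplyr::mutate(
      kind = "marginal", code2 = NA_character_, state2 = NA_character_,
      reversed = FALSE, block_id = "marginals"
    )

  pr <- combn(3L, 2L)
  pairs <- tibble(s1 = states[pr[1, ]], s2 = states[pr[2, ]])
  forward <- tidyr::expand_grid(
    pairs,
    kind = c("conjunction", "disjunction", "conditional"),
    code1 = c("A", "B"), code2 = c("A", "B")
  ) |>
    dplyr::transmute(
      .data$kind, .data$code1, state1 = .data$s1,
      .data$code2, state2 = .data$s2,
      reversed = FALSE,
      block_id = paste(.data$s1, .data$s2, .data$kind, sep = "-")
    )
  backward <- forward |>
    dplyr::mutate(
      code1 = forward$code2, state1 = forward$state2,
      code2 = forward$code1, state2 = forward$state1,
      reversed = TRUE
    )

  items <- dplyr::bind_rows(marginals, forward, backward)

  composite_blocks <- unique(items$block_id[items$block_id != "marginals"])
  ord <- withr::with_seed(seed, {
    block_order <- c("marginals", sample(composite_blocks))
    order(match(items$block_id, block_order), runif(nrow(items)))
  })
  items <- items[ord, ]
  block_order <- unique(items$block_id)

  labels <- c(A = candidate_labels[1], B = candidate_labels[2])
  items <- items |>
    dplyr::mutate(
      position = dplyr::row_number(),
      candidate1 = unname(labels[.data$code1]),
      candidate2 = ifelse(is.na(.data$code2), NA_character_,
                          unname(labels[.data$code2])),
      item_id = item_ids(.data$kind, .data$code1, .data$state1,
                         .data$code2, .data$state2, .data$reversed)
    )
  items$prompt_text <- render_prompt(items)
  items <- items |>
    dplyr::select(
      "item_id", "position", "block_id", "kind", "reversed",
      "code1", "candidate1", "state1", "code2", "candidate2", "state2",
      "prompt_text"
    )

  structure(
    items,
    triplet = triplet,
    candidate_labels = candidate_labels,
    seed = seed,
    block_order = block_order,
    class = c("battery", class(items))
  )
}

#' Render the elicitation prompt for battery items
#'
#' Produces the natural-language question shown to a responder: a 0-100
#' likelihood request with conjunctions joined by "and", disjunctions by
#' "or", and conditionals by "given that". Reversed items mention their
#' (swapped) first event first, so the rendered order is always
#' first-then-second.
#'
#' @param items A data frame of battery items (rows of [build_battery()])
#'   with columns `kind`, `candidate1`, `state1`, `candidate2`, `state2`.
#' @return Character vector of prompts, one per row.
#' @export
render_prompt <- function(items) {
  items <- as_tibble(items)
  needed <- c("kind", "candidate1", "state1")
  if (!all(needed %in% names(items))) {
    abort("`items` must contain columns kind, candidate1, state1 (and candidate2, state2 for composites).")
  }
  first <- paste(items$candidate1, "wins", items$state1)
  second <- if ("candidate2" %in% names(items)) {
    paste(items$candidate2, "wins", items$state2)
  } else {
    NA_character_
  }
  event <- dplyr::case_when(
    items$kind == "marginal" ~ first,
    items$kind == "conjunction" ~ paste(first, "and", second),
    items$kind == "disjunction" ~ paste(first, "or", second),
    items$kind == "conditional" ~ paste(first, "given that", second),
    TRUE ~ NA_character_
  )
  if (anyNA(event)) abort("Unknown or incomplete item kind in `items`.")
  paste0(
    "On a scale from 0 to 100, what is the likelihood that ", event,
    "? Respond with a single whole number between 0 and 100."
  )
}

#' Serialize a battery to CSV or JSON
#'
#' @param battery A [build_battery()] result.
#' @param path Output file path.
#' @param format `"csv"` (one row per item) or `"json"`.
#' @return `path`, invisibly.
#' @export
write_battery <- function(battery, path, format = c("csv", "json")) {
  format <- rlang::arg_match(format)
  if (format == "csv") {
    readr::write_csv(as_tibble(battery), path)
  } else {
    jsonlite::write_json(
      list(
        triplet = attr(battery, "triplet"),
        candidate_labels = attr(battery, "candidate_labels"),
        seed = attr(battery, "seed"),
        items = as_tibble(battery)
      ),
      path, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}

#' Read a battery table from CSV
#'
#' Restores the item table written by [write_battery()]. The triplet is
#' inferred from the item states; the original permutation seed is not
#' recoverable from the file.
#'
#' @param path CSV file written by [write_battery()].
#' @return A `battery` tibble.
#' @export
read_battery <- function(path) {
  items <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  states <- unique(items$state1)
  triplet <- names(.triplets)[vapply(.triplets, function(s) all(states %in% s), logical(1))]
  if (length(triplet) != 1L) {
    abort("Could not infer a known state triplet from the battery file.",
          class = "probcoherence_config_error")
  }
  labels <- c(
    unique(items$candidate1[items$code1 == "A"]),
    unique(items$candidate1[items$code1 == "B"])
  )
  structure(
    items,
    triplet = triplet,
    candidate_labels = labels,
    seed = NA_integer_,
    block_order = unique(items$block_id),
    class = c("battery", class(items))
  )
}

battery_triplet <- function(battery) {
  attr(battery, "triplet") %||% {
    states <- unique(battery$state1)
    hit <- names(.triplets)[vapply(.triplets, function(s) all(states %in% s), logical(1))]
    if (length(hit) != 1L) {
      abort("Battery states do not match a known triplet.",
            class = "probcoherence_config_error")
    }
    hit
  }
}
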