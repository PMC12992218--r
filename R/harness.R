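# Elicitation harness: persona-initialised chat sessions with a bounded
# sliding memory window. Every query sees exactly the persona
# initialisation exchange plus the most recent `window_pairs`
# question-answer pairs; everything earlier is dropped before the next
# item is issued.

#' Default task instructions
#'
#' The three directives given to participants: answer with intuitive,
#' first-impression estimates; return a single integer between 0 and 100;
#' respond as if the election outcome were not yet known. The exact
#' original wording is not public, so this template is a reconstruction
#' around those directives.
#'
#' @return A single instruction string.
#' @export
default_instructions <- function() {
  paste(
    "You will be asked a series of questions about the likelihood of",
    "outcomes in the upcoming U.S. presidential election. Give your",
    "intuitive, first-impression estimate for each question. Respond with",
    "a single whole number between 0 and 100, where 0 means impossible and",
    "100 means certain. Answer as if the outcome of the election were not",
    "yet known. Do not explain your answers."
  )
}

session_ack <- function() {
  "Understood. I will answer each question with a single whole number between 0 and 100."
}

#' Build the persona-initialisation prompt
#'
#' One descriptive sentence from a fixed template -- e.g. "You are a
#' 54-year-old female with a bachelor's degree living in Ohio." -- followed
#' by the task instructions verbatim. Personas differ only in the four
#' demographic fields; no psychological descriptors are added.
#'
#' @param persona A one-row data frame or list with fields `age`, `gender`,
#'   `education` (one of the four levels in `education_levels`) and `state`.
#' @param instructions Task instruction text appended after the persona
#'   sentence.
#' @return A single prompt string.
#' @export
#' @examples
#' build_persona_prompt(list(age = 54, gender = "female",
#'                           education = "bachelor's degree", state = "Ohio"))
build_persona_prompt <- function(persona, instructions = default_instructions()) {
  persona <- as.list(persona)
  for (f in c("age", "gender", "education", "state")) {
    v <- persona[[f]]
    if (is.null(v) || length(v) != 1L || is.na(v) || !nzchar(as.character(v))) {
      abort(paste0("Persona field `", f, "` is missing or empty."),
            class = "probcoherence_validation_error")
    }
  }
  if (!is.numeric(persona$age) || persona$age <= 0) {
    abort("Persona `age` must be a positive number.",
          class = "probcoherence_validation_error")
  }
  if (!persona$education %in% education_levels) {
    abort(paste0("Persona `education` must be one of: ",
                 paste(education_levels, collapse = "; ")),
          class = "probcoherence_validation_error")
  }
  edu <- switch(persona$education,
    "high school or less" = "a high school education or less",
    "some college" = "some college education",
    "bachelor's degree" = "a bachelor's degree",
    "postgraduate education" = "postgraduate education"
  )
  paste0(
    "You are a ", persona$age, "-year-old ", persona$gender, " with ", edu,
    " living in ", persona$state, ".\n\n", instructions
  )
}

#' Parse a raw reply into an integer 0-100
#'
#' Accepts a single integer token, optionally surrounded by whitespace and
#' followed by a percent sign. Anything else -- multiple numbers, decimals,
#' out-of-range values, free text -- fails and returns `NA`, signalling a
#' retry to the harness.
#'
#' @param raw Character vector of raw replies.
#' @return Integer vector with `NA` for unparseable replies.
#' @export
#' @examples
#' parse_reply(c("73", " 100 ", "42%", "101", "about 60 or 70"))
parse_reply <- function(raw) {
  s <- trimws(as.character(raw))
  s <- sub("%$", "", s)
  s <- trimws(s)
  ok <- !is.na(s) & grepl("^[0-9]{1,3}$", s)
  out <- rep(NA_integer_, length(raw))
  out[ok] <- as.integer(s[ok])
  out[!is.na(out) & out > 100L] <- NA_integer_
  out
}

#' Responder objects
#'
#' A responder is the pluggable answer-generating side of a session. It has
#' an optional `init(persona, battery, seed)` hook returning session state,
#' and a `reply(state, item, messages)` function returning raw text for the
#' current item given the visible message window. External chat backends
#' implement the same contract (their `reply` would POST `messages` to an
#' API); tests exercise it with scripted mocks.
#'
#' @param reply `function(state, item, messages)` returning a single string.
#' @param init Optional `function(persona, battery, seed)` returning state.
#' @param name Display name.
#' @return A `responder` object.
#' @export
responder <- function(reply, init = NULL, name = "custom") {
  if (!is.function(reply)) abort("`reply` must be a function.")
  structure(list(init = init, reply = reply, name = name),
            class = "responder")
}

#' @export
print.responder <- function(x, ...) {
  cat("<responder>", x$name, "\n")
  invisible(x)
}

#' Scripted mock responder
#'
#' Replies with a fixed string, or with the result of
#' `function(state, item, messages)` if `reply` is a function. Used to test
#' the harness protocol without any model behind it.
#'
#' @param reply A string or a reply function.
#' @return A `responder`.
#' @export
#' @examples
#' responder_mock("42")
responder_mock <- function(reply = "42") {
  f <- if (is.function(reply)) reply else {
    force(reply)
    function(state, item, messages) as.character(reply)
  }
  responder(f, name = "mock")
}

#' Wrap a generative model as a responder
#'
#' `respond_fn(persona, battery, seed)` must return a response-set tibble
#' (the common contract of [coherent_respond()], [bayesian_sampler_respond()]
#' and [quantum_respond()]). The session caches that response set at
#' initialisation and replies to each item with its value rounded to an
#' integer -- rounding therefore happens exactly once, at the harness
#' boundary.
#'
#' @param respond_fn `function(persona, battery, seed)` returning a
#'   response set.
#' @param name Display name.
#' @return A `responder`.
#' @export
responder_model <- function(respond_fn, name = "model") {
  responder(
    init = function(persona, battery, seed) respond_fn(persona, battery, seed),
    reply = function(state, item, messages) {
      v <- state$raw[match(item$item_id, state$item_id)]
      if (length(v) != 1L || is.na(v)) "no answer" else
        sprintf("%d", as.integer(round(v)))
    },
    name = name
  )
}

resolve_world <- function(world, persona, seed) {
  if (is.function(world)) world(persona, seed) else world
}

#' Built-in model responders
#'
#' Convenience wrappers binding the three generative models into the
#' session contract. `world` may be a single [latent_world()] shared by the
#' whole cohort, or a `function(persona, seed)` returning one per persona
#' (e.g. a lookup into [make_persona_worlds()]). For the sampler, the
#' session seed drives the binomial draws so each persona's run is an
#' independent replicate. For the quantum model, `config` may likewise be a
#' `quantum_config` or a `function(persona, seed)`.
#'
#' @param world A `latent_world` or `function(persona, seed)`.
#' @param n_marginal,n_compound,beta Sampler parameters, see
#'   [sampler_config()].
#' @param config A [quantum_config()] or `function(persona, seed)`.
#' @return A `responder`.
#' @name model_responders
NULL

#' @rdname model_responders
#' @export
responder_coherent <- function(world) {
  responder_model(function(persona, battery, seed) {
    coherent_respond(battery, resolve_world(world, persona, seed))
  }, name = "coherent")
}

#' @rdname model_responders
#' @export
responder_sampler <- function(world, n_marginal = 18L, n_compound = 5L,
                              beta = 1) {
  responder_model(function(persona, battery, seed) {
    bayesian_sampler_respond(
      battery, resolve_world(world, persona, seed),
      sampler_config(n_marginal, n_compound, beta, seed = seed)
    )
  }, name = "bayesian_sampler")
}

#' @rdname model_responders
#' @export
responder_quantum <- function(config) {
  responder_model(function(persona, battery, seed) {
    cfg <- if (is.function(config)) config(persona, seed) else config
    quantum_respond(battery, cfg)
  }, name = "quantum")
}

#' Run one persona-matched elicitation session
#'
#' Issues the battery's items in presentation order. Before each query the
#' visible context is exactly the persona-initialisation exchange (persona
#' prompt plus the responder's fixed acknowledgment) and the most recent
#' `min(k, window_pairs)` question-answer pairs, where k is the number of
#' items already asked; earlier interactions are removed. Raw replies are
#' parsed by [parse_reply()]; a failed parse is retried with the same
#' prompt up to `retries` total attempts and then recorded as missing. A
#' session with more than 10% missing items is flagged with a warning.
#'
#' @param persona One persona row (see [build_persona_prompt()]).
#' @param battery A [build_battery()] result.
#' @param responder A [responder()] object.
#' @param window_pairs Sliding-window size in question-answer pairs
#'   (default 7).
#' @param retries Total parse attempts per item (default 3).
#' @param seed Integer seed handed to the responder's `init`.
#' @param instructions Task instructions for the initialisation prompt.
#' @return A transcript tibble with one row per item: persona and item
#'   metadata, `prompt_text`, `raw_reply`, `parsed_value` (integer or `NA`)
#'   and `context_size_at_query`.
#' @export
run_session <- function(persona, battery, responder, window_pairs = 7L,
                        retries = 3L, seed = 1L,
                        instructions = default_instructions()) {
  if (!inherits(responder, "responder")) {
    abort("`responder` must be a responder object.")
  }
  window_pairs <- as.integer(window_pairs)
  if (is.na(window_pairs) || window_pairs < 0L) {
    abort("`window_pairs` must be a nonnegative integer.")
  }
  retries <- max(1L, as.integer(retries))
  persona <- as.list(as_tibble(persona)[1L, ])
  init_prompt <- build_persona_prompt(persona, instructions)
  ack <- session_ack()
  state <- if (is.function(responder$init)) {
    responder$init(persona, battery, seed)
  }

  n <- nrow(battery)
  raw_reply <- character(n)
  parsed <- rep(NA_integer_, n)
  ctx_size <- integer(n)
  qa <- vector("list", n)

  init_msgs <- list(
    list(role = "user", content = init_prompt),
    list(role = "assistant", content = ack)
  )
  for (i in seq_len(n)) {
    k <- min(i - 1L, window_pairs)
    ctx <- if (k > 0L) do.call(c, qa[(i - k):(i - 1L)]) else list()
    item <- battery[i, ]
    messages <- c(init_msgs, ctx,
                  list(list(role = "user", content = item$prompt_text)))
    reply <- NA_character_
    value <- NA_integer_
    for (attempt in seq_len(retries)) {
      reply <- as.character(responder$reply(state, item, messages))[1L]
      value <- parse_reply(reply)
      if (!is.na(value)) break
    }
    raw_reply[i] <- reply
    parsed[i] <- value
    ctx_size[i] <- k
    qa[[i]] <- list(list(role = "user", content = item$prompt_text),
                    list(role = "assistant", content = reply))
  }

  out <- tibble(
    persona_id = as.character(persona$persona_id %||% NA_character_),
    session_seed = as.integer(seed),
    position = battery$position,
    item_id = battery$item_id,
    kind = battery$kind,
    reversed = battery$reversed,
    code1 = battery$code1,
    candidate1 = battery$candidate1,
    state1 = battery$state1,
    code2 = battery$code2,
    candidate2 = battery$candidate2,
    state2 = battery$state2,
    prompt_text = battery$prompt_text,
    raw_reply = raw_reply,
    parsed_value = parsed,
    context_size_at_query = ctx_size
  )
  missing_frac <- mean(is.na(parsed))
  attr(out, "flagged") <- missing_frac > 0.1
  if (missing_frac > 0.1) {
    warn(sprintf("Session %s has %.0f%% missing responses.",
                 out$persona_id[1], 100 * missing_frac),
         class = "probcoherence_flagged_session")
  }
  out
}

#' Run a cohort of independent sessions
#'
#' One session per persona, each with an independently re-randomized item
#' order (a fresh battery seed per persona) and an independent session
#' seed, both derived deterministically from `seed`. The archive stacks all
#' transcripts: `personas x 78` rows.
#'
#' @param personas Persona table with unique `persona_id`s and a `triplet`
#'   column assigning each persona to `"T1"` or `"T2"`.
#' @param responder A [responder()].
#' @param candidate_labels Candidate labels for the batteries.
#' @inheritParams run_session
#' @return A transcript archive tibble.
#' @export
run_cohort <- function(personas, responder,
                       candidate_labels = c("Trump", "Biden"),
                       window_pairs = 7L, retries = 3L, seed = 1L,
                       instructions = default_instructions()) {
  personas <- as_tibble(personas)
  if (nrow(personas) == 0L) {
    return(tibble(
      persona_id = character(), session_seed = integer(),
      position = integer(), item_id = character(), kind = character(),
      reversed = logical(), code1 = character(), candidate1 = character(),
      state1 = character(), code2 = character(), candidate2 = character(),
      state2 = character(), prompt_text = character(),
      raw_reply = character(), parsed_value = integer(),
      context_size_at_query = integer()
    ))
  }
  validate_personas(personas, require_triplet = TRUE)
  n <- nrow(personas)
  seeds <- withr::with_seed(as.integer(seed),
                            matrix(sample.int(.Machine$integer.max, 2L * n),
                                   ncol = 2L))
  purrr::map(seq_len(n), function(i) {
    b <- build_battery(personas$triplet[i], candidate_labels,
                       seed = seeds[i, 1L])
    run_session(personas[i, ], b, responder, window_pairs, retries,
                seed = seeds[i, 2L], instructions = instructions)
  }) |>
    dplyr::bind_rows()
}

#' Convert transcripts to a scorable response archive
#'
#' Normalizes parsed 0-100 replies to `[0, 1]` and keeps the item metadata,
#' so a replayed transcript scores identically to the responder's direct
#' response set.
#'
#' @param transcripts A [run_session()] transcript or [run_cohort()]
#'   archive.
#' @return A response-archive tibble (`prob` in `[0,1]`, `raw` in 0-100).
#' @export
responses_from_transcripts <- function(transcripts) {
  transcripts |>
    dplyr::transmute(
      persona_id = as.character(.data$persona_id),
      .data$item_id, .data$kind, .data$reversed,
      .data$code1, .data$candidate1, .data$state1,
      .data$code2, .data$candidate2, .data$state2,
      prob = .data$parsed_value / 100,
      raw = as.numeric(.data$parsed_value)
    )
}
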