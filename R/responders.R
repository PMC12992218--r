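# Generative responder models. Each takes a battery (the data frame of
# items) and returns a complete response set: one probability per item, on
# [0, 1] in `prob` and on the 0-100 elicitation scale in `raw`. Rounding to
# integers is a harness-boundary concern; by default responders return
# exact values so analytic invariants hold exactly.

response_set <- function(battery, prob, persona_id = NA_character_,
                         round = FALSE) {
  raw <- 100 * prob
  if (round) {
    raw <- round(raw)
    prob <- raw / 100
  }
  out <- tibble(
    persona_id = persona_id,
    item_id = battery$item_id,
    kind = battery$kind,
    reversed = battery$reversed,
    code1 = battery$code1,
    candidate1 = battery$candidate1,
    state1 = battery$state1,
    code2 = battery$code2,
    candidate2 = battery$candidate2,
    state2 = battery$state2,
    prob = prob,
    raw = raw
  )
  attr(out, "triplet") <- battery_triplet(battery)
  out
}

#' Coherent classical responses
#'
#' The normative baseline: every item is answered with the exact classical
#' probability of its event under a latent world (conditionals by Bayes'
#' rule). Every coherence metric of the scoring module is zero on this
#' output.
#'
#' @param battery A [build_battery()] result.
#' @param world A [latent_world()] over the same triplet.
#' @param persona_id Optional id attached to the response rows.
#' @param round If `TRUE`, responses are rounded to integer percentages
#'   (the harness boundary behaviour). Default `FALSE`: exact values.
#' @return A response-set tibble (item metadata plus `prob` and `raw`).
#'   Conditional items whose conditioning event has probability zero are
#'   answered `NA` and flagged with a warning.
#' @export
#' @examples
#' b <- build_battery("T1", seed = 1)
#' rs <- coherent_respond(b, latent_world())  # uniform world: marginals 0.5
coherent_respond <- function(battery, world, persona_id = NA_character_,
                             round = FALSE) {
  prob <- world_item_probs(world, battery)
  if (anyNA(prob)) {
    bad <- battery$item_id[is.na(prob)]
    warn(
      paste0("Conditional item(s) with zero-probability condition skipped: ",
             paste(bad, collapse = ", ")),
      class = "probcoherence_flagged_items"
    )
  }
  response_set(battery, prob, persona_id, round)
}

#' Bayesian sampler configuration
#'
#' Parameters of the finite-sample estimator: an item whose true probability
#' is p is answered with (S + beta) / (N + 2 beta), where S ~ Binomial(N, p)
#' and N is `n_marginal` for marginal items and the (smaller) `n_compound`
#' for composite items. The symmetric beta prior pulls small-sample
#' estimates toward 1/2, which is what generates conjunction and
#' disjunction fallacies.
#'
#' @param n_marginal Samples drawn for marginal items.
#' @param n_compound Samples drawn for composite items; must not exceed
#'   `n_marginal` (the model's biasing assumption).
#' @param beta Symmetric beta prior parameter (> 0).
#' @param seed Integer seed for the binomial draws.
#' @return A `sampler_config` list.
#' @export
sampler_config <- function(n_marginal = 18L, n_compound = 5L, beta = 1,
                           seed = 1L) {
  n_marginal <- as.integer(n_marginal)
  n_compound <- as.integer(n_compound)
  if (is.na(n_marginal) || n_marginal < 1L || is.na(n_compound) ||
      n_compound < 1L) {
    abort("Sample counts must be positive integers.",
          class = "probcoherence_config_error")
  }
  if (n_compound > n_marginal) {
    abort("`n_compound` must not exceed `n_marginal`.",
          class = "probcoherence_config_error")
  }
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) || beta <= 0) {
    abort("`beta` must be a positive number.",
          class = "probcoherence_config_error")
  }
  structure(
    list(n_marginal = n_marginal, n_compound = n_compound,
         beta = as.numeric(beta), seed = as.integer(seed)),
    class = "sampler_config"
  )
}

#' Bayesian sampler responses
#'
#' Finite-memory-sample estimates of each item's true classical probability
#' under a latent world (see [sampler_config()] for the estimator). Each
#' item gets one independent binomial draw; the result is deterministic
#' given the config seed.
#'
#' @inheritParams coherent_respond
#' @param config A [sampler_config()].
#' @return A response-set tibble.
#' @export
bayesian_sampler_respond <- function(battery, world,
                                     config = sampler_config(),
                                     persona_id = NA_character_,
                                     round = FALSE) {
  if (!inherits(config, "sampler_config")) {
    abort("`config` must be a sampler_config().",
          class = "probcoherence_config_error")
  }
  p <- world_item_probs(world, battery)
  n <- ifelse(battery$kind == "marginal", config$n_marginal, config$n_compound)
  est <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  s <- withr::with_seed(config$seed, rbinom(sum(ok), n[ok], p[ok]))
  est[ok] <- (s + config$beta) / (n[ok] + 2 * config$beta)
  response_set(battery, est, persona_id, round)
}

#' Sequential quantum model configuration
#'
#' A two-dimensional real Hilbert-space realization: the cognitive state is
#' a ray at angle `psi` and each atomic event "candidate A wins state s" a
#' ray at angle `theta[s]` (degrees, mod 180). The negated atom (candidate B
#' wins the same state) is the orthogonal ray at `theta[s] + 90`, so binary
#' complementarity holds by construction. Composites are evaluated by
#' sequential projection.
#'
#' `ordering` controls which event of a composite is evaluated first:
#' * `"more_likely_first"` (default): for each state pair the first-evaluated
#'   atom is the one in the state with the more extreme marginal (ties broken
#'   by the candidate-A marginal, then triplet order). A pair-consistent
#'   more-likely-first order: you resolve the state you are more certain
#'   about first. It forbids double fallacies and preserves both marginal and
#'   joint complementarity exactly.
#' * `"more_likely_first_item"`: the literal per-item rule; the atom with the
#'   larger marginal in that item goes first (ties: presented order). Also
#'   forbids double fallacies and preserves marginal complementarity, but
#'   the four sign-combination conjunctions of a pair no longer sum to 1.
#' * `"as_presented"`: presentation order.
#'
#' @param psi Cognitive state angle, degrees.
#' @param theta Named numeric vector of candidate-A ray angles (degrees),
#'   one per state of the triplet.
#' @param ordering Evaluation-order rule (see Details).
#' @param seed Optional integer seed carried along for API symmetry; the
#'   model itself is deterministic.
#' @return A `quantum_config` list.
#' @export
quantum_config <- function(psi, theta,
                           ordering = c("more_likely_first",
                                        "more_likely_first_item",
                                        "as_presented"),
                           seed = NULL) {
  ordering <- rlang::arg_match(ordering)
  if (!is.numeric(psi) || length(psi) != 1L || is.na(psi)) {
    abort("`psi` must be a single angle in degrees.",
          class = "probcoherence_config_error")
  }
  if (!is.numeric(theta) || is.null(names(theta)) || anyNA(theta) ||
      !all(nzchar(names(theta)))) {
    abort("`theta` must be a named numeric vector of ray angles per state.",
          class = "probcoherence_config_error")
  }
  structure(
    list(psi = psi %% 180, theta = theta %% 180, ordering = ordering,
         seed = seed),
    class = "quantum_config"
  )
}

#' Draw a random quantum configuration
#'
#' Uniform `psi` and per-state `theta` angles on `[0, 180)` degrees; used to
#' build populations ("grids") of quantum responders.
#'
#' @param triplet Triplet id naming the states `theta` must cover.
#' @param seed Integer seed.
#' @inheritParams quantum_config
#' @return A `quantum_config`.
#' @export
random_quantum_config <- function(triplet = "T1", seed = 1L,
                                  ordering = "more_likely_first") {
  states <- triplet_states(triplet)
  ang <- withr::with_seed(as.integer(seed), runif(4L, 0, 180))
  quantum_config(psi = ang[1L],
                 theta = stats::setNames(ang[2:4], states),
                 ordering = ordering)
}

#' Sequential quantum responses
#'
#' Marginals are squared projections, P(E) = cos^2(psi - theta(E)).
#' A conjunction is evaluated sequentially, first X then Y:
#' P = cos^2(psi - theta(X)) * cos^2(theta(X) - theta(Y)), with X chosen by
#' the config's ordering rule. A disjunction is evaluated through its
#' complement, P(A or B) = 1 - P(not-A and not-B), with the same ordering
#' rule applied to the complements. A conditional is the pure transition
#' probability P(first | second) = cos^2(theta(second) - theta(first)).
#' Because a sequential product never exceeds its first factor, double
#' conjunction and double disjunction fallacies are impossible under every
#' ordering rule, while single fallacies against the other constituent can
#' and do occur.
#'
#' @inheritParams coherent_respond
#' @param config A [quantum_config()] whose `theta` covers the battery's
#'   triplet states.
#' @return A response-set tibble.
#' @export
#' @examples
#' b <- build_battery("T1", seed = 1)
#' cfg <- quantum_config(psi = 0,
#'                       theta = c(Ohio = 30, Missouri = 60, Michigan = 100))
#' rs <- quantum_respond(b, cfg)
quantum_respond <- function(battery, config, persona_id = NA_character_,
                            round = FALSE) {
  if (!inherits(config, "quantum_config")) {
    abort("`config` must be a quantum_config().",
          class = "probcoherence_config_error")
  }
  states <- triplet_states(battery_triplet(battery))
  if (!all(states %in% names(config$theta))) {
    abort(
      paste0("`theta` missing ray angle for state(s): ",
             paste(setdiff(states, names(config$theta)), collapse = ", ")),
      class = "probcoherence_config_error"
    )
  }
  th <- config$theta[states]
  psi <- config$psi
  m_a <- cospi((psi - th) / 180)^2          # candidate-A marginal per state
  cert <- pmax(m_a, 1 - m_a)                # how decided each state is

  atom_theta <- function(code, state) {
    unname(th[state]) + 90 * (code == "B")
  }
  atom_marg <- function(code, state) {
    ifelse(code == "A", unname(m_a[state]), 1 - unname(m_a[state]))
  }
  # TRUE where the first-presented atom is evaluated first
  first_presented_first <- function(code1, state1, code2, state2) {
    switch(
      config$ordering,
      as_presented = rep(TRUE, length(code1)),
      more_likely_first_item = {
        p1 <- atom_marg(code1, state1)
        p2 <- atom_marg(code2, state2)
        p1 >= p2
      },
      more_likely_first = {
        c1 <- unname(cert[state1]); c2 <- unname(cert[state2])
        a1 <- unname(m_a[state1]);  a2 <- unname(m_a[state2])
        c1 > c2 | (c1 == c2 & (a1 > a2 |
          (a1 == a2 & match(state1, states) < match(state2, states))))
      }
    )
  }
  seq_conjunction <- function(code1, state1, code2, state2) {
    swap <- !first_presented_first(code1, state1, code2, state2)
    cx <- ifelse(swap, code2, code1); sx <- ifelse(swap, state2, state1)
    cy <- ifelse(swap, code1, code2); sy <- ifelse(swap, state1, state2)
    atom_marg(cx, sx) * cospi((atom_theta(cx, sx) - atom_theta(cy, sy)) / 180)^2
  }
  flip <- function(code) ifelse(code == "A", "B", "A")

  prob <- numeric(nrow(battery))
  k <- battery$kind
  i <- k == "marginal"
  prob[i] <- atom_marg(battery$code1[i], battery$state1[i])
  i <- k == "conjunction"
  prob[i] <- seq_conjunction(battery$code1[i], battery$state1[i],
                             battery$code2[i], battery$state2[i])
  i <- k == "disjunction"
  prob[i] <- 1 - seq_conjunction(flip(battery$code1[i]), battery$state1[i],
                                 flip(battery$code2[i]), battery$state2[i])
  i <- k == "conditional"
  prob[i] <- cospi((atom_theta(battery$code2[i], battery$state2[i]) -
                      atom_theta(battery$code1[i], battery$state1[i])) / 180)^2

  response_set(battery, prob, persona_id, round)
}
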