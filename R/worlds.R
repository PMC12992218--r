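# Latent classical worlds: full joint distributions over the 8 possible
# candidate assignments to the three states of a triplet. They ground the
# coherent baseline responder and supply true event probabilities to the
# Bayesian sampler.

#' Construct a latent classical world
#'
#' A latent world is a probability measure over the 8 outcomes of "which
#' candidate wins each of the three states" for one triplet. It is the
#' classical sample space against which coherent responses and sampler
#' estimates are defined.
#'
#' @param probs Numeric vector of 8 nonnegative outcome probabilities
#'   summing to 1 (within 1e-12). Outcomes are ordered with the first
#'   state's winner varying fastest (A before B). Defaults to the uniform
#'   distribution.
#' @param triplet Triplet id, `"T1"` or `"T2"`.
#' @return A `latent_world` object.
#' @export
#' @examples
#' latent_world()                      # uniform over the 8 outcomes
#' latent_world(c(1, rep(0, 7)))       # candidate A sweeps all three states
latent_world <- function(probs = NULL, triplet = "T1") {
  states <- triplet_states(triplet)
  probs <- probs %||% rep(1 / 8, 8L)
  probs <- as.numeric(probs)
  if (length(probs) != 8L || anyNA(probs) || any(probs < 0)) {
    abort("`probs` must be 8 nonnegative outcome probabilities.",
          class = "probcoherence_config_error")
  }
  if (abs(sum(probs) - 1) > 1e-12) {
    abort("`probs` must sum to 1 within 1e-12.",
          class = "probcoherence_config_error")
  }
  winners <- as.matrix(expand.grid(
    rep(list(c("A", "B")), 3L),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  ))
  colnames(winners) <- states
  structure(
    list(triplet = triplet, states = states, probs = probs, winners = winners),
    class = "latent_world"
  )
}

#' @export
print.latent_world <- function(x, ...) {
  cat("<latent_world> triplet", x$triplet, "\n")
  lab <- apply(x$winners, 1L, paste, collapse = "")
  print(stats::setNames(round(x$probs, 4), lab))
  invisible(x)
}

#' Draw a random latent world
#'
#' Samples outcome weights from a symmetric Dirichlet (via gamma draws) and
#' snaps them to a dyadic grid (`resolution` equiprobable atoms), so the
#' stored probabilities are exact binary fractions. Classical event
#' probabilities derived from such a world are then exact in double
#' precision, which keeps the coherent baseline's scores identically zero
#' rather than zero up to rounding.
#'
#' @param triplet Triplet id.
#' @param seed Integer seed.
#' @param resolution Number of atoms on the dyadic grid (a power of two).
#' @param concentration Dirichlet concentration; 1 is uniform on the simplex.
#' @return A `latent_world`.
#' @export
random_world <- function(triplet = "T1", seed = 1L,
                         resolution = 2^20, concentration = 1) {
  counts <- withr::with_seed(as.integer(seed), {
    w <- rgamma(8L, shape = concentration)
    rmultinom(1L, size = resolution, prob = w / sum(w))[, 1L]
  })
  latent_world(counts / resolution, triplet = triplet)
}

#' Per-persona latent worlds
#'
#' Perturbs the log-weights of a base world with independent zero-mean
#' Gaussian noise (one draw per outcome per persona) and renormalizes,
#' yielding one world per persona. `heterogeneity = 0` returns the base
#' world unchanged for every persona.
#'
#' @param personas Persona table with a `persona_id` column.
#' @param base_world A [latent_world()] shared by the cohort.
#' @param heterogeneity Nonnegative standard deviation of the log-weight
#'   noise.
#' @param seed Integer seed.
#' @return Named list of `latent_world` objects, one per persona.
#' @export
make_persona_worlds <- function(personas, base_world, heterogeneity = 0.5,
                                seed = 1L) {
  personas <- as_tibble(personas)
  if (!"persona_id" %in% names(personas)) {
    abort("`personas` must have a persona_id column.")
  }
  if (!is.numeric(heterogeneity) || length(heterogeneity) != 1L ||
      is.na(heterogeneity) || heterogeneity < 0) {
    abort("`heterogeneity` must be a single nonnegative number.",
          class = "probcoherence_config_error")
  }
  n <- nrow(personas)
  ids <- as.character(personas$persona_id)
  if (heterogeneity == 0 || n == 0L) {
    return(stats::setNames(rep(list(base_world), n), ids))
  }
  noise <- withr::with_seed(as.integer(seed),
                            matrix(rnorm(8L * n, sd = heterogeneity), nrow = n))
  worlds <- lapply(seq_len(n), function(i) {
    lw <- log(pmax(base_world$probs, 1e-300)) + noise[i, ]
    w <- exp(lw - max(lw))
    latent_world(w / sum(w), triplet = base_world$triplet)
  })
  stats::setNames(worlds, ids)
}

# True classical probability of every battery item's event under a world.
# Subset sums are taken over a fixed outcome order so that conjunction and
# disjunction sums are never (even in floating point) larger resp. smaller
# than their constituent marginals. Conditionals with a zero-probability
# condition come back NA.
world_item_probs <- function(world, battery) {
  if (!inherits(world, "latent_world")) {
    abort("`world` must be a latent_world.", class = "probcoherence_config_error")
  }
  if (!identical(battery_triplet(battery), world$triplet)) {
    abort("World triplet does not match battery triplet.",
          class = "probcoherence_config_error")
  }
  W <- world$winners
  p <- world$probs
  i1 <- match(battery$state1, world$states)
  i2 <- match(battery$state2, world$states)
  n <- nrow(battery)
  out <- numeric(n)
  for (r in seq_len(n)) {
    in1 <- W[, i1[r]] == battery$code1[r]
    out[r] <- switch(
      battery$kind[r],
      marginal = sum(p[in1]),
      conjunction = sum(p[in1 & (W[, i2[r]] == battery$code2[r])]),
      disjunction = sum(p[in1 | (W[, i2[r]] == battery$code2[r])]),
      conditional = {
        in2 <- W[, i2[r]] == battery$code2[r]
        pc <- sum(p[in2])
        if (pc == 0) NA_real_ else sum(p[in1 & in2]) / pc
      },
      abort(paste0("Unknown item kind: ", battery$kind[r]))
    )
  }
  out
}
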