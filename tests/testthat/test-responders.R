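battery_t1 <- build_battery("T1", seed = 1)

test_that("coherent responder reproduces classical probabilities", {
  uniform <- coherent_respond(battery_t1, latent_world())
  expect_true(all(uniform$prob[uniform$kind == "marginal"] == 0.5))
  expect_true(all(uniform$prob[uniform$kind == "conjunction"] == 0.25))
  expect_true(all(uniform$prob[uniform$kind == "disjunction"] == 0.75))
  expect_true(all(uniform$prob[uniform$kind == "conditional"] == 0.5))

  sweep <- suppressWarnings(
    coherent_respond(battery_t1, latent_world(c(1, rep(0, 7))))
  )
  m <- sweep[sweep$kind == "marginal", ]
  expect_true(all(m$prob[m$code1 == "A"] == 1))
  expect_true(all(m$prob[m$code1 == "B"] == 0))
  # conditionals on the impossible candidate-B events are flagged NA
  expect_warning(
    rs <- coherent_respond(battery_t1, latent_world(c(1, rep(0, 7)))),
    class = "probcoherence_flagged_items"
  )
  expect_true(anyNA(rs$prob[rs$kind == "conditional"]))
})

test_that("coherent output scores zero on every metric across random worlds", {
  for (seed in c(3, 17, 101)) {
    w <- random_world("T1", seed = seed)
    sp <- suppressWarnings(
      score_participant(coherent_respond(battery_t1, w))
    )
    expect_identical(sp$marginal_comp, 0)
    expect_identical(sp$joint_comp, 0)
    expect_identical(sp$cf_mean, 0)
    expect_identical(sp$df_mean, 0)
  }
})

test_that("sampler estimates match the closed-form expectation (N p + beta) / (N + 2 beta)", {
  # single-item Monte Carlo: p = 0.7, N = 10, beta = 1 -> E = 8/12
  p <- 0.7; n <- 10L; beta <- 1
  draws <- withr::with_seed(404, rbinom(10000, n, p))
  oracle_mean <- (n * p + beta) / (n + 2 * beta)
  est <- (draws + beta) / (n + 2 * beta)
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - oracle_mean), 3 * se)

  # through the responder: a marginal with true probability 0.75
  # first state's winner varies fastest: odd outcomes have A winning Ohio
  w <- latent_world(rep(c(0.75 / 4, 0.25 / 4), 4))  # P(A wins Ohio) = .75
  vals <- vapply(1:2000, function(s) {
    rs <- bayesian_sampler_respond(battery_t1, w,
                                   sampler_config(10L, 5L, 1, seed = s))
    rs$prob[rs$item_id == "M:A.Ohio"]
  }, numeric(1))
  expect_lt(abs(mean(vals) - (10 * 0.75 + 1) / 12),
            3 * sd(vals) / sqrt(length(vals)))
})

test_that("sampler concentrates on the truth at large N and is seed-deterministic", {
  w <- random_world("T1", seed = 5)
  truth <- coherent_respond(battery_t1, w)$prob
  big <- bayesian_sampler_respond(battery_t1, w,
                                  sampler_config(10000L, 10000L, 1, seed = 1))
  expect_gte(mean(abs(big$prob - truth) < 0.02, na.rm = TRUE), 0.99)

  a <- bayesian_sampler_respond(battery_t1, w, sampler_config(seed = 9))
  b <- bayesian_sampler_respond(battery_t1, w, sampler_config(seed = 9))
  c <- bayesian_sampler_respond(battery_t1, w, sampler_config(seed = 10))
  expect_identical(a$prob, b$prob)
  expect_false(identical(a$prob, c$prob))
})

test_that("quantum marginals respect orthogonality and the worked example", {
  cfg <- quantum_config(psi = 0, theta = c(Ohio = 45, Missouri = 60,
                                           Michigan = 10))
  rs <- quantum_respond(battery_t1, cfg)
  m <- rs[rs$kind == "marginal", ]
  expect_equal(m$prob[m$code1 == "A" & m$state1 == "Ohio"], 0.5)
  expect_equal(m$prob[m$code1 == "B" & m$state1 == "Ohio"], 0.5)

  # psi = 0, theta(A) = 30, theta(B) = 60: P(A)=0.75, P(B)=0.25,
  # P(A and B) = 0.75 cos^2(30) = 0.5625 -> single CF of 0.3125, no DCF
  cfg2 <- quantum_config(psi = 0, theta = c(Ohio = 30, Missouri = 60,
                                            Michigan = 120))
  rs2 <- quantum_respond(battery_t1, cfg2)
  expect_equal(rs2$prob[rs2$item_id == "M:A.Ohio"], 0.75)
  expect_equal(rs2$prob[rs2$item_id == "M:A.Missouri"], 0.25)
  pab <- rs2$prob[rs2$item_id == "CJ:A.Ohio+A.Missouri:f"]
  expect_equal(pab, 0.5625)
  sc <- conjunction_scores(0.75, 0.25, pab)
  expect_equal(sc$cf, 0.3125)
  expect_equal(sc$dcf, 0)
})

test_that("sequential evaluation forbids double fallacies under every ordering rule", {
  for (ordering in c("more_likely_first", "more_likely_first_item",
                     "as_presented")) {
    for (seed in 1:40) {
      cfg <- random_quantum_config("T1", seed = seed, ordering = ordering)
      sp <- score_participant(quantum_respond(battery_t1, cfg))
      expect_identical(sp$dcf_mean, 0)
      expect_identical(sp$ddf_mean, 0)
      expect_lt(sp$marginal_comp, 1e-12)
    }
  }
})

test_that("pair-consistent ordering keeps joint complementarity; the per-item rule does not", {
  pair_dev <- item_dev <- numeric(30)
  for (seed in 1:30) {
    cfg <- random_quantum_config("T1", seed = seed)
    pair_dev[seed] <- joint_complementarity(quantum_respond(battery_t1, cfg))
    cfg_i <- quantum_config(cfg$psi, cfg$theta,
                            ordering = "more_likely_first_item")
    item_dev[seed] <- joint_complementarity(quantum_respond(battery_t1, cfg_i))
  }
  expect_lt(max(pair_dev), 1e-12)
  expect_gt(max(item_dev), 0.01)
})

test_that("quantum config validation catches missing rays and bad orderings", {
  expect_error(quantum_config(0, c(Ohio = 10), ordering = "nope"))
  cfg <- quantum_config(0, c(Ohio = 10, Missouri = 20))
  expect_error(quantum_respond(battery_t1, cfg),
               class = "probcoherence_config_error")
  expect_error(quantum_respond(battery_t1, list(psi = 0)),
               class = "probcoherence_config_error")
})

test_that("persona worlds perturb the base only when heterogeneity > 0", {
  personas <- simulate_personas(5, seed = 4)
  base <- random_world("T1", seed = 2)
  same <- make_persona_worlds(personas, base, heterogeneity = 0)
  expect_length(same, 5L)
  for (w in same) expect_identical(w$probs, base$probs)

  w1 <- make_persona_worlds(personas, base, heterogeneity = 0.8, seed = 1)
  w2 <- make_persona_worlds(personas, base, heterogeneity = 0.8, seed = 2)
  expect_false(identical(w1[[1]]$probs, w2[[1]]$probs))
  for (w in c(w1, w2)) expect_lt(abs(sum(w$probs) - 1), 1e-12)
  expect_error(make_persona_worlds(personas, base, heterogeneity = -1),
               class = "probcoherence_config_error")
})

test_that("sampler config enforces the compound-sample biasing assumption", {
  expect_error(sampler_config(n_marginal = 5, n_compound = 10),
               class = "probcoherence_config_error")
  expect_error(sampler_config(beta = 0), class = "probcoherence_config_error")
  expect_error(sampler_config(n_marginal = 0),
               class = "probcoherence_config_error")
})
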