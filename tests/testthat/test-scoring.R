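battery_s <- build_battery("T1", seed = 21)

test_that("conjunction and disjunction scores evaluate the fallacy rules", {
  # coherent, violating and tied triples
  expect_equal(conjunction_scores(0.6, 0.4, 0.3), tibble::tibble(cf = 0, dcf = 0))
  expect_equal(conjunction_scores(0.4, 0.7, 0.8), tibble::tibble(cf = 0.5, dcf = 0.1))
  expect_equal(conjunction_scores(0.5, 0.5, 0.5), tibble::tibble(cf = 0, dcf = 0))
  expect_equal(disjunction_scores(0.3, 0.6, 0.7), tibble::tibble(df = 0, ddf = 0))
  expect_equal(disjunction_scores(0.6, 0.4, 0.3), tibble::tibble(df = 0.4, ddf = 0.1))
  expect_equal(disjunction_scores(0.2, 0.9, 0.2), tibble::tibble(df = 0.7, ddf = 0))
  # single <= double bound holds over random triples
  tr <- withr::with_seed(5, matrix(runif(300), ncol = 3))
  cs <- conjunction_scores(tr[, 1], tr[, 2], tr[, 3])
  ds <- disjunction_scores(tr[, 1], tr[, 2], tr[, 3])
  expect_true(all(cs$cf >= cs$dcf))
  expect_true(all(ds$df >= ds$ddf))
  expect_true(all(cs$cf <= 2 & cs$dcf <= 1))
  expect_error(conjunction_scores(1.2, 0.5, 0.5),
               class = "probcoherence_validation_error")
})

make_rs <- function(battery, values) {
  rs <- random_response_set(battery, seed = 1)
  rs$prob <- values
  rs$raw <- 100 * values
  rs
}

test_that("marginal complementarity averages per-state deviations", {
  rs <- random_response_set(battery_s, seed = 2)
  m <- rs$kind == "marginal"
  rs$prob[m] <- 0.5
  expect_equal(marginal_complementarity(rs), 0)

  # (0.6, 0.3), (0.5, 0.5), (0.8, 0.4) across the three states
  states <- triplet_states("T1")
  vals <- list(c(0.6, 0.3), c(0.5, 0.5), c(0.8, 0.4))
  for (i in 1:3) {
    rs$prob[m & rs$code1 == "A" & rs$state1 == states[i]] <- vals[[i]][1]
    rs$prob[m & rs$code1 == "B" & rs$state1 == states[i]] <- vals[[i]][2]
  }
  expect_equal(marginal_complementarity(rs), (0.1 + 0 + 0.2) / 3)

  rs$prob[m] <- 1
  expect_equal(marginal_complementarity(rs), 1)

  rs$prob[m & rs$state1 == states[1]] <- NA
  expect_warning(dev <- marginal_complementarity(rs),
                 class = "probcoherence_flagged_items")
  expect_equal(dev, 1)
  rs$prob[m] <- NA
  expect_error(suppressWarnings(marginal_complementarity(rs)),
               class = "probcoherence_validation_error")
})

test_that("joint complementarity sums the four sign combinations per configuration", {
  rs <- random_response_set(battery_s, seed = 3)
  cj <- rs$kind == "conjunction"
  rs$prob[cj] <- 0.25
  expect_equal(joint_complementarity(rs), 0)
  rs$prob[cj] <- 0.5
  expect_equal(joint_complementarity(rs), 1)
  # dropping one configuration's item flags and excludes it
  drop <- which(cj)[1]
  rs$prob[drop] <- NA
  expect_warning(dev <- joint_complementarity(rs),
                 class = "probcoherence_flagged_items")
  expect_equal(dev, 1)
})

test_that("a single planted conjunction violation yields 1/24 prevalence", {
  rs <- random_response_set(battery_s, seed = 4)
  m <- rs$kind == "marginal"
  rs$prob[m] <- ifelse(rs$code1[m] == "A", 0.4, 0.6)
  rs$prob[rs$kind == "conjunction"] <- 0.1
  rs$prob[rs$kind == "disjunction"] <- 0.9
  target <- which(rs$item_id == "CJ:A.Ohio+A.Missouri:f")
  rs$prob[target] <- 0.8   # inflated above both 0.4 marginals
  sp <- score_participant(rs)
  expect_equal(sp$cf_prevalence, 1 / 24)
  expect_equal(sp$df_prevalence, 0)
  expect_equal(sp$cf_double_share, 1)  # the planted item beats both marginals
})

test_that("scoring raw 0-100 values is the normalized scoring times 100", {
  rs <- random_response_set(battery_s, seed = 6)
  raw_rs <- rs
  raw_rs$prob <- rs$raw
  sp <- score_participant(rs)
  sp_raw <- score_participant(raw_rs, unit = 100)
  for (mcol in c("marginal_comp", "joint_comp", "cf_mean", "dcf_mean",
                 "df_mean", "ddf_mean")) {
    expect_equal(sp_raw[[mcol]] / 100, sp[[mcol]], tolerance = 1e-12)
  }
  for (mcol in c("cf_prevalence", "df_prevalence")) {
    expect_equal(sp_raw[[mcol]], sp[[mcol]])
  }
})

test_that("participant scores match the brute-force oracle on random response sets", {
  for (seed in c(1, 2, 3, 50, 999)) {
    expect_scores_match_oracle(random_response_set(battery_s, seed))
  }
})

test_that("insufficient composite coverage raises a listing error", {
  rs <- random_response_set(battery_s, seed = 7)
  rs$prob[rs$kind %in% c("conjunction", "disjunction")][1:10] <- NA
  expect_error(score_participant(rs), "unscorable",
               class = "probcoherence_validation_error")
  # mild missingness under the threshold just narrows the averages
  rs2 <- random_response_set(battery_s, seed = 8)
  rs2$prob[which(rs2$kind == "conjunction")[1]] <- NA
  sp <- suppressWarnings(score_participant(rs2))
  expect_equal(sp$n_conjunctions_scored, 23L)
})

test_that("cohort scoring stacks one row per persona with pooled prevalence labels", {
  arch <- dplyr::bind_rows(
    random_response_set(battery_s, seed = 11),
    random_response_set(battery_s, seed = 12),
    random_response_set(battery_s, seed = 13)
  )
  scores <- score_cohort(arch)
  expect_s3_class(scores, "coherence_scores")
  expect_equal(nrow(scores), 3L)
  prev <- prevalence_summary(arch)
  expect_setequal(prev$family, c("conjunction", "disjunction"))
  expect_true(all(prev$pooled_prevalence >= 0 & prev$pooled_prevalence <= 1))
  expect_true(all(abs(prev$single_share + prev$double_share - 1) < 1e-12))
})

test_that("political sensitivity recovers a planted state asymmetry", {
  # cohort drawn from a world where candidate A dominates Ohio
  base <- latent_world(rep(c(0.9 / 4, 0.1 / 4), 4))  # P(A wins Ohio) = 0.9
  personas <- simulate_personas(40, seed = 3)
  personas$triplet <- "T1"
  worlds <- make_persona_worlds(personas, base, heterogeneity = 0.4, seed = 5)
  arch <- purrr::map2(
    worlds, personas$persona_id,
    function(w, id) {
      suppressWarnings(coherent_respond(battery_s, w, persona_id = id,
                                        round = TRUE))
    }
  ) |> dplyr::bind_rows()
  tab <- political_sensitivity(arch)
  expect_equal(nrow(tab), 3L)
  expect_gt(tab$mean_diff[tab$state == "Ohio"], 0)
  expect_equal(tab$df, tab$n - 1L)

  # degenerate: every persona answers (60, 40)
  rs <- dplyr::bind_rows(
    random_response_set(battery_s, 1) |> dplyr::mutate(persona_id = "x"),
    random_response_set(battery_s, 2) |> dplyr::mutate(persona_id = "y")
  )
  m <- rs$kind == "marginal"
  rs$raw[m] <- ifelse(rs$code1[m] == "A", 60, 40)
  tab2 <- political_sensitivity(rs)
  expect_true(all(tab2$mean_diff == 20))
  expect_true(all(is.na(tab2$t)))
  expect_match(tab2$note[1], "zero variance")

  # antisymmetric cohort nets to zero
  rs$raw[m & rs$persona_id == "y"] <- ifelse(rs$code1[m & rs$persona_id == "y"] == "A", 40, 60)
  tab3 <- political_sensitivity(rs)
  expect_true(all(tab3$mean_diff == 0))
})
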