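persona_54 <- list(persona_id = "p1", age = 54, gender = "female",
                   education = "bachelor's degree", state = "Ohio")

test_that("persona prompt follows the fixed demographic template", {
  p <- build_persona_prompt(persona_54)
  expect_match(
    p,
    "^You are a 54-year-old female with a bachelor's degree living in Ohio\\."
  )
  # only the demographic tokens may differ between personas
  p2 <- build_persona_prompt(modifyList(persona_54, list(age = 31)))
  expect_identical(gsub("54", "31", p), p2)

  expect_error(build_persona_prompt(modifyList(persona_54, list(state = ""))),
               class = "probcoherence_validation_error")
  expect_error(build_persona_prompt(modifyList(persona_54, list(age = -3))),
               class = "probcoherence_validation_error")
  expect_error(
    build_persona_prompt(modifyList(persona_54, list(education = "PhD"))),
    class = "probcoherence_validation_error"
  )
})

test_that("reply parsing accepts one integer 0-100 and rejects everything else", {
  expect_equal(parse_reply(c("73", " 100 ", "0", "42%")),
               c(73L, 100L, 0L, 42L))
  expect_true(all(is.na(parse_reply(
    c("101", "-5", "about 60 or 70", "sixty", "6.5", "", NA, "60 70")
  ))))
})

test_that("the sliding window never exceeds its limit and grows as answered", {
  b <- build_battery("T1", seed = 2)
  tr <- run_session(persona_54, b, responder_mock("42"), window_pairs = 7)
  expect_equal(nrow(tr), 78L)
  expect_equal(tr$context_size_at_query, pmin(0:77, 7L))
  expect_equal(max(tr$context_size_at_query), 7L)
  expect_true(all(tr$parsed_value == 42L))

  tr0 <- run_session(persona_54, b, responder_mock("9"), window_pairs = 0)
  expect_true(all(tr0$context_size_at_query == 0L))
})

test_that("the responder sees exactly the initialization exchange plus the window", {
  b <- build_battery("T1", seed = 2)
  seen <- integer(0)
  spy <- responder_mock(function(state, item, messages) {
    seen <<- c(seen, length(messages))
    "50"
  })
  run_session(persona_54, b, spy, window_pairs = 3)
  # 2 init messages + 2 per remembered pair + the current question
  expect_equal(seen, 2L + 2L * pmin(0:77, 3L) + 1L)
})

test_that("unparseable replies are retried then recorded missing, with session flagging", {
  b <- build_battery("T1", seed = 2)
  attempts <- 0L
  flaky <- responder_mock(function(state, item, messages) {
    attempts <<- attempts + 1L
    if (attempts %% 3L == 0L) "61" else "no idea"
  })
  tr <- run_session(persona_54, b, flaky, retries = 3)
  expect_true(all(tr$parsed_value == 61L))

  expect_warning(
    bad <- run_session(persona_54, b, responder_mock("unsure"), retries = 2),
    class = "probcoherence_flagged_session"
  )
  expect_true(all(is.na(bad$parsed_value)))
  expect_true(attr(bad, "flagged"))
})

test_that("cohorts run one independent session per persona", {
  personas <- simulate_personas(4, seed = 8)
  arch <- run_cohort(personas, responder_mock("42"), seed = 3)
  expect_equal(nrow(arch), 4L * 78L)
  expect_equal(dplyr::n_distinct(arch$persona_id), 4L)
  # item order re-randomized per persona
  orders <- split(arch$item_id, arch$persona_id)
  expect_false(identical(orders[[1]], orders[[2]]))
  # deterministic given the cohort seed
  arch2 <- run_cohort(personas, responder_mock("42"), seed = 3)
  expect_identical(arch$item_id, arch2$item_id)

  expect_equal(nrow(run_cohort(personas[0, ], responder_mock())), 0L)
  dup <- dplyr::bind_rows(personas[1, ], personas[1, ])
  expect_error(run_cohort(dup, responder_mock()), "Duplicate persona_id")
})

test_that("replayed transcripts score identically to the responder's direct output", {
  personas <- simulate_personas(2, seed = 12)
  b <- build_battery("T1", seed = 31)
  cfg <- quantum_config(psi = 20, theta = c(Ohio = 35, Missouri = 70,
                                            Michigan = 110))
  tr <- run_session(personas[1, ], b, responder_quantum(cfg), seed = 5)
  replayed <- score_participant(responses_from_transcripts(tr))
  direct <- score_participant(
    quantum_respond(b, cfg, persona_id = personas$persona_id[1], round = TRUE)
  )
  expect_equal(as.data.frame(replayed), as.data.frame(direct))
})

test_that("transcripts survive a JSONL round trip", {
  b <- build_battery("T1", seed = 2)
  tr <- run_session(persona_54, b, responder_mock("42"))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_transcripts(tr, path)
  back <- read_transcripts(path)
  expect_equal(nrow(back), 78L)
  expect_equal(back$item_id, tr$item_id)
  expect_equal(back$parsed_value, tr$parsed_value)
})
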