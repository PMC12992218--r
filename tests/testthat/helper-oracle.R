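# Independent brute-force scorer: plain loops over raw item triples,
# deliberately sharing no code with score_participant().

oracle_score <- function(responses, unit = 1) {
  responses <- as.data.frame(responses)
  marg <- function(code, state) {
    v <- responses$prob[responses$kind == "marginal" &
                          responses$code1 == code &
                          responses$state1 == state]
    if (length(v) == 1) v else NA_real_
  }

  states <- unique(responses$state1[responses$kind == "marginal"])
  mdev <- c()
  for (s in states) {
    a <- marg("A", s); b <- marg("B", s)
    if (!is.na(a) && !is.na(b)) mdev <- c(mdev, abs(a + b - unit))
  }

  cj <- responses[responses$kind == "conjunction", ]
  jdev <- c()
  for (pr in unique(paste(pmin(cj$state1, cj$state2),
                          pmax(cj$state1, cj$state2)))) {
    for (rev in c(FALSE, TRUE)) {
      rows <- cj[paste(pmin(cj$state1, cj$state2),
                       pmax(cj$state1, cj$state2)) == pr &
                   cj$reversed == rev, ]
      if (nrow(rows) == 4 && !anyNA(rows$prob)) {
        jdev <- c(jdev, abs(sum(rows$prob) - unit))
      }
    }
  }

  cf <- dcf <- df <- ddf <- cfv <- dfv <- cfd <- dfd <- c()
  for (i in seq_len(nrow(responses))) {
    r <- responses[i, ]
    if (!r$kind %in% c("conjunction", "disjunction")) next
    pa <- marg(r$code1, r$state1); pb <- marg(r$code2, r$state2)
    if (is.na(pa) || is.na(pb) || is.na(r$prob)) next
    if (r$kind == "conjunction") {
      s <- max(r$prob - pa, 0) + max(r$prob - pb, 0)
      d <- max(r$prob - max(pa, pb), 0)
      cf <- c(cf, s); dcf <- c(dcf, d)
      cfv <- c(cfv, s > 0)
      if (s > 0) cfd <- c(cfd, d > 0)
    } else {
      s <- max(pa - r$prob, 0) + max(pb - r$prob, 0)
      d <- max(min(pa, pb) - r$prob, 0)
      df <- c(df, s); ddf <- c(ddf, d)
      dfv <- c(dfv, s > 0)
      if (s > 0) dfd <- c(dfd, d > 0)
    }
  }

  list(
    marginal_comp = mean(mdev),
    joint_comp = mean(jdev),
    cf_mean = mean(cf), dcf_mean = mean(dcf),
    df_mean = mean(df), ddf_mean = mean(ddf),
    cf_prevalence = mean(cfv), df_prevalence = mean(dfv),
    cf_single_share = if (length(cfd)) mean(!cfd) else NA_real_,
    cf_double_share = if (length(cfd)) mean(cfd) else NA_real_,
    df_single_share = if (length(dfd)) mean(!dfd) else NA_real_,
    df_double_share = if (length(dfd)) mean(dfd) else NA_real_
  )
}

# A response set with arbitrary (incoherent) uniform-random judgments.
random_response_set <- function(battery, seed) {
  probs <- withr::with_seed(seed, runif(nrow(battery)))
  tibble::tibble(
    persona_id = paste0("R", seed),
    item_id = battery$item_id, kind = battery$kind,
    reversed = battery$reversed,
    code1 = battery$code1, candidate1 = battery$candidate1,
    state1 = battery$state1,
    code2 = battery$code2, candidate2 = battery$candidate2,
    state2 = battery$state2,
    prob = probs, raw = 100 * probs
  )
}

expect_scores_match_oracle <- function(responses, unit = 1) {
  got <- score_participant(responses, unit = unit)
  want <- oracle_score(responses, unit = unit)
  for (m in names(want)) {
    expect_equal(got[[m]], want[[m]], tolerance = 1e-12, label = m)
  }
}
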