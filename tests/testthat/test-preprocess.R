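test_that("token normalization lower-cases, strips accents and trims", {
  expect_equal(normalize_token("Bűntudat "), "buntudat")
  expect_equal(normalize_token("guilt"), "guilt")
  expect_equal(normalize_token("  Szégyen  érzet "), "szegyen erzet")
  expect_error(normalize_token("   "), class = "coop_validation_error")
})

test_that("merge maps collapse synonyms and never increase the lexicon", {
  corpus <- make_corpus(list(
    c("wasting time", "a", "b", "c", "d"),
    c("time wasting", "a", "b", "c", "e")
  ))
  merged <- apply_merge_map(corpus, c(
    "time wasting" = "time wasting", "wasting time" = "time wasting"
  ))
  lex <- lexicon(merged)
  expect_equal(lex$n_participants[lex$token == "time wasting"], 2L)
  expect_false("wasting time" %in% lex$token)
  expect_lte(nrow(lex), nrow(lexicon(corpus)))

  # empty map is the identity
  expect_equal(apply_merge_map(corpus, character())$mentions, corpus$mentions)
  # data-frame form, unmapped tokens pass through
  df_map <- data.frame(raw = "a", canonical = "alpha")
  expect_true("alpha" %in% lexicon(apply_merge_map(corpus, df_map))$token)
  # non-idempotent map rejected
  expect_error(
    apply_merge_map(corpus, c(a = "b", b = "c")),
    class = "coop_validation_error"
  )
})

test_that("other-category participants are removed and the removal logged", {
  corpus <- make_corpus(
    replicate(10, c("a", "b", "c", "d", "e"), simplify = FALSE),
    category = c(rep("alcohol", 5), rep("gaming", 3), "other", "other")
  )
  out <- drop_other_category(corpus)
  expect_equal(n_participants(out), 8)
  expect_equal(out$filter_log$n_removed[out$filter_log$step == "drop_other"], 2L)
  # no 'other' present: identity
  out2 <- drop_other_category(out)
  expect_equal(out2$participants, out$participants)
  # all 'other': warning + empty corpus
  all_other <- make_corpus(list(c("a", "b", "c", "d", "e")), category = "other")
  expect_warning(dropped <- drop_other_category(all_other), "empty")
  expect_equal(n_participants(dropped), 0)
})

test_that("the rare-token filter keeps tokens at or above the cutoff and reports coverage", {
  # 12 participants mention "a", 9 of them also "b"; filler tokens unique
  assoc <- lapply(1:12, function(i) {
    c("a", if (i <= 9) "b" else paste0("x", i), paste0("f", i, "_", 1:3))
  })
  corpus <- make_corpus(assoc)
  out <- filter_rare_tokens(corpus, min_count = 10)
  expect_equal(lexicon(out)$token, "a")

  # derived coverage: one token in all 4 quintets, 16 singletons -> 4/20
  assoc <- lapply(1:4, function(i) c("z", paste0("u", i, "_", 1:4)))
  corpus4 <- make_corpus(assoc)
  out4 <- filter_rare_tokens(corpus4, min_count = 4)
  expect_equal(attr(out4, "coverage"), 4 / 20)

  # min_count = 1 is the identity with full coverage
  out1 <- filter_rare_tokens(corpus, min_count = 1)
  expect_equal(out1$mentions, corpus$mentions)
  expect_equal(attr(out1, "coverage"), 1)
})

test_that("participants retaining zero tokens are dropped, boundary cases kept", {
  assoc <- c(
    lapply(1:10, function(i) c("a", "b", paste0("f", i, "_", 1:3))),
    list(paste0("lone_", 1:5)) # all five tokens idiosyncratic
  )
  corpus <- make_corpus(assoc)
  filtered <- filter_rare_tokens(corpus, min_count = 10)
  out <- drop_unclassifiable_participants(filtered)
  expect_equal(n_participants(out), 10)
  expect_false("p11" %in% out$participants$participant_id)
  # a participant retaining a single token is kept
  expect_true(all(out$participants$participant_id %in% out$mentions$participant_id))
  # nothing to drop: identity
  out2 <- drop_unclassifiable_participants(out)
  expect_equal(out2$participants, out$participants)
})

test_that("emotion labels are retained at or above the participation threshold (inclusive)", {
  labels <- panas_labels()
  wide <- make_responses(lapply(1:4, function(i) paste0("t", i, "_", 1:5)))
  # participant-level provision: rebuild labels so "joy" appears for exactly 2
  # of 4 participants and "shame" for 3 of 4
  wide$emo_1a <- c("joy", "joy", "shame", "shame")
  wide$emo_1b <- c("shame", "guilt", "guilt", "guilt")
  corpus <- as_corpus(wide, pipeline_config())
  part <- label_participation(corpus)
  expect_equal(part$n_participants[part$label == "joy"], 2L)
  expect_equal(part$n_participants[part$label == "shame"], 3L)

  out <- filter_emotion_labels(corpus, threshold = 0.5)
  expect_true("shame" %in% out$retained_labels)
  expect_true("joy" %in% out$retained_labels) # exactly half: >= is inclusive
  expect_false("hostility" %in% out$retained_labels)

  all20 <- filter_emotion_labels(corpus, threshold = 0)
  expect_setequal(all20$retained_labels, labels)
})

test_that("filtering is monotone in the cutoff", {
  sim <- generate_corpus(synthetic_config(
    n_participants = 120, tokens_per_module = c(10, 10, 10, 10)
  ), seed = 2)
  prev_tokens <- Inf
  prev_cov <- Inf
  prev_part <- Inf
  for (mc in c(1, 3, 6, 12, 25)) {
    out <- filter_rare_tokens(sim$corpus, min_count = mc)
    out <- drop_unclassifiable_participants(out)
    expect_lte(nrow(lexicon(out)), prev_tokens)
    expect_lte(attr(out, "coverage"), prev_cov)
    expect_lte(n_participants(out), prev_part)
    prev_tokens <- nrow(lexicon(out))
    prev_cov <- attr(out, "coverage")
    prev_part <- n_participants(out)
  }
})

test_that("the full chain runs in order and each step is idempotent", {
  sim <- generate_corpus(synthetic_config(
    n_participants = 150, tokens_per_module = c(10, 10, 10, 10)
  ), seed = 3)
  cfg <- pipeline_config(min_token_count = 5)
  out <- preprocess_corpus(sim$corpus, config = cfg)
  expect_equal(out$filter_log$step, c(
    "normalize", "merge", "drop_other", "filter_rare",
    "drop_unclassifiable", "filter_labels"
  ))
  again <- preprocess_corpus(out, config = cfg)
  expect_equal(again$mentions, out$mentions)
  expect_equal(again$participants, out$participants)
  expect_equal(again$retained_labels, out$retained_labels)
})

test_that("the frequency-rank report orders tokens and accumulates coverage to 1", {
  corpus <- make_corpus(list(
    c("a", "b", "c", "d", "e"),
    c("a", "b", "f", "g", "h")
  ))
  rep <- frequency_rank_report(corpus)
  expect_equal(rep$rank, seq_len(nrow(rep)))
  expect_true(all(diff(rep$n_participants) <= 0))
  expect_equal(rep$cum_coverage[nrow(rep)], 1)
})
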