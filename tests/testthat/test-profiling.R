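# a small corpus with a controllable module structure: tokens a* in module 1,
# b* in module 2
profile_fixture <- function() {
  assoc <- list(
    c("a1", "a2", "a1", "a2", "b1"),   # distinct {a1,a2,b1}: 2 vs 1 -> module 1
    c("a1", "a2", "b1", "b2", "b2"),   # distinct 2 vs 2: tie
    c("b1", "b2", "b1", "b2", "b1"),   # module 2
    c("a1", "b1", "b2", "b2", "b1")    # 1 vs 2 -> module 2
  )
  corpus <- make_corpus(assoc,
                        category = c("alcohol", "gaming", "tobacco", "eating"),
                        intensity = c(4, 2, 4, 1))
  partition <- tibble::tibble(
    token = c("a1", "a2", "b1", "b2"),
    module = c(1L, 1L, 2L, 2L)
  )
  list(corpus = corpus, partition = partition)
}

test_that("participants are linked by plurality with the documented tie-breaks", {
  fx <- profile_fixture()
  asg <- assign_participants(fx$corpus, fx$partition)
  expect_equal(asg$module[asg$participant_id == "p01"], 1L)
  expect_equal(asg$module[asg$participant_id == "p03"], 2L)
  expect_equal(asg$module[asg$participant_id == "p04"], 2L)
  # tie for p02: b-tokens are more frequent in the corpus (b1:4, b2:3 vs
  # a1:3, a2:2) so the tie goes to module 2
  expect_equal(asg$module[asg$participant_id == "p02"], 2L)

  # frequency-equal tie falls back to the lowest module id
  even <- make_corpus(list(
    c("a1", "a2", "b1", "b2", "b2"),
    c("a1", "a2", "b1", "b2", "a1")
  ))
  asg_even <- assign_participants(even, fx$partition)
  expect_equal(asg_even$module, c(1L, 1L))
})

test_that("assignment ignores participant order and respects module relabeling", {
  fx <- profile_fixture()
  asg <- assign_participants(fx$corpus, fx$partition)

  shuffled <- fx$corpus
  shuffled$participants <- shuffled$participants[c(3, 1, 4, 2), ]
  shuffled$mentions <- shuffled$mentions[rev(seq_len(nrow(shuffled$mentions))), ]
  asg2 <- assign_participants(shuffled, fx$partition)
  j <- dplyr::inner_join(asg, asg2, by = "participant_id")
  expect_equal(j$module.x, j$module.y)

  relabeled <- fx$partition
  relabeled$module <- 3L - relabeled$module # swap 1 <-> 2
  asg3 <- assign_participants(fx$corpus, relabeled)
  expect_equal(asg3$module, 3L - asg$module)

  # dropping a participant leaves the others untouched
  smaller <- fx$corpus
  smaller$participants <- smaller$participants[-2, ]
  smaller$mentions <- dplyr::filter(smaller$mentions, participant_id != "p02")
  asg4 <- assign_participants(smaller, fx$partition)
  j <- dplyr::inner_join(asg, asg4, by = "participant_id")
  expect_equal(j$module.x, j$module.y)

  # unassigned participants get NA, and partitions must cover the lexicon
  expect_error(
    assign_participants(fx$corpus, fx$partition[-1, ]),
    class = "coop_consistency_error"
  )
})

test_that("module emotion distributions normalize to 100 within modules", {
  fx <- profile_fixture()
  corpus <- filter_emotion_labels(fx$corpus, threshold = 0)
  ed <- emotion_distribution(corpus, fx$partition)
  sums <- as.numeric(tapply(ed$pct, ed$module, sum))
  expect_equal(sums, rep(100, length(sums)), tolerance = 1e-9)

  # a module carrying a single label is 100% that label
  one <- make_corpus(list(c("a1", "a1", "a1", "a1", "a1"),
                          c("b1", "b1", "b1", "b1", "b1")))
  one$mentions$label_1 <- "joy"
  one$mentions$label_2 <- "calmness"
  ed1 <- emotion_distribution(one, tibble::tibble(
    token = c("a1", "b1"), module = c(1L, 2L)
  ), labels = "joy")
  expect_equal(ed1$pct, c(100, 100))
  expect_equal(ed1$label, c("joy", "joy"))
})

test_that("synthetic corpora recover the generating emotion profiles", {
  cfg <- synthetic_config(n_participants = 500, concentration = 0.9)
  sim <- generate_corpus(cfg, seed = 6)
  ed <- emotion_distribution(sim$corpus, sim$token_modules, labels = cfg$labels)
  full <- tidyr::expand_grid(module = 1:4, label = cfg$labels) %>%
    dplyr::left_join(ed, by = c("module", "label")) %>%
    dplyr::mutate(pct = tidyr::replace_na(pct, 0))
  true <- cfg$emotion_profiles * 100
  errs <- abs(full$pct - true[cbind(full$module, match(full$label, colnames(true)))])
  expect_lt(max(errs), 3) # within 3 percentage points at n = 500
})

test_that("module summaries have consistent counts and type percentages", {
  sim <- generate_corpus(synthetic_config(n_participants = 300), seed = 8)
  corp <- filter_emotion_labels(sim$corpus, 0.5)
  part <- sim$token_modules
  asg <- assign_participants(corp, part)
  ms <- module_summary(corp, part, asg)
  expect_equal(sum(ms$n), sum(!is.na(asg$module)))
  expect_equal(sum(ms$pct_substance), 100, tolerance = 1e-9)
  expect_equal(sum(ms$pct_behavior), 100, tolerance = 1e-9)
  expect_true(all(ms$pct_high_intensity >= 0 & ms$pct_high_intensity <= 100))
  expect_equal(nrow(ms), 4)
  # affect shares sum to 100 within each module
  expect_equal(ms$pct_affect_positive + ms$pct_affect_negative,
               rep(100, 4), tolerance = 1e-9)

  # a single-module corpus yields a single all-inclusive profile
  fx <- profile_fixture()
  corpus1 <- filter_emotion_labels(fx$corpus, 0)
  p1 <- tibble::tibble(token = c("a1", "a2", "b1", "b2"), module = 1L)
  ms1 <- module_summary(corpus1, p1)
  expect_equal(nrow(ms1), 1)
  expect_equal(ms1$n, 4L)

  # top-token ties break alphabetically
  expect_equal(ms1$top_tokens[[1]]$token[1:2], c("b1", "a1"))
})
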