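test_that("pair tables count duplicate-collapsed participant sets", {
  # sets {a,b}, {a,b}, {a}, {c}
  corpus <- make_corpus(list(
    c("a", "b", "a", "b", "a"),
    c("a", "b", "b", "a", "b"),
    c("a", "a", "a", "a", "a"),
    c("c", "c", "c", "c", "c")
  ))
  t <- pair_table(corpus, "a", "b")
  expect_equal(t$n11, 2)
  expect_equal(t$n10, 1)
  expect_equal(t$n01, 0)
  expect_equal(t$n00, 1)
  expect_equal(t$N, 4)

  expect_error(pair_table(corpus, "a", "a"), class = "coop_lookup_error")
  expect_error(pair_table(corpus, "a", "zz"), class = "coop_lookup_error")
  empty <- make_corpus(list(c("a", "b", "c", "d", "e")), category = "other")
  empty <- suppressWarnings(drop_other_category(empty))
  expect_error(pair_table(empty, "a", "b"), class = "coop_degenerate_error")
})

test_that("the G statistic matches closed forms and the likelihood oracle", {
  # observed equals expectation -> 0
  expect_equal(loglikelihood_ratio(list(n11 = 5, n10 = 5, n01 = 5, n00 = 5)), 0)
  # perfect association, closed form 40 ln 2
  g <- loglikelihood_ratio(list(n11 = 10, n10 = 0, n01 = 0, n00 = 10))
  expect_equal(g, 40 * log(2), tolerance = 1e-12)
  expect_gt(signed_weight(list(n11 = 10, n10 = 0, n01 = 0, n00 = 10)), 0)
  expect_lt(signed_weight(list(n11 = 0, n10 = 10, n01 = 10, n00 = 0)), 0)
  # exact independence -> weight 0
  expect_equal(signed_weight(list(n11 = 4, n10 = 4, n01 = 4, n00 = 4)), 0)
  # zero margins are undefined
  expect_error(loglikelihood_ratio(list(n11 = 0, n10 = 0, n01 = 3, n00 = 7)),
               class = "coop_degenerate_error")
  expect_error(signed_weight(list(n11 = 5, n10 = 0, n01 = 5, n00 = 0)),
               class = "coop_degenerate_error")

  # random tables against the independent multinomial log-likelihood oracle
  withr::with_seed(42, {
    for (r in 1:200) {
      tt <- as.list(setNames(rmultinom(1, sample(8:200, 1), runif(4, 0.05, 1)),
                             c("n11", "n10", "n01", "n00")))
      ok <- (tt$n11 + tt$n10) > 0 && (tt$n01 + tt$n00) > 0 &&
        (tt$n11 + tt$n01) > 0 && (tt$n10 + tt$n00) > 0
      if (!ok) next
      expect_equal(loglikelihood_ratio(tt),
                   g_oracle(tt$n11, tt$n10, tt$n01, tt$n00),
                   tolerance = 1e-9)
    }
  })
})

test_that("G is invariant under token swap and table transposition", {
  withr::with_seed(9, {
    for (r in 1:50) {
      v <- as.numeric(rmultinom(1, 60, c(.3, .25, .25, .2))) + 1
      g0 <- loglikelihood_ratio(list(n11 = v[1], n10 = v[2], n01 = v[3], n00 = v[4]))
      gs <- loglikelihood_ratio(list(n11 = v[1], n10 = v[3], n01 = v[2], n00 = v[4]))
      expect_equal(g0, gs, tolerance = 1e-12)
    }
  })
})

test_that("the network carries hand-checkable signs and is order invariant", {
  # a and b always together, never with c; d is filler
  assoc <- list(
    c("a", "b", "d1", "d2", "d3"),
    c("a", "b", "d4", "d5", "d6"),
    c("a", "b", "d7", "d8", "d9"),
    c("c", "d1", "d4", "d7", "e1"),
    c("c", "d2", "d5", "d8", "e2"),
    c("c", "d3", "d6", "d9", "e3")
  )
  corpus <- make_corpus(assoc)
  net <- build_network(corpus)
  W <- as_adjacency(net)
  expect_gt(W["a", "b"], 0)
  expect_lt(W["a", "c"], 0)
  expect_equal(W, t(W))
  expect_true(all(is.finite(W)))
  expect_equal(diag(W), setNames(rep(0, nrow(W)), rownames(W)))

  # strengths recompute exactly from edges; totals split by sign
  s <- network_strengths(net)
  expect_equal(s$s_pos, rowSums(pmax(W, 0)), ignore_attr = TRUE)
  tot <- network_totals(net)
  expect_equal(tot$v_pos, sum(pmax(W, 0)) / 2)
  expect_equal(tot$v_neg, sum(pmax(-W, 0)) / 2)

  # permuting participants leaves the network unchanged
  perm <- corpus
  ord <- rev(seq_len(nrow(perm$participants)))
  perm$participants <- perm$participants[ord, ]
  perm$mentions <- perm$mentions[sample(nrow(perm$mentions)), ]
  net2 <- build_network(perm)
  expect_equal(as_adjacency(net2), W)

  single <- make_corpus(list(c("a", "a", "a", "a", "a")))
  expect_error(build_network(single), class = "coop_degenerate_error")
})

test_that("G is calibrated on corpora with truly independent token mentions", {
  # control: Bernoulli incidence at matched margins; fraction of pairs above
  # the chi-square(1) 0.999 quantile should be near 0.001
  crit <- qchisq(0.999, 1)
  fracs <- sapply(1:3, function(s) {
    withr::with_seed(s, {
      n <- 2000
      V <- 77
      p <- pmin(5 * (seq_len(V)^-1) / sum(seq_len(V)^-1), 0.9)
      M <- matrix(rbinom(n * V, 1, rep(p, each = n)), n, V)
      C <- crossprod(M)
      cnt <- diag(C)
      ut <- which(upper.tri(C), arr.ind = TRUE)
      n11 <- C[ut]
      ci <- cnt[ut[, 1]]
      cj <- cnt[ut[, 2]]
      ok <- ci > 0 & cj > 0 & ci < n & cj < n
      g <- abs(signed_weight(list(
        n11 = n11[ok], n10 = ci[ok] - n11[ok],
        n01 = cj[ok] - n11[ok], n00 = n - ci[ok] - cj[ok] + n11[ok]
      )))
      mean(g > crit)
    })
  })
  expect_gte(mean(fracs), 0)
  expect_lte(mean(fracs), 0.002)
})
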