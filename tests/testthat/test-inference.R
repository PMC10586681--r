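test_that("the chi-square test matches hand computation and an independent oracle", {
  res <- chi_square_independence(matrix(c(10, 20, 20, 10), 2, byrow = TRUE))
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-12)
  expect_equal(res$df, 1)
  expect_equal(res$n, 60)
  # independent oracle: direct sum of (O-E)^2/E
  withr::with_seed(13, {
    for (r in 1:25) {
      tab <- matrix(rpois(8, 20) + 1, 2, 4)
      res <- chi_square_independence(tab)
      E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      expect_equal(res$statistic, sum((tab - E)^2 / E), tolerance = 1e-10)
      expect_equal(res$df, 3)
      expect_equal(res$residuals, (tab - E) / sqrt(E), ignore_attr = TRUE,
                   tolerance = 1e-10)
      expect_equal(rowSums(res$expected), rowSums(tab), ignore_attr = TRUE)
    }
  })
})

test_that("chi-square is zero under exact proportionality and invariant to permutation", {
  prop <- outer(c(1, 2, 3), c(10, 20, 5, 15))
  expect_equal(chi_square_independence(prop)$statistic, 0, tolerance = 1e-10)

  tab <- matrix(c(12, 7, 30, 9, 14, 22, 5, 11), 2, 4)
  s0 <- chi_square_independence(tab)$statistic
  expect_equal(chi_square_independence(tab[, c(3, 1, 4, 2)])$statistic, s0)
  expect_equal(chi_square_independence(tab[c(2, 1), ])$statistic, s0)
  expect_equal(chi_square_independence(t(tab))$statistic, s0)

  expect_error(chi_square_independence(matrix(c(0, 0, 3, 4), 2)),
               class = "coop_degenerate_error")
})

test_that("intensity dichotomizes at 'Totally agree'", {
  x <- c(1, 2, 3, 4, 4, 2)
  g <- dichotomize_intensity(x)
  expect_equal(as.character(g), c("low", "low", "low", "high", "high", "low"))
  expect_equal(length(g), length(x))
  expect_error(dichotomize_intensity(c(1, 5)))
})

test_that("Kruskal-Wallis matches a brute-force rank oracle and handles ties", {
  kw_oracle <- function(values, groups) {
    r <- rank(values)
    N <- length(values)
    h <- 12 / (N * (N + 1)) *
      sum(tapply(r, groups, function(x) length(x) * mean(x)^2)) - 3 * (N + 1)
    ties <- table(values)
    h / (1 - sum(ties^3 - ties) / (N^3 - N))
  }
  df <- data.frame(v = c(1, 2, 3, 4), g = c("a", "a", "b", "b"))
  res <- kruskal_wallis(df, v, g)
  expect_equal(res$h, kw_oracle(df$v, df$g), tolerance = 1e-12)
  expect_equal(res$df, 1)

  withr::with_seed(21, {
    for (r in 1:20) {
      k <- sample(2:4, 1)
      df <- data.frame(
        v = sample(1:6, 40, replace = TRUE), # heavy ties
        g = sample(letters[1:k], 40, replace = TRUE)
      )
      if (length(unique(df$g)) < k || length(unique(df$v)) == 1) next
      res <- kruskal_wallis(df, v, g)
      expect_equal(res$h, kw_oracle(df$v, df$g), tolerance = 1e-10)
      expect_equal(res$df, length(unique(df$g)) - 1)
      expect_gte(res$h, 0)
    }
  })

  # two identically distributed groups -> H = 0
  sym <- data.frame(v = c(1, 2, 3, 1, 2, 3), g = rep(c("a", "b"), each = 3))
  expect_equal(kruskal_wallis(sym, v, g)$h, 0, tolerance = 1e-12)

  # degenerate: all values identical -> flagged, not thrown
  flat <- data.frame(v = rep(2, 10), g = rep(c("a", "b"), 5))
  res <- kruskal_wallis(flat, v, g)
  expect_true(res$degenerate)
  expect_true(is.na(res$h))

  expect_error(kruskal_wallis(data.frame(v = 1:3, g = "a"), v, g),
               class = "coop_degenerate_error")
})

test_that("Dunn z statistics match a direct mean-rank oracle", {
  dunn_oracle <- function(values, groups, g1, g2) {
    r <- rank(values)
    N <- length(values)
    ties <- table(values)
    s2 <- (N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1)))
    m <- tapply(r, groups, mean)
    n <- tapply(r, groups, length)
    (m[g1] - m[g2]) / sqrt(s2 * (1 / n[g1] + 1 / n[g2]))
  }
  withr::with_seed(31, {
    for (r in 1:15) {
      df <- data.frame(
        v = sample(1:8, 45, replace = TRUE),
        g = sample(c("a", "b", "c"), 45, replace = TRUE)
      )
      if (length(unique(df$v)) == 1) next
      dn <- dunn_pairwise(df, v, g)
      for (i in seq_len(nrow(dn))) {
        expect_equal(
          dn$z[i],
          unname(dunn_oracle(df$v, df$g, dn$group1[i], dn$group2[i])),
          tolerance = 1e-10
        )
      }
      expect_equal(dn$p_value, 2 * pnorm(-abs(dn$z)), tolerance = 1e-12)
    }
  })
})

test_that("Dunn handles identical groups, symmetry, and p adjustment", {
  flat <- data.frame(v = rep(1, 9), g = rep(c("a", "b", "c"), 3))
  dn <- dunn_pairwise(flat, v, g)
  expect_equal(dn$z, rep(0, 3))
  expect_equal(dn$p_value, rep(1, 3))

  df <- data.frame(v = c(1, 5, 2, 8, 3, 9, 4, 2, 7), g = rep(c("a", "b", "c"), 3))
  dn <- dunn_pairwise(df, v, g)
  m <- dunn_matrix(dn, "p_value")
  expect_equal(m, t(m))
  expect_true(all(is.na(diag(m))))

  dh <- dunn_pairwise(df, v, g, adjust = "holm")
  expect_true(all(dh$p_adjusted >= dh$p_value - 1e-12))

  # a coop_kruskal object can seed the pairwise tests directly
  kw <- kruskal_wallis(df, v, g)
  expect_equal(dunn_pairwise(kw)$z, dn$z)
})

test_that("emotion rank tests run per label over module and type groupings", {
  sim <- generate_corpus(synthetic_config(n_participants = 250), seed = 12)
  corp <- filter_emotion_labels(sim$corpus, 0.4)
  asg <- assign_participants(corp, sim$token_modules)
  rt <- emotion_rank_tests(corp, asg, group = "module")
  expect_setequal(rt$label, corp$retained_labels)
  expect_true(all(rt$df == 3 | rt$degenerate))
  expect_true(all(vapply(rt$dunn, nrow, 1L) == 6))

  rt2 <- emotion_rank_tests(corp, asg, group = "type")
  expect_true(all(rt2$df == 1 | rt2$degenerate))

  cts <- mr_chisq_tests(asg)
  expect_named(cts, c("type_by_module", "intensity_by_module_substance",
                      "intensity_by_module_behavior"))
  expect_equal(cts$type_by_module$df, 3)
})
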