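#' Chi-square test of independence with cell residuals
#'
#' Plain Pearson chi-square (no continuity correction) on a two-way count
#' table, with per-cell standardized residuals `(O - E) / sqrt(E)` describing
#' how far each cell deviates from independence.
#'
#' @param x A count matrix/table, or a data frame of two categorical columns
#'   to be cross-tabulated.
#' @return A `coop_chisq` object: `observed`, `expected`, `statistic`, `df`,
#'   `n`, `p_value`, `residuals`. Use [tidy()] for a per-cell tibble and
#'   [glance()] for a one-row summary.
#' @export
chi_square_independence <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(ncol(x) == 2)
    x <- table(x[[1]], x[[2]])
  }
  x <- as.matrix(x)
  if (any(x < 0) || any(rowSums(x) == 0) || any(colSums(x) == 0)) {
    abort("Degenerate table: negative cells or a zero margin.",
          class = "coop_degenerate_error")
  }
  ct <- suppressWarnings(chisq.test(x, correct = FALSE))
  structure(
    list(
      observed = unclass(ct$observed),
      expected = unclass(ct$expected),
      statistic = unname(ct$statistic),
      df = unname(ct$parameter),
      n = sum(x),
      p_value = unname(ct$p.value),
      residuals = unclass(ct$residuals)
    ),
    class = "coop_chisq"
  )
}

#' @export
print.coop_chisq <- function(x, ...) {
  cat(sprintf(
    "Chi-square test of independence: chi2(df = %d, N = %d) = %.4g, p = %.4g\n",
    x$df, x$n, x$statistic, x$p_value
  ))
  invisible(x)
}

#' Split the intensity item into low/high problem intensity
#'
#' Participants answering "Totally agree" (4) to the past-12-months excess
#' item form the high-intensity group; "Totally disagree", "Partly disagree"
#' and "Partly agree" (1-3) form the low-intensity group.
#'
#' @param intensity Integer vector with values in 1-4.
#' @return Factor with levels `low`, `high`.
#' @export
dichotomize_intensity <- function(intensity) {
  stopifnot(all(intensity %in% 1:4 | is.na(intensity)))
  factor(ifelse(intensity == 4, "high", "low"), levels = c("low", "high"))
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic referred to a chi-square distribution on
#' `k - 1` degrees of freedom. If every observation is identical the statistic
#' is undefined; the result is returned flagged (`degenerate = TRUE`, `h = NA`)
#' rather than throwing.
#'
#' @param data A data frame.
#' @param value Column with the numeric response (tidy-eval).
#' @param group Column with the grouping variable (tidy-eval).
#' @return A `coop_kruskal` object: `h`, `df`, `p_value`, `group_sizes`,
#'   `degenerate`, plus the data vectors for downstream [dunn_pairwise()].
#' @export
kruskal_wallis <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- factor(dplyr::pull(data, {{ group }}))
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]
  g <- droplevels(g[keep])
  if (nlevels(g) < 2 || any(tabulate(g) == 0)) {
    abort("Need at least 2 non-empty groups.", class = "coop_degenerate_error")
  }
  if (length(unique(v)) == 1) {
    out <- list(
      h = NA_real_, df = nlevels(g) - 1L, p_value = NA_real_,
      group_sizes = table(g), degenerate = TRUE, value = v, group = g
    )
    return(structure(out, class = "coop_kruskal"))
  }
  kt <- kruskal.test(v, g)
  structure(
    list(
      h = unname(kt$statistic),
      df = unname(kt$parameter),
      p_value = unname(kt$p.value),
      group_sizes = table(g),
      degenerate = FALSE,
      value = v,
      group = g
    ),
    class = "coop_kruskal"
  )
}

#' @export
print.coop_kruskal <- function(x, ...) {
  if (x$degenerate) {
    cat("Kruskal-Wallis: undefined (all observations identical)\n")
  } else {
    cat(sprintf(
      "Kruskal-Wallis: H = %.4g, df = %d, p = %.4g\n", x$h, x$df, x$p_value
    ))
  }
  invisible(x)
}

#' Dunn's pairwise comparisons after a Kruskal-Wallis test
#'
#' Pairwise z statistics on the pooled ranks with tie correction:
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j))`
#' with `T = sum(t^3 - t)` over tie groups. Two-sided p-values; no
#' multiplicity adjustment by default (Holm etc. available via `adjust`).
#'
#' @param x A `coop_kruskal` object, or a data frame (then give `value` and
#'   `group` as for [kruskal_wallis()]).
#' @param value,group Tidy-eval columns when `x` is a data frame.
#' @param adjust A [stats::p.adjust()] method; default `"none"`.
#' @return A tibble with one row per unordered group pair: `group1`, `group2`,
#'   `mean_rank_diff`, `z`, `p_value`, `p_adjusted`.
#' @export
dunn_pairwise <- function(x, value = NULL, group = NULL, adjust = "none") {
  if (inherits(x, "coop_kruskal")) {
    v <- x$value
    g <- x$group
  } else {
    v <- dplyr::pull(x, {{ value }})
    g <- factor(dplyr::pull(x, {{ group }}))
  }
  if (length(unique(v)) == 1) {
    lev <- levels(g)
    pairs <- utils::combn(lev, 2)
    return(tibble(
      group1 = pairs[1, ], group2 = pairs[2, ],
      mean_rank_diff = 0, z = 0, p_value = 1, p_adjusted = 1
    ))
  }
  N <- length(v)
  r <- rank(v)
  tie_counts <- table(v)
  TT <- sum(tie_counts^3 - tie_counts)
  sigma2 <- N * (N + 1) / 12 - TT / (12 * (N - 1))
  mean_ranks <- tapply(r, g, mean)
  sizes <- tapply(r, g, length)
  lev <- levels(g)
  pairs <- utils::combn(lev, 2)
  diffs <- mean_ranks[pairs[1, ]] - mean_ranks[pairs[2, ]]
  se <- sqrt(sigma2 * (1 / sizes[pairs[1, ]] + 1 / sizes[pairs[2, ]]))
  z <- as.numeric(diffs / se)
  p <- 2 * pnorm(-abs(z))
  tibble(
    group1 = pairs[1, ],
    group2 = pairs[2, ],
    mean_rank_diff = as.numeric(diffs),
    z = z,
    p_value = p,
    p_adjusted = p.adjust(p, method = adjust)
  )
}

#' Matrix view of Dunn pairwise results
#'
#' @param dunn Output of [dunn_pairwise()].
#' @param what Column to spread into a symmetric matrix (`"p_value"`,
#'   `"p_adjusted"` or `"z"`; z is antisymmetric, so its magnitude is used).
#' @return A symmetric matrix with `NA` diagonal.
#' @export
dunn_matrix <- function(dunn, what = c("p_value", "p_adjusted", "z")) {
  what <- match.arg(what)
  lev <- unique(c(dunn$group1, dunn$group2))
  m <- matrix(NA_real_, length(lev), length(lev), dimnames = list(lev, lev))
  vals <- dunn[[what]]
  if (what == "z") vals <- abs(vals)
  m[cbind(dunn$group1, dunn$group2)] <- vals
  m[cbind(dunn$group2, dunn$group1)] <- vals
  m
}

#' Per-participant counts of each retained emotion label
#'
#' The observation unit for the emotion rank tests: for every participant, how
#' many of their retained selections (two labels per retained association)
#' carry the focal label.
#'
#' @param corpus A [coop_corpus] with retained labels (or pass `labels`).
#' @param labels Labels to count; defaults to the retained set.
#' @return A tibble `participant_id`, `label`, `n` (zeros included).
#' @export
emotion_label_counts <- function(corpus, labels = NULL) {
  stopifnot(inherits(corpus, "coop_corpus"))
  labels <- labels %||% corpus$retained_labels
  if (is.null(labels)) {
    abort("No retained labels: run filter_emotion_labels() or pass `labels`.",
          class = "coop_config_error")
  }
  long <- corpus$mentions %>%
    tidyr::pivot_longer(c("label_1", "label_2"), values_to = "label") %>%
    filter(.data$label %in% labels) %>%
    count(.data$participant_id, .data$label)
  tidyr::expand_grid(
    participant_id = corpus$participants$participant_id,
    label = labels
  ) %>%
    left_join(long, by = c("participant_id", "label")) %>%
    mutate(n = tidyr::replace_na(.data$n, 0L))
}

#' Kruskal-Wallis + Dunn tests of emotion frequencies across groups
#'
#' For each retained label, participants' per-label counts are compared across
#' either the assigned modules (`group = "module"`) or the substance/behavior
#' problem type (`group = "type"`); the module/type ambiguity is left to the
#' caller. Unassigned participants are dropped.
#'
#' @param corpus A [coop_corpus].
#' @param assignments Output of [assign_participants()].
#' @param group `"module"` or `"type"`.
#' @param labels Labels to test; defaults to the retained set.
#' @param adjust p-adjustment method for the Dunn tests; default `"none"`.
#' @return A tibble with one row per label: `label`, `h`, `df`, `p_value`,
#'   `degenerate` and a `dunn` list-column of pairwise tibbles.
#' @export
emotion_rank_tests <- function(corpus, assignments, group = c("module", "type"),
                               labels = NULL, adjust = "none") {
  group <- match.arg(group)
  counts <- emotion_label_counts(corpus, labels) %>%
    inner_join(assignments, by = "participant_id") %>%
    filter(!is.na(.data$module))
  if (group == "type") {
    counts <- filter(counts, .data$type %in% c("substance", "behavior"))
  }
  counts %>%
    group_by(label_ = .data$label) %>%
    group_map(~ {
      kw <- kruskal_wallis(.x, .data$n, .data[[group]])
      tibble(
        label = .y$label_,
        h = kw$h, df = kw$df, p_value = kw$p_value,
        degenerate = kw$degenerate,
        dunn = list(dunn_pairwise(kw, adjust = adjust))
      )
    }) %>%
    bind_rows()
}

#' The module-membership contingency tests
#'
#' The three chi-square tests linking module membership to the participants'
#' problem characteristics: problem type (substance vs behavior) against
#' module, and problem intensity (low vs high) against module within the
#' substance and behavior subsets separately.
#'
#' @param assignments Output of [assign_participants()] (unassigned rows are
#'   dropped).
#' @return A named list of `coop_chisq` objects:
#'   `type_by_module`, `intensity_by_module_substance`,
#'   `intensity_by_module_behavior`.
#' @export
mr_chisq_tests <- function(assignments) {
  a <- assignments %>%
    filter(!is.na(.data$module), .data$type %in% c("substance", "behavior"))
  list(
    type_by_module = chi_square_independence(table(a$type, a$module)),
    intensity_by_module_substance = chi_square_independence(
      with(filter(a, .data$type == "substance"), table(intensity_group, module))
    ),
    intensity_by_module_behavior = chi_square_independence(
      with(filter(a, .data$type == "behavior"), table(intensity_group, module))
    )
  )
}
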