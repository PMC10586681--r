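#' Link participants to modules by plurality of their associations
#'
#' Each participant is assigned to the module from which most of their
#' retained associations come. Ties go to the module whose tied tokens have
#' the larger summed corpus frequency, then to the lowest module id.
#' Participants retaining no tokens are left unassigned (`NA`).
#'
#' @param corpus A preprocessed [coop_corpus].
#' @param partition A `coop_partition` covering the corpus lexicon.
#' @return A tibble with one row per participant: `participant_id`, `module`
#'   (integer or `NA`), `n_tokens` (retained distinct tokens), plus the
#'   participant's `category`, `type`, `intensity` and `intensity_group`
#'   (low/high, see [dichotomize_intensity()]).
#' @export
assign_participants <- function(corpus, partition) {
  stopifnot(inherits(corpus, "coop_corpus"))
  p <- as_tibble(partition)
  lex <- lexicon(corpus)
  if (!all(lex$token %in% p$token)) {
    abort("Partition does not cover the corpus lexicon.", class = "coop_consistency_error")
  }
  sets <- corpus$mentions %>%
    distinct(.data$participant_id, .data$token) %>%
    left_join(p, by = "token") %>%
    left_join(lex, by = "token")
  scored <- sets %>%
    group_by(.data$participant_id, .data$module) %>%
    summarise(
      n_in_module = n(),
      freq_sum = sum(.data$n_participants),
      .groups = "drop"
    ) %>%
    group_by(.data$participant_id) %>%
    arrange(desc(.data$n_in_module), desc(.data$freq_sum), .data$module,
            .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    select("participant_id", "module", n_tokens_grp = "n_in_module")
  counts <- sets %>% count(.data$participant_id, name = "n_tokens")
  corpus$participants %>%
    left_join(counts, by = "participant_id") %>%
    left_join(scored %>% select("participant_id", "module"), by = "participant_id") %>%
    mutate(
      n_tokens = tidyr::replace_na(.data$n_tokens, 0L),
      module = ifelse(.data$n_tokens == 0, NA_integer_, .data$module),
      intensity_group = dichotomize_intensity(.data$intensity)
    ) %>%
    select("participant_id", "module", "n_tokens", "category", "type",
           "intensity", "intensity_group")
}

#' Relative emotion-label distribution per module
#'
#' Counts every retained label attached to a member-token mention (one count
#' per participant-association-label triple) and normalizes within modules to
#' percentages.
#'
#' @param corpus A [coop_corpus] (run [filter_emotion_labels()] first, or pass
#'   `labels` explicitly).
#' @param partition A `coop_partition`.
#' @param labels Labels to tabulate; defaults to the corpus' retained labels.
#' @return A tibble `module`, `label`, `n`, `pct`; `pct` sums to 100 within
#'   each module. Modules whose mentions carry none of the labels are dropped
#'   with a warning.
#' @export
emotion_distribution <- function(corpus, partition, labels = NULL) {
  stopifnot(inherits(corpus, "coop_corpus"))
  labels <- labels %||% corpus$retained_labels
  if (is.null(labels)) {
    abort("No retained labels: run filter_emotion_labels() or pass `labels`.",
          class = "coop_config_error")
  }
  p <- as_tibble(partition)
  long <- corpus$mentions %>%
    inner_join(p, by = "token") %>%
    tidyr::pivot_longer(c("label_1", "label_2"), values_to = "label") %>%
    filter(.data$label %in% labels)
  empty <- setdiff(unique(p$module[p$token %in% corpus$mentions$token]),
                   unique(long$module))
  if (length(empty)) {
    warn(sprintf("Module(s) %s have no retained-label mentions.",
                 paste(sort(empty), collapse = ", ")))
  }
  long %>%
    count(.data$module, .data$label) %>%
    group_by(.data$module) %>%
    mutate(pct = 100 * .data$n / sum(.data$n)) %>%
    ungroup() %>%
    arrange(.data$module, desc(.data$pct), .data$label)
}

#' Positive/negative affect shares per module
#'
#' Aggregates the module emotion distribution through a label-to-valence map.
#'
#' @inheritParams emotion_distribution
#' @param valence A `label`/`valence` data frame, see [default_valence()].
#' @return A tibble `module`, `valence`, `pct`.
#' @export
affect_shares <- function(corpus, partition, labels = NULL,
                          valence = default_valence(corpus$labels)) {
  emotion_distribution(corpus, partition, labels) %>%
    left_join(as_tibble(valence), by = "label") %>%
    group_by(.data$module, .data$valence) %>%
    summarise(pct = sum(.data$pct), .groups = "drop")
}

#' Module summary table
#'
#' One row per module: participant count, the top member tokens by corpus
#' frequency (ties alphabetical), the distribution of substance-type and
#' behavior-type participants across modules (each normalized within its own
#' type, so the `pct_substance` column sums to 100 over modules and likewise
#' `pct_behavior`), the within-module share of high-intensity participants,
#' and positive/negative affect shares.
#'
#' @param corpus A preprocessed [coop_corpus].
#' @param partition A `coop_partition`.
#' @param assignments Optional precomputed [assign_participants()] output.
#' @param top_n How many top tokens to list. Default 5.
#' @param valence Label-to-valence map.
#' @return A tibble with one row per module; `top_tokens` is a list-column of
#'   `token`/`n_participants` tibbles and `top_tokens_label` a flat string.
#' @export
module_summary <- function(corpus, partition, assignments = NULL, top_n = 5,
                           valence = default_valence(corpus$labels)) {
  stopifnot(inherits(corpus, "coop_corpus"))
  assignments <- assignments %||% assign_participants(corpus, partition)
  p <- as_tibble(partition)
  lex <- lexicon(corpus)

  tops <- p %>%
    inner_join(lex, by = "token") %>%
    group_by(.data$module) %>%
    arrange(desc(.data$n_participants), .data$token, .by_group = TRUE) %>%
    summarise(
      n_tokens = n(),
      top_tokens = list(tibble(
        token = head(token, top_n),
        n_participants = head(n_participants, top_n)
      )),
      top_tokens_label = paste(
        sprintf("%s (%d)", head(token, top_n), head(n_participants, top_n)),
        collapse = ", "
      ),
      .groups = "drop"
    )

  assigned <- filter(assignments, !is.na(.data$module))
  base <- assigned %>%
    group_by(.data$module) %>%
    summarise(
      n = n(),
      pct_high_intensity = 100 * mean(.data$intensity_group == "high"),
      .groups = "drop"
    )
  by_type <- assigned %>%
    filter(.data$type %in% c("substance", "behavior")) %>%
    count(.data$type, .data$module) %>%
    group_by(.data$type) %>%
    mutate(pct = 100 * .data$n / sum(.data$n)) %>%
    ungroup() %>%
    select(-"n") %>%
    tidyr::pivot_wider(names_from = "type", values_from = "pct",
                       names_prefix = "pct_")

  aff <- tryCatch(
    affect_shares(corpus, p, valence = valence) %>%
      tidyr::pivot_wider(names_from = "valence", values_from = "pct",
                         names_prefix = "pct_affect_"),
    coop_config_error = function(e) tibble(module = integer())
  )

  tops %>%
    left_join(base, by = "module") %>%
    left_join(by_type, by = "module") %>%
    left_join(aff, by = "module") %>%
    mutate(across(starts_with("pct_"), ~ tidyr::replace_na(.x, 0))) %>%
    mutate(n = tidyr::replace_na(.data$n, 0L)) %>%
    arrange(.data$module)
}
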