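#' Normalize raw association tokens
#'
#' Lower-cases, strips accents/diacritics (Latin-ASCII transliteration) and
#' trims/collapses whitespace. Tokens that become empty are invalid: free
#' associations are expected to carry at least one word character.
#'
#' @param x Character vector of raw tokens.
#' @return Character vector of canonical tokens.
#' @export
#' @examples
#' normalize_token(c("Bűntudat ", "guilt"))
normalize_token <- function(x) {
  out <- stringr::str_squish(stringr::str_to_lower(as.character(x)))
  out <- stringi::stri_trans_general(out, "Latin-ASCII")
  if (any(is.na(out) | out == "")) {
    abort("Token(s) empty after normalization.", class = "coop_validation_error")
  }
  out
}

#' Normalize every token of a corpus
#'
#' @param corpus A [coop_corpus].
#' @return The corpus with canonical tokens and a `normalize` entry in the
#'   filter log.
#' @export
normalize_corpus <- function(corpus) {
  stopifnot(inherits(corpus, "coop_corpus"))
  corpus$mentions$token <- normalize_token(corpus$mentions$token)
  log_step(corpus, "normalize")
}

#' Apply a user-supplied merge map
#'
#' Synonym/translation merging is a human judgment; it enters the pipeline as
#' an explicit many-to-one map from raw token to canonical token. The map must
#' be idempotent: any canonical target that also appears as a key must map to
#' itself. Unmapped tokens pass through unchanged, so the unique-token count
#' never increases.
#'
#' @param corpus A [coop_corpus].
#' @param map Either a named character vector (`names` = raw, values =
#'   canonical) or a two-column data frame with columns `raw` and `canonical`.
#' @return The corpus with merged tokens.
#' @export
apply_merge_map <- function(corpus, map) {
  stopifnot(inherits(corpus, "coop_corpus"))
  if (is.data.frame(map)) {
    stopifnot(all(c("raw", "canonical") %in% names(map)))
    map <- setNames(as.character(map$canonical), as.character(map$raw))
  }
  if (length(map) == 0) {
    return(log_step(corpus, "merge"))
  }
  if (any(is.na(map) | map == "")) {
    abort("Merge map has empty canonical targets.", class = "coop_validation_error")
  }
  chained <- intersect(unname(map), names(map))
  if (any(map[chained] != chained)) {
    abort("Merge map is not idempotent: some canonical targets are remapped elsewhere.",
          class = "coop_validation_error")
  }
  tok <- corpus$mentions$token
  hit <- tok %in% names(map)
  tok[hit] <- unname(map[tok[hit]])
  corpus$mentions$token <- tok
  log_step(corpus, "merge")
}

#' Drop participants who chose the "other" category
#'
#' Whether these participants thought of a substance or a behavior is unknown,
#' so they cannot enter the substance/behavior contrasts and are removed
#' entirely.
#'
#' @param corpus A [coop_corpus].
#' @return The corpus without `other`-type participants.
#' @export
drop_other_category <- function(corpus) {
  stopifnot(inherits(corpus, "coop_corpus"))
  other_ids <- corpus$participants$participant_id[corpus$participants$type == "other"]
  corpus$participants <- filter(corpus$participants, .data$type != "other")
  corpus$mentions <- filter(corpus$mentions, !.data$participant_id %in% other_ids)
  if (nrow(corpus$participants) == 0) {
    warn("All participants were in the 'other' category; corpus is empty.")
  }
  log_step(corpus, "drop_other", n_removed = length(other_ids))
}

#' Remove idiosyncratic (rare) tokens
#'
#' Tokens mentioned by fewer than `min_count` distinct participants are
#' removed from every record; such terms reflect unstable, idiosyncratic parts
#' of the representation rather than shared structure. Records keep their
#' surviving tokens (arity may fall below five). The fraction of association
#' mentions retained is recorded as `coverage` in the filter log and as an
#' attribute of the result.
#'
#' @param corpus A [coop_corpus].
#' @param min_count Minimum participant count; default 10.
#' @return The filtered corpus, with attribute `coverage`.
#' @export
filter_rare_tokens <- function(corpus, min_count = 10) {
  stopifnot(inherits(corpus, "coop_corpus"), min_count >= 1)
  lex <- lexicon(corpus)
  keep <- lex$token[lex$n_participants >= min_count]
  coverage <- if (nrow(corpus$mentions)) mean(corpus$mentions$token %in% keep) else NA_real_
  n_dropped <- nrow(lex) - length(keep)
  corpus$mentions <- filter(corpus$mentions, .data$token %in% keep)
  corpus <- log_step(corpus, "filter_rare", n_removed = n_dropped, value = coverage)
  attr(corpus, "coverage") <- coverage
  corpus
}

#' Remove participants left with no analyzable associations
#'
#' After the rare-token filter some participants may retain zero tokens; they
#' cannot be linked to any module and are excluded.
#'
#' @param corpus A [coop_corpus].
#' @return The corpus without empty participants.
#' @export
drop_unclassifiable_participants <- function(corpus) {
  stopifnot(inherits(corpus, "coop_corpus"))
  with_tokens <- unique(corpus$mentions$participant_id)
  gone <- setdiff(corpus$participants$participant_id, with_tokens)
  corpus$participants <- filter(corpus$participants, .data$participant_id %in% with_tokens)
  log_step(corpus, "drop_unclassifiable", n_removed = length(gone))
}

#' Participant-level provision rate of each emotion label
#'
#' A participant "provides" a label if it appears anywhere among their ten
#' selections (two labels for each of five associations).
#'
#' @param corpus A [coop_corpus].
#' @return A tibble with columns `label`, `n_participants`, `fraction`,
#'   covering all configured labels (zero rows included).
#' @export
label_participation <- function(corpus) {
  stopifnot(inherits(corpus, "coop_corpus"))
  n <- n_participants(corpus)
  counts <- corpus$mentions %>%
    select("participant_id", "label_1", "label_2") %>%
    tidyr::pivot_longer(c("label_1", "label_2"), values_to = "label") %>%
    distinct(.data$participant_id, .data$label) %>%
    count(.data$label, name = "n_participants")
  tibble(label = corpus$labels) %>%
    left_join(counts, by = "label") %>%
    mutate(
      n_participants = tidyr::replace_na(.data$n_participants, 0L),
      fraction = if (n > 0) .data$n_participants / n else NA_real_
    ) %>%
    arrange(desc(.data$fraction), .data$label)
}

#' Keep only emotion labels provided by enough participants
#'
#' Labels provided by at least `threshold` (inclusive) of the current
#' participants are retained for all downstream emotion summaries and tests;
#' the rest are set aside. The retained set is stored on the corpus
#' (`corpus$retained_labels`).
#'
#' @param corpus A [coop_corpus].
#' @param threshold Fraction in `[0, 1]`; default 0.5.
#' @return The corpus with `retained_labels` populated.
#' @export
filter_emotion_labels <- function(corpus, threshold = 0.5) {
  stopifnot(inherits(corpus, "coop_corpus"), threshold >= 0, threshold <= 1)
  part <- label_participation(corpus)
  retained <- part$label[!is.na(part$fraction) & part$fraction >= threshold]
  corpus$retained_labels <- retained
  log_step(corpus, "filter_labels",
           n_removed = length(corpus$labels) - length(retained),
           value = length(retained))
}

#' Frequency-rank diagnostic for choosing the rare-token cutoff
#'
#' Returns tokens ordered by decreasing participant count with their rank and
#' cumulative mention coverage, the plot behind an elbow/breakpoint inspection
#' of the frequency distribution. Purely diagnostic: it never chooses a
#' threshold.
#'
#' @param corpus A [coop_corpus].
#' @return A tibble `token`, `n_participants`, `rank`, `cum_coverage`.
#' @export
frequency_rank_report <- function(corpus) {
  lex <- lexicon(corpus)
  mention_counts <- count(corpus$mentions, .data$token, name = "n_mentions")
  lex %>%
    left_join(mention_counts, by = "token") %>%
    mutate(
      rank = row_number(),
      cum_coverage = cumsum(.data$n_mentions) / sum(.data$n_mentions)
    ) %>%
    select("token", "n_participants", "rank", "cum_coverage")
}

#' Run the whole preprocessing chain
#'
#' Fixed order: normalize, merge, drop `other`-category participants, filter
#' rare tokens, drop participants left empty, filter emotion labels. Each step
#' is idempotent, and the filter log records what every step removed.
#'
#' @param corpus A [coop_corpus].
#' @param merge_map Optional merge map (see [apply_merge_map()]).
#' @param config A [pipeline_config()] supplying the thresholds.
#' @return The preprocessed corpus.
#' @export
preprocess_corpus <- function(corpus, merge_map = NULL, config = pipeline_config()) {
  corpus <- normalize_corpus(corpus)
  corpus <- apply_merge_map(corpus, merge_map %||% character())
  corpus <- drop_other_category(corpus)
  corpus <- filter_rare_tokens(corpus, config$min_token_count)
  corpus <- drop_unclassifiable_participants(corpus)
  filter_emotion_labels(corpus, config$emotion_label_threshold)
}
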