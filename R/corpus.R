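#' Free-association corpus
#'
#' A `coop_corpus` holds one survey's worth of responses in two tidy tables:
#'
#' * `mentions` — one row per (participant, association slot): columns
#'   `participant_id`, `position` (1-5), `token`, `label_1`, `label_2`.
#' * `participants` — one row per participant: `participant_id`, `category`,
#'   `type` (substance/behavior/other), `intensity` (ordinal 1-4, where
#'   1 = totally disagree ... 4 = totally agree with "I did it too much in the
#'   past 12 months").
#'
#' plus the label list, the category map, the set of retained emotion labels
#' (populated by [filter_emotion_labels()]) and a `filter_log` recording what
#' each preprocessing step removed.
#'
#' @name coop_corpus
NULL

empty_filter_log <- function() {
  tibble(
    step = character(), n_participants = integer(), n_tokens = integer(),
    n_removed = integer(), value = double()
  )
}

new_corpus <- function(mentions, participants, labels, categories,
                       retained_labels = NULL, filter_log = empty_filter_log()) {
  structure(
    list(
      mentions = as_tibble(mentions),
      participants = as_tibble(participants),
      labels = labels,
      categories = as_tibble(categories),
      retained_labels = retained_labels,
      filter_log = filter_log
    ),
    class = "coop_corpus"
  )
}

log_step <- function(corpus, step, n_removed = 0L, value = NA_real_) {
  corpus$filter_log <- bind_rows(
    corpus$filter_log,
    tibble(
      step = step,
      n_participants = nrow(corpus$participants),
      n_tokens = nrow(lexicon(corpus)),
      n_removed = as.integer(n_removed),
      value = value
    )
  )
  corpus
}

#' Canonical lexicon of a corpus
#'
#' Counts, for every token, the number of distinct participants mentioning it
#' (a participant mentioning a token twice contributes once: the participant is
#' the co-occurrence unit throughout).
#'
#' @param corpus A [coop_corpus].
#' @return A tibble with columns `token` and `n_participants`, ordered by
#'   decreasing count then token.
#' @export
lexicon <- function(corpus) {
  stopifnot(inherits(corpus, "coop_corpus"))
  corpus$mentions %>%
    distinct(.data$participant_id, .data$token) %>%
    count(.data$token, name = "n_participants") %>%
    arrange(desc(.data$n_participants), .data$token)
}

#' @export
print.coop_corpus <- function(x, ...) {
  cat("<coop_corpus>\n")
  cat("  participants:", nrow(x$participants), "\n")
  cat("  mentions:    ", nrow(x$mentions), "\n")
  cat("  tokens:      ", nrow(lexicon(x)), "unique\n")
  if (!is.null(x$retained_labels)) {
    cat("  labels kept: ", length(x$retained_labels), "of", length(x$labels), "\n")
  }
  if (nrow(x$filter_log)) {
    cat("  steps:       ", paste(x$filter_log$step, collapse = " > "), "\n")
  }
  invisible(x)
}

required_response_columns <- function() {
  c(
    "participant_id",
    paste0("assoc_", 1:5),
    as.vector(t(outer(paste0("emo_", 1:5), c("a", "b"), paste0))),
    "category", "intensity"
  )
}

#' Build a corpus from a wide response table
#'
#' The expected layout is one row per participant: `participant_id`,
#' `assoc_1`..`assoc_5`, `emo_1a`, `emo_1b`, ..., `emo_5a`, `emo_5b`,
#' `category`, `intensity`. Rows violating the record invariants (wrong
#' association or label arity, unknown labels or category, intensity outside
#' 1-4, duplicated ids) cause a validation error naming the offending
#' participants.
#'
#' @param data A data frame in the wide layout above.
#' @param config A [pipeline_config()]; supplies the label list and category
#'   map used for validation.
#' @return A [coop_corpus].
#' @export
as_corpus <- function(data, config = pipeline_config()) {
  data <- as_tibble(data)
  missing_cols <- setdiff(required_response_columns(), names(data))
  if (length(missing_cols)) {
    abort(
      paste0("Response table is missing columns: ", paste(missing_cols, collapse = ", ")),
      class = "coop_format_error"
    )
  }
  data$participant_id <- as.character(data$participant_id)

  problems <- character()
  flag <- function(bad, what) {
    if (any(bad)) {
      ids <- unique(data$participant_id[bad])
      problems <<- c(problems, paste0(
        what, ": ", paste(head(ids, 10), collapse = ", "),
        if (length(ids) > 10) sprintf(" (+%d more)", length(ids) - 10) else ""
      ))
    }
  }

  flag(duplicated(data$participant_id), "duplicated participant_id")

  assoc <- as.matrix(data[paste0("assoc_", 1:5)])
  assoc[] <- stringr::str_trim(ifelse(is.na(assoc), "", as.character(assoc)))
  flag(rowSums(assoc == "") > 0, "fewer than 5 associations")

  emo_cols <- as.vector(t(outer(paste0("emo_", 1:5), c("a", "b"), paste0)))
  emo <- as.matrix(data[emo_cols])
  emo[] <- stringr::str_trim(as.character(emo))
  flag(rowSums(is.na(emo) | emo == "") > 0, "missing emotion labels")
  bad_label <- !is.na(emo) & emo != "" & !matrix(emo %in% config$labels, nrow = nrow(data))
  flag(rowSums(bad_label) > 0, "emotion label not in configured list")
  same <- vapply(1:5, function(k) {
    emo[, paste0("emo_", k, "a")] == emo[, paste0("emo_", k, "b")]
  }, logical(nrow(data)))
  if (is.null(dim(same))) same <- matrix(same, nrow = nrow(data))
  flag(rowSums(same, na.rm = TRUE) > 0, "emotion labels for an association not distinct")

  flag(!(data$category %in% config$categories$category), "unknown category")
  flag(!(data$intensity %in% 1:4), "intensity outside 1-4")

  if (length(problems)) {
    abort(
      paste0("Invalid response rows:\n  ", paste(problems, collapse = "\n  ")),
      class = "coop_validation_error"
    )
  }

  mentions <- purrr::map_dfr(1:5, function(k) {
    tibble(
      participant_id = data$participant_id,
      position = k,
      token = assoc[, paste0("assoc_", k)],
      label_1 = emo[, paste0("emo_", k, "a")],
      label_2 = emo[, paste0("emo_", k, "b")]
    )
  }) %>%
    arrange(.data$participant_id, .data$position)

  participants <- data %>%
    select("participant_id", "category", "intensity") %>%
    mutate(intensity = as.integer(.data$intensity)) %>%
    left_join(config$categories, by = "category")

  new_corpus(mentions, participants, config$labels, config$categories)
}

#' Read and write response tables
#'
#' `read_responses()` reads a UTF-8 delimited file (comma by default, tab if
#' the extension is `.tsv`) in the wide one-row-per-participant layout and
#' validates it into a corpus; `write_responses()` is its inverse.
#'
#' @param path File path.
#' @param config A [pipeline_config()].
#' @param delim Field delimiter; guessed from the extension when `NULL`.
#' @return `read_responses()` returns a [coop_corpus]; `write_responses()`
#'   returns `path` invisibly.
#' @export
read_responses <- function(path, config = pipeline_config(), delim = NULL) {
  if (!file.exists(path)) {
    abort(paste0("No such file: ", path), class = "coop_format_error")
  }
  delim <- delim %||% if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  data <- readr::read_delim(
    path, delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  data$intensity <- suppressWarnings(as.integer(data$intensity))
  as_corpus(data, config)
}

#' @rdname read_responses
#' @param corpus A [coop_corpus].
#' @export
write_responses <- function(corpus, path) {
  stopifnot(inherits(corpus, "coop_corpus"))
  wide <- corpus$mentions %>%
    tidyr::pivot_wider(
      id_cols = "participant_id",
      names_from = "position",
      values_from = c("token", "label_1", "label_2"),
      names_glue = "{.value}_{position}"
    )
  # rename to the canonical header
  for (k in 1:5) {
    names(wide)[names(wide) == paste0("token_", k)] <- paste0("assoc_", k)
    names(wide)[names(wide) == paste0("label_1_", k)] <- paste0("emo_", k, "a")
    names(wide)[names(wide) == paste0("label_2_", k)] <- paste0("emo_", k, "b")
  }
  wide <- wide %>%
    left_join(
      corpus$participants %>% select("participant_id", "category", "intensity"),
      by = "participant_id"
    ) %>%
    select(all_of(intersect(required_response_columns(), names(.))))
  readr::write_csv(wide, path, progress = FALSE)
  invisible(path)
}

#' Number of participants in a corpus
#' @param corpus A [coop_corpus].
#' @return Integer count.
#' @export
n_participants <- function(corpus) {
  stopifnot(inherits(corpus, "coop_corpus"))
  nrow(corpus$participants)
}
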