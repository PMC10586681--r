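#' The 20 emotion labels offered with every association
#'
#' Participants attach exactly two labels from a fixed 20-item positive and
#' negative affect list to each of their five associations. The list used here
#' covers ten positive and ten negative affect terms (including the six that
#' typically dominate: worries, shame, anxiety, contempt, joy, calmness); a
#' different 20-item list can be passed anywhere a `labels` argument appears.
#'
#' @return Character vector of 20 labels.
#' @export
panas_labels <- function() {
  c(
    # positive affect
    "joy", "calmness", "enthusiasm", "interest", "pride",
    "determination", "inspiration", "strength", "activity", "attentiveness",
    # negative affect
    "worries", "shame", "anxiety", "contempt", "guilt",
    "distress", "irritability", "fear", "nervousness", "hostility"
  )
}

#' Default label-to-valence map
#'
#' @param labels Character vector of emotion labels. For the default list the
#'   first ten are positive and the last ten negative; for a custom list a
#'   two-column data frame (`label`, `valence`) must be supplied explicitly
#'   wherever a valence map is needed.
#' @return A tibble with columns `label` and `valence`
#'   (`"positive"`/`"negative"`).
#' @export
default_valence <- function(labels = panas_labels()) {
  if (!identical(labels, panas_labels())) {
    abort("default_valence() only knows the built-in label list; supply a custom valence map.",
          class = "coop_config_error")
  }
  tibble(
    label = labels,
    valence = rep(c("positive", "negative"), each = 10)
  )
}

#' Default substance/behavior category list
#'
#' Four psychoactive substance categories, ten potentially addictive behavior
#' categories, and an `"other"` escape option that is excluded from analysis.
#'
#' @return A tibble with columns `category` and `type`
#'   (`"substance"`, `"behavior"` or `"other"`).
#' @export
default_categories <- function() {
  tibble(
    category = c(
      "alcohol", "tobacco", "cannabis", "other_substance",
      "social_media", "internet", "tv_series", "eating", "work",
      "pornography", "shopping", "gaming", "sex", "gambling",
      "other"
    ),
    type = c(rep("substance", 4), rep("behavior", 10), "other")
  )
}

#' Pipeline configuration
#'
#' Bundles the tunable thresholds of the preprocessing and clustering chain.
#'
#' @param min_token_count Minimum number of distinct participants that must
#'   mention a token for it to be kept (idiosyncratic-association filter).
#'   Default 10.
#' @param emotion_label_threshold Fraction of retained participants that must
#'   provide a label (anywhere among their ten selections) for the label to be
#'   analyzed. Inclusive (`>=`). Default 0.5.
#' @param consensus_runs Number of Louvain restarts feeding the consensus
#'   co-classification matrix. Default 100.
#' @param consensus_threshold Co-classification fraction below which a pair is
#'   disconnected in the consensus graph. Default 0.4.
#' @param seed Integer seed used for every stochastic step of a pipeline run.
#' @param labels The emotion label list (length 20 by convention, any length
#'   accepted).
#' @param categories Category-to-type map, see [default_categories()].
#' @param valence Label-to-valence map, see [default_valence()].
#' @return An object of class `coop_config` (a validated list).
#' @export
pipeline_config <- function(min_token_count = 10,
                            emotion_label_threshold = 0.5,
                            consensus_runs = 100,
                            consensus_threshold = 0.4,
                            seed = 1L,
                            labels = panas_labels(),
                            categories = default_categories(),
                            valence = NULL) {
  valence <- valence %||% if (identical(labels, panas_labels())) {
    default_valence(labels)
  } else {
    tibble(label = labels, valence = NA_character_)
  }
  if (!is.numeric(min_token_count) || min_token_count < 1) {
    abort("`min_token_count` must be >= 1.", class = "coop_config_error")
  }
  if (emotion_label_threshold < 0 || emotion_label_threshold > 1) {
    abort("`emotion_label_threshold` must lie in [0, 1].", class = "coop_config_error")
  }
  if (!is.numeric(consensus_runs) || consensus_runs < 2) {
    abort("`consensus_runs` must be >= 2.", class = "coop_config_error")
  }
  if (consensus_threshold <= 0 || consensus_threshold >= 1) {
    abort("`consensus_threshold` must lie in (0, 1).", class = "coop_config_error")
  }
  stopifnot(is.character(labels), !anyDuplicated(labels))
  stopifnot(all(c("category", "type") %in% names(categories)))
  stopifnot(all(c("label", "valence") %in% names(valence)))
  structure(
    list(
      min_token_count = as.integer(min_token_count),
      emotion_label_threshold = emotion_label_threshold,
      consensus_runs = as.integer(consensus_runs),
      consensus_threshold = consensus_threshold,
      seed = as.integer(seed),
      labels = labels,
      categories = as_tibble(categories),
      valence = as_tibble(valence)
    ),
    class = "coop_config"
  )
}

#' @export
print.coop_config <- function(x, ...) {
  cat("<coop_config>\n")
  cat("  min_token_count:        ", x$min_token_count, "\n")
  cat("  emotion_label_threshold:", x$emotion_label_threshold, "\n")
  cat("  consensus_runs:         ", x$consensus_runs, "\n")
  cat("  consensus_threshold:    ", x$consensus_threshold, "\n")
  cat("  seed:                   ", x$seed, "\n")
  cat("  labels:                 ", length(x$labels), "emotion labels\n")
  cat("  categories:             ", nrow(x$categories), "categories\n")
  invisible(x)
}

#' Read / write a pipeline configuration as YAML
#'
#' Only scalar fields and the label list are serialized; category and valence
#' tables are stored as named lists.
#'
#' @param config A [pipeline_config()] object.
#' @param path File path.
#' @return `write_config()` returns `path` invisibly; `read_config()` returns a
#'   `coop_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "coop_config"))
  out <- list(
    min_token_count = config$min_token_count,
    emotion_label_threshold = config$emotion_label_threshold,
    consensus_runs = config$consensus_runs,
    consensus_threshold = config$consensus_threshold,
    seed = config$seed,
    labels = config$labels,
    categories = as.list(setNames(config$categories$type, config$categories$category)),
    valence = as.list(setNames(config$valence$valence, config$valence$label))
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pipeline_config(
    min_token_count = raw$min_token_count,
    emotion_label_threshold = raw$emotion_label_threshold,
    consensus_runs = raw$consensus_runs,
    consensus_threshold = raw$consensus_threshold,
    seed = raw$seed,
    labels = unlist(raw$labels),
    categories = tibble(
      category = names(raw$categories),
      type = unname(unlist(raw$categories))
    ),
    valence = tibble(
      label = names(raw$valence),
      valence = unname(unlist(raw$valence))
    )
  )
}

# config hash used in log lines so a run is reproducible from its log
config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(unclass(config))), collapse = "")
  # small rolling hash; no digest dependency
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}
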