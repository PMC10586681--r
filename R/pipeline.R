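#' Run the full association-network pipeline
#'
#' Preprocess, build the signed co-occurrence network, consensus-cluster it,
#' link participants to modules, profile the modules and run the inference
#' layer — the whole chain behind a single call. When `output_dir` is given,
#' every intermediate artifact is written there: the filtered corpus
#' (`corpus.csv`), the filter report (`filter_report.json`), the network
#' (`network.graphml`, `network.edges.tsv`, `network.nodes.tsv`,
#' `network_summary.json`), the partition (`partition.json`), the consensus
#' co-classification matrix (`consensus_matrix.csv`), the module profiles
#' (`profiles.json`, `profiles.csv`, `emotions.csv`) and the statistical
#' report (`stats.json`, `dunn_pairwise.csv`).
#'
#' @param x A [coop_corpus], a `coop_simulation`, or a path to a response
#'   file.
#' @param config A [pipeline_config()]. Its `seed` drives all stochastic
#'   steps.
#' @param merge_map Optional merge map, see [apply_merge_map()].
#' @param output_dir Optional directory for file outputs.
#' @param preprocess Set `FALSE` to skip the preprocessing chain (e.g. for
#'   benchmark corpora that should enter the network stage unfiltered;
#'   emotion labels are then all retained).
#' @return A list of class `coop_result` with elements `corpus`, `network`,
#'   `consensus`, `partition`, `assignments`, `profiles`, `emotions`,
#'   `chisq`, `rank_tests`, `config` and (for simulations) `recovery`.
#' @export
run_coop_pipeline <- function(x, config = pipeline_config(), merge_map = NULL,
                              output_dir = NULL, preprocess = TRUE) {
  truth <- NULL
  if (inherits(x, "coop_simulation")) {
    truth <- x
    corpus <- x$corpus
  } else if (inherits(x, "coop_corpus")) {
    corpus <- x
  } else if (is.character(x) && length(x) == 1) {
    corpus <- read_responses(x, config)
  } else {
    abort("`x` must be a corpus, a simulation, or a response file path.",
          class = "coop_format_error")
  }
  message(sprintf(
    "coopnet run: seed=%d config=%s", config$seed, config_hash(config)
  ))

  if (preprocess) {
    corpus <- preprocess_corpus(corpus, merge_map, config)
  } else if (is.null(corpus$retained_labels)) {
    corpus$retained_labels <- corpus$labels
  }

  network <- build_network(corpus)
  consensus <- consensus_cluster(
    network,
    runs = config$consensus_runs,
    threshold = config$consensus_threshold,
    seed = config$seed
  )
  partition <- consensus$final_partition
  assignments <- assign_participants(corpus, partition)
  profiles <- module_summary(corpus, partition, assignments,
                             valence = config$valence)
  emotions <- emotion_distribution(corpus, partition)
  chisq <- tryCatch(mr_chisq_tests(assignments),
                    coop_degenerate_error = function(e) NULL)
  rank_tests <- emotion_rank_tests(corpus, assignments, group = "module")

  result <- structure(
    list(
      corpus = corpus, network = network, consensus = consensus,
      partition = partition, assignments = assignments,
      profiles = profiles, emotions = emotions,
      chisq = chisq, rank_tests = rank_tests, config = config,
      recovery = if (!is.null(truth)) {
        score_recovery(truth, partition, assignments)
      }
    ),
    class = "coop_result"
  )
  if (!is.null(output_dir)) {
    write_pipeline_outputs(result, output_dir)
  }
  result
}

#' @export
print.coop_result <- function(x, ...) {
  cat("<coop_result>\n")
  cat("  participants:", n_participants(x$corpus),
      " tokens:", nrow(x$network$nodes),
      " modules:", n_modules(x$partition), "\n")
  cat("  modularity:  ", format(x$consensus$modularity, digits = 4),
      if (x$consensus$converged) "(consensus converged)" else "(consensus NOT converged)",
      "\n")
  if (!is.null(x$recovery) && !is.na(x$recovery$token_ari)) {
    cat("  token ARI vs planted truth:", round(x$recovery$token_ari, 3), "\n")
  }
  invisible(x)
}

write_pipeline_outputs <- function(result, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(output_dir, ...)

  write_responses(result$corpus, fp("corpus.csv"))
  jsonlite::write_json(result$corpus$filter_log, fp("filter_report.json"),
                       digits = NA)
  write_network(result$network, fp("network"), result$partition)
  jsonlite::write_json(as.list(glance(result$network)),
                       fp("network_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  write_partition(result$partition, fp("partition.json"))
  readr::write_csv(
    as_tibble(result$consensus$co_classification, rownames = "token"),
    fp("consensus_matrix.csv"), progress = FALSE
  )
  jsonlite::write_json(
    result$profiles %>% select(-"top_tokens"),
    fp("profiles.json"), digits = NA
  )
  readr::write_csv(result$profiles %>% select(-"top_tokens"),
                   fp("profiles.csv"), progress = FALSE)
  readr::write_csv(result$emotions, fp("emotions.csv"), progress = FALSE)

  stats_out <- list(
    chisq = lapply(result$chisq, function(ct) {
      list(
        statistic = ct$statistic, df = ct$df, n = ct$n, p_value = ct$p_value,
        observed = ct$observed, residuals = ct$residuals
      )
    }),
    rank_tests = result$rank_tests %>% select(-"dunn")
  )
  jsonlite::write_json(stats_out, fp("stats.json"), auto_unbox = TRUE, digits = NA)
  readr::write_csv(
    result$rank_tests %>%
      select("label", "dunn") %>%
      tidyr::unnest("dunn"),
    fp("dunn_pairwise.csv"), progress = FALSE
  )
  invisible(output_dir)
}
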