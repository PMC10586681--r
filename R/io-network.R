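#' Export a signed network (GraphML + edge list)
#'
#' Writes `<path>.graphml` (nodes carry `token`, `frequency` and, when a
#' partition is given, `module`; edges carry the signed `weight`) for Gephi
#' and friends, and `<path>.edges.tsv`, a plain weighted edge list with
#' weights printed at full double precision so that [read_network()]
#' reproduces the network exactly.
#'
#' @param net A `coop_network`.
#' @param path Output path prefix (no extension).
#' @param partition Optional `coop_partition`; must cover all nodes.
#' @return The two file paths, invisibly.
#' @export
write_network <- function(net, path, partition = NULL) {
  stopifnot(inherits(net, "coop_network"))
  vertices <- tibble(
    name = net$nodes$token,
    frequency = as.integer(net$nodes$n_participants)
  )
  if (!is.null(partition)) {
    p <- as_tibble(partition)
    if (!all(net$nodes$token %in% p$token)) {
      abort("Partition does not cover all network nodes.",
            class = "coop_consistency_error")
    }
    vertices$module <- as.integer(p$module[match(vertices$name, p$token)])
  }
  g <- igraph::graph_from_data_frame(
    net$edges, directed = FALSE, vertices = vertices
  )
  graphml <- paste0(path, ".graphml")
  igraph::write_graph(g, graphml, format = "graphml")

  edges <- paste0(path, ".edges.tsv")
  df <- net$edges
  lines <- c(
    "from\tto\tweight",
    sprintf("%s\t%s\t%.17g", df$from, df$to, df$weight)
  )
  writeLines(lines, edges)
  # node list rides along in the edge file header comment-free via a sidecar
  readr::write_tsv(
    tibble(
      token = net$nodes$token,
      frequency = net$nodes$n_participants,
      n_participants_total = net$n_participants
    ),
    paste0(path, ".nodes.tsv"), progress = FALSE
  )
  invisible(c(graphml = graphml, edges = edges))
}

#' Read back a network written by [write_network()]
#'
#' Reconstructs the `coop_network` from the `.nodes.tsv` / `.edges.tsv` pair
#' (exact weights); the GraphML file is for external tools.
#'
#' @param path The path prefix used in [write_network()].
#' @return A `coop_network`.
#' @export
read_network <- function(path) {
  nodes <- readr::read_tsv(paste0(path, ".nodes.tsv"),
                           show_col_types = FALSE, progress = FALSE)
  ef <- readLines(paste0(path, ".edges.tsv"))
  if (length(ef) > 1) {
    parts <- strsplit(ef[-1], "\t", fixed = TRUE)
    edges <- tibble(
      from = vapply(parts, `[[`, "", 1),
      to = vapply(parts, `[[`, "", 2),
      weight = as.numeric(vapply(parts, `[[`, "", 3))
    )
  } else {
    edges <- tibble(from = character(), to = character(), weight = double())
  }
  structure(
    list(
      nodes = tibble(
        token = as.character(nodes$token),
        n_participants = as.integer(nodes$frequency)
      ),
      edges = edges,
      n_participants = as.integer(nodes$n_participants_total[1])
    ),
    class = "coop_network"
  )
}

#' Write / read a partition as JSON
#'
#' @param partition A `coop_partition`.
#' @param path File path.
#' @return `write_partition()` returns `path` invisibly; `read_partition()`
#'   returns a `coop_partition`.
#' @export
write_partition <- function(partition, path) {
  p <- as_tibble(partition)
  jsonlite::write_json(
    list(
      modules = setNames(as.list(as.integer(p$module)), p$token),
      modularity = attr(partition, "modularity"),
      seed = attr(partition, "seed")
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  raw <- jsonlite::read_json(path)
  new_partition(
    tokens = names(raw$modules),
    membership = as.integer(unlist(raw$modules)),
    modularity = raw$modularity %||% NA_real_,
    seed = raw$seed
  )
}
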