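#' Tidiers for coopnet objects
#'
#' broom-style [tidy()] and [glance()] methods. `tidy()` returns the
#' object's natural per-unit table (nodes/edges/cells/pairs); `glance()` a
#' one-row summary.
#'
#' @param x A coopnet object.
#' @param ... Unused.
#' @name coopnet-tidiers
NULL

#' @rdname coopnet-tidiers
#' @export
tidy.coop_network <- function(x, ...) {
  x$edges %>%
    mutate(sign = ifelse(.data$weight > 0, "attractive", "repulsive")) %>%
    arrange(desc(abs(.data$weight)))
}

#' @rdname coopnet-tidiers
#' @export
glance.coop_network <- function(x, ...) {
  tot <- network_totals(x)
  tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_attractive = sum(x$edges$weight > 0),
    n_repulsive = sum(x$edges$weight < 0),
    v_pos = tot$v_pos,
    v_neg = tot$v_neg,
    n_participants = x$n_participants
  )
}

#' @rdname coopnet-tidiers
#' @export
tidy.coop_partition <- function(x, ...) {
  tibble(token = x$token, module = x$module)
}

#' @rdname coopnet-tidiers
#' @export
glance.coop_partition <- function(x, ...) {
  tibble(
    n_nodes = nrow(x),
    n_modules = n_modules(x),
    modularity = attr(x, "modularity") %||% NA_real_
  )
}

#' @rdname coopnet-tidiers
#' @export
tidy.coop_consensus <- function(x, ...) {
  tidy(x$final_partition)
}

#' @rdname coopnet-tidiers
#' @export
glance.coop_consensus <- function(x, ...) {
  tibble(
    n_modules = n_modules(x$final_partition),
    modularity = x$modularity,
    runs = x$runs,
    threshold = x$threshold,
    iterations = x$iterations,
    converged = x$converged
  )
}

#' @rdname coopnet-tidiers
#' @export
tidy.coop_chisq <- function(x, ...) {
  as.data.frame(as.table(x$observed)) %>%
    setNames(c("row", "col", "observed")) %>%
    as_tibble() %>%
    mutate(
      expected = as.vector(x$expected),
      residual = as.vector(x$residuals)
    )
}

#' @rdname coopnet-tidiers
#' @export
glance.coop_chisq <- function(x, ...) {
  tibble(
    statistic = x$statistic, df = x$df, p_value = x$p_value, n = x$n
  )
}

#' @rdname coopnet-tidiers
#' @export
tidy.coop_kruskal <- function(x, ...) {
  tibble(
    h = x$h, df = x$df, p_value = x$p_value,
    n_groups = length(x$group_sizes),
    n = sum(x$group_sizes),
    degenerate = x$degenerate
  )
}

#' @rdname coopnet-tidiers
#' @export
glance.coop_kruskal <- tidy.coop_kruskal
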