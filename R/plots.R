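#' Plot the module emotion profiles
#'
#' Bar panels of the relative emotion-label distribution per module.
#'
#' @param emdist Output of [emotion_distribution()].
#' @return A ggplot object.
#' @export
plot_emotion_profile <- function(emdist) {
  ggplot2::ggplot(
    emdist,
    ggplot2::aes(
      x = stats::reorder(.data$label, .data$pct),
      y = .data$pct, fill = factor(.data$module)
    )
  ) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~module, labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "share of labels (%)") +
    ggplot2::theme_minimal()
}

#' Heatmap of the consensus co-classification matrix
#'
#' Nodes ordered by final module; block structure shows how stable the
#' partition is across Louvain runs.
#'
#' @param object A `coop_consensus`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coop_consensus <- function(object, ...) {
  ord <- order(object$final_partition$module)
  tokens <- object$final_partition$token[ord]
  df <- as.data.frame(as.table(object$co_classification[tokens, tokens])) %>%
    setNames(c("token_i", "token_j", "fraction"))
  ggplot2::ggplot(df, ggplot2::aes(.data$token_i, .data$token_j,
                                   fill = .data$fraction)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue4",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "co-classified") +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, hjust = 1, size = 6),
      axis.text.y = ggplot2::element_text(size = 6)
    )
}

#' Residual tile plot of a contingency test
#'
#' Colors show the standardized residuals, i.e. how far each observed cell
#' deviates from the independence expectation.
#'
#' @param object A `coop_chisq`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coop_chisq <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$residual)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%d\n(%.1f)", .data$observed, .data$expected)
    ), size = 3) +
    ggplot2::scale_fill_gradient2(low = "steelblue4", mid = "white",
                                  high = "firebrick3") +
    ggplot2::labs(x = NULL, y = NULL, fill = "std. residual") +
    ggplot2::theme_minimal()
}
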