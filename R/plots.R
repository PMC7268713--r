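#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Loading plot for a Q solution
#'
#' Tile map of rotated loadings (participants x factors) with flagged
#' exemplar cells outlined.
#'
#' @param object A `q_solution`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.q_solution <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$factor, y = .data$participant_id,
                                   fill = .data$loading)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = df[df$flagged, ], fill = NA,
                       colour = "black", linewidth = 0.6) +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "loading",
                  title = "Rotated loadings (flagged exemplars outlined)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 6))
}

#' Plot factor arrays as a rank heat map
#'
#' @param arrays Tibble `statement_id` + integer factor columns (e.g.
#'   `solution$arrays` or `q_study()$factor_arrays`).
#' @param statements Optional tibble `statement_id`, `text` for labels.
#' @return A ggplot.
#' @export
plot_factor_arrays <- function(arrays, statements = NULL) {
  long <- tidyr::pivot_longer(arrays, -"statement_id",
                              names_to = "factor", values_to = "rank")
  if (!is.null(statements)) {
    long <- dplyr::left_join(long, statements, by = "statement_id")
    long$label <- paste0(long$statement_id, ". ",
                         substr(long$text, 1, 40))
  } else {
    long$label <- as.character(long$statement_id)
  }
  long$label <- stats::reorder(long$label, -long$statement_id)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$factor, y = .data$label,
                                     fill = .data$rank)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$rank), size = 2.6) +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac") +
    ggplot2::labs(x = NULL, y = NULL, fill = "rank",
                  title = "Factor arrays") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 6),
                   legend.position = "none")
}
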