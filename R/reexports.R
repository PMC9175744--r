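#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.srwr_scores <- function(object, top_n = 30, ...) {
  df <- dplyr::slice_max(object, order_by = abs(.data$r), n = top_n,
                         with_ties = FALSE)
  df$node <- stats::reorder(df$node, df$r)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r, y = .data$node,
                                   fill = .data$r < 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "steelblue",
                                          `FALSE` = "firebrick")) +
    ggplot2::labs(x = "activation score r = p - n", y = NULL,
                  title = sprintf("strongest %d propagated effects", top_n)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cluster_assignment <- function(object, ...) {
  hc <- attr(object, "hclust")
  ord <- hc$labels[hc$order]
  df <- dplyr::mutate(tibble::as_tibble(object),
                      drug = factor(.data$drug, levels = ord))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$drug, y = 1,
                                   fill = factor(.data$cluster))) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = NULL, y = NULL, fill = "cluster") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
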