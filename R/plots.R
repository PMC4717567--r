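#' Plot a host-range incidence matrix
#'
#' Tile map of the binary parasitoid x host-taxon table: filled tiles mark
#' at least one rearing record.
#'
#' @param inc an incidence matrix from [collapse_incidence()].
#' @return a ggplot object.
#' @export
plot_incidence <- function(inc) {
  df <- as_tibble(as.data.frame(as.table(unclass(inc))))
  names(df) <- c("parasitoid", "taxon", "present")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$taxon, y = .data$parasitoid,
                                   fill = factor(.data$present))) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = c(`0` = "grey92", `1` = "grey20"),
                               guide = "none") +
    ggplot2::labs(x = paste0("host taxon (", attr(inc, "level") %||% "host",
                             ")"),
                  y = "parasitoid species") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}

#' @describeIn run_comparative_analysis dot-and-error overview of every
#'   Mantel test in a report: the observed r per comparison and level, solid
#'   points where p < 0.05.
#' @param object an `analysis_report`.
#' @param ... unused.
#' @method autoplot analysis_report
#' @export
autoplot.analysis_report <- function(object, ...) {
  df <- object$mantel
  if (is.null(df) || nrow(df) == 0) abort("report contains no Mantel results.")
  df <- mutate(df, significant = .data$p_value < 0.05,
               label = paste0(.data$comparison, " [", .data$level, "]"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r, y = .data$label,
                                   shape = .data$significant)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 1, `TRUE` = 16),
                                name = "p < 0.05") +
    ggplot2::labs(x = "Mantel r", y = NULL,
                  title = "Matrix correlations (simple and partial Mantel tests)")
}
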