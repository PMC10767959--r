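# ggplot2 displays for the three result types.

#' @method autoplot hc_summary
#' @export
autoplot.hc_summary <- function(object, ...) {
  tb <- tidy(object)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$combo, y = .data$n, fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~source) +
    ggplot2::labs(x = "mark combination", y = "regions",
                  title = "Heterochromatin regions by recognition class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @method autoplot hc_report
#' @export
autoplot.hc_report <- function(object, ...) {
  tb <- tidy(object)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$source, y = .data$n, fill = .data$class)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "regions (log10)",
                  title = "Region counts by source and recognition class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @method autoplot dfrap_tbl
#' @export
autoplot.dfrap_tbl <- function(object, ...) {
  tb <- tidy(object)
  tb <- tb[tb$overlaps_control, ]
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$p_value, fill = factor(.data$F))) +
    ggplot2::geom_histogram(breaks = seq(0, 1, by = 0.05), boundary = 0) +
    ggplot2::scale_fill_manual(values = c(`0` = "grey70", `1` = "firebrick"),
                               name = "F") +
    ggplot2::labs(x = "exact-test p-value (overlapping case regions)",
                  y = "regions",
                  title = "Differential heterochromatin region p-values") +
    ggplot2::theme_minimal()
}

#' @method autoplot enrich_tbl
#' @export
autoplot.enrich_tbl <- function(object, top_n = 20, ...) {
  tb <- head(tidy(object), top_n)
  tb$set_id <- factor(tb$set_id, levels = rev(tb$set_id))
  ggplot2::ggplot(tb, ggplot2::aes(x = -log10(.data$p_value), y = .data$set_id,
                                   size = .data$overlap_count,
                                   colour = .data$fdr)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "-log10 p", y = NULL, title = "Gene-set over-representation") +
    ggplot2::theme_minimal()
}
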