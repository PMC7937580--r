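#' Correlogram heatmap
#'
#' Renders a [build_correlogram()] table as a heatmap per modality:
#' thresholds on the x axis, PFT metrics on the y axis, fill colour the
#' Pearson r. Undefined cells (too few patients or constant input) are shown
#' as crossed-out blanks.
#'
#' @param object A `correlogram` tibble.
#' @param ... Unused.
#' @return A ggplot object, deterministic given the table.
#' @method autoplot correlogram
#' @export
autoplot.correlogram <- function(object, ...) {
  df <- dplyr::mutate(
    object,
    threshold_pct = factor(round(100 * .data$threshold)),
    pft_metric = factor(.data$pft_metric, levels = rev(pft_metrics)))
  und <- dplyr::filter(df, is.na(.data$r))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold_pct,
                                        y = .data$pft_metric)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$r), colour = "white") +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$r), "", sprintf("%.2f", .data$r))),
      size = 2.6) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0,
                                  limits = c(-1, 1), na.value = "grey90") +
    ggplot2::facet_wrap(~modality, ncol = 1) +
    ggplot2::labs(x = "Threshold (% of converged peak intensity)",
                  y = NULL, fill = "Pearson r",
                  title = "Functional volume vs PFT correlogram") +
    ggplot2::theme_minimal()
  if (nrow(und) > 0) {
    p <- p + ggplot2::geom_point(data = und, shape = 4, size = 3,
                                 colour = "grey40")
  }
  p
}

#' Write a correlogram heatmap to disk
#'
#' @param table A `correlogram` tibble from [build_correlogram()].
#' @param out Output image path (`.png`, `.pdf`, or `.svg`).
#' @param width,height Plot size in inches.
#' @return Invisibly, `out`.
#' @export
plot_correlogram <- function(table, out, width = 8, height = 7) {
  if (nrow(table) == 0L) {
    stop("correlogram table is empty", call. = FALSE)
  }
  if (all(is.na(table$r))) {
    stop("correlogram has no defined cells to plot", call. = FALSE)
  }
  p <- autoplot.correlogram(table)
  ggplot2::ggsave(out, p, width = width, height = height, dpi = 150)
  invisible(out)
}
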