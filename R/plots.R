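# Plotting ----------------------------------------------------------------

#' Spaghetti plot of raw vs BLUP-predicted gene trajectories
#'
#' One line per gene (median over patients), raw expression on the left
#' facet and the smoother mixed-model predictions on the right; colours show
#' trend membership when a partition is supplied.
#'
#' @param pred a prediction tibble from [blup_predict()].
#' @param partition optional `tcgsa_trend_partition` for colouring.
#' @param title plot title.
#' @return A ggplot object.
#' @export
plot_set_trends <- function(pred, partition = NULL, title = NULL) {
  med <- pred |>
    dplyr::group_by(.data$gene, .data$time) |>
    dplyr::summarise(raw = median(.data$observed),
                     predicted = median(.data$fitted), .groups = "drop") |>
    tidyr::pivot_longer(c("raw", "predicted"), names_to = "panel",
                        values_to = "value") |>
    dplyr::mutate(panel = factor(.data$panel, levels = c("raw", "predicted")))
  if (!is.null(partition)) {
    med$trend <- factor(partition$labels[med$gene])
  } else {
    med$trend <- factor(1)
  }
  ggplot2::ggplot(med, ggplot2::aes(x = .data$time, y = .data$value,
                                    group = .data$gene,
                                    colour = .data$trend)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::facet_wrap(~panel) +
    ggplot2::labs(x = "time", y = "median expression over patients",
                  title = title, colour = "trend") +
    ggplot2::theme_minimal()
}

#' Heatmap of trend dynamics across significant gene sets
#'
#' @param x a `tcgsa_heatmap` from [heatmap_table()].
#' @param ... unused.
#' @return A ggplot object (tile heatmap, one row per trend, one column per
#'   time, diverging colour scale on the unit-variance trend medians).
#' @method autoplot tcgsa_heatmap
#' @export
autoplot.tcgsa_heatmap <- function(x, ...) {
  if (nrow(x$matrix) == 0) {
    stop_tcgsa("empty heatmap: no significant gene sets")
  }
  df <- tibble::as_tibble(x$matrix, rownames = "row") |>
    tidyr::pivot_longer(-"row", names_to = "time", values_to = "value") |>
    dplyr::mutate(time = as.numeric(.data$time),
                  row = factor(.data$row, levels = rev(rownames(x$matrix))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", midpoint = 0) +
    ggplot2::labs(x = "time", y = NULL, fill = "standardised\ntrend median") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 6))
}

#' @export
plot.tcgsa_heatmap <- function(x, ...) print(autoplot.tcgsa_heatmap(x, ...))

#' Volcano-style overview of a gene set analysis
#'
#' @param x a `tcgsa_result`.
#' @param ... unused.
#' @return A ggplot of LR (x) against -log10 adjusted p (y).
#' @method autoplot tcgsa_result
#' @export
autoplot.tcgsa_result <- function(x, ...) {
  tab <- dplyr::filter(x$table, !is.na(.data$p_adj))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$LR,
                                    y = -log10(pmax(.data$p_adj, 1e-300)),
                                    colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "likelihood ratio", y = "-log10 adjusted p",
                  colour = "significant") +
    ggplot2::theme_minimal()
}
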