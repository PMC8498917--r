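#' Ranked dynamic-range plot
#'
#' log10 of each experiment's values against abundance rank, one line per
#' experiment — the standard picture of a label-free screen spanning several
#' orders of magnitude.
#'
#' @param quant long quantification tibble with positive values.
#' @param value value column.
#' @return A ggplot object.
#' @export
plot_dynamic_range <- function(quant, value = "fot") {
  df <- quant |>
    group_by(.data$experiment_id) |>
    arrange(desc(.data[[value]]), .by_group = TRUE) |>
    mutate(rank = row_number(), log10_value = log10(.data[[value]])) |>
    ungroup()
  ggplot(df, aes(x = .data$rank, y = .data$log10_value,
                 group = .data$experiment_id)) +
    geom_line(alpha = 0.4) +
    labs(x = "abundance rank", y = expression(log[10] ~ FOT)) +
    theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot restricted-binding call counts per module and context
#'
#' @param object a `dmr_calls` tibble.
#' @param ... unused.
#' @return A ggplot bar chart: calls per modification module, faceted by
#'   context.
#' @export
autoplot.dmr_calls <- function(object, ...) {
  df <- filter(as_tibble(object), !is.na(.data$called_bait))
  baits <- attr(object, "baits") %||% unique(df$called_bait)
  df$called_bait <- factor(df$called_bait, levels = baits)
  ggplot(df, aes(x = .data$called_bait, fill = .data$called_bait)) +
    geom_bar(show.legend = FALSE) +
    facet_wrap(~context) +
    labs(x = "called modification", y = "restricted binders") +
    theme_minimal()
}

#' Ordination scatter plot
#'
#' @param object a `modbind_ord` tibble from [ordinate()].
#' @param ... unused.
#' @return A ggplot scatter of PC1 vs PC2, colored by context and shaped by
#'   bait when those design columns are present.
#' @export
autoplot.modbind_ord <- function(object, ...) {
  df <- as_tibble(object)
  p <- ggplot(df, aes(x = .data$PC1, y = .data$PC2))
  if (all(c("context", "bait") %in% names(df))) {
    p <- p + geom_point(aes(color = .data$context, shape = .data$bait),
                        size = 2)
  } else {
    p <- p + geom_point(size = 2)
  }
  p + labs(x = "PC1", y = "PC2") + theme_minimal()
}

#' Correlation heatmap
#'
#' @param cormat experiment-by-experiment correlation matrix from
#'   [correlation_matrix()].
#' @return A ggplot tile heatmap.
#' @export
plot_correlation_heatmap <- function(cormat) {
  df <- as_tibble(cormat, rownames = "row") |>
    tidyr::pivot_longer(-"row", names_to = "col", values_to = "rho")
  ggplot(df, aes(x = .data$col, y = .data$row, fill = .data$rho)) +
    geom_tile() +
    scale_fill_gradient2(low = "steelblue", mid = "white",
                         high = "firebrick", midpoint = 0.5,
                         limits = c(0, 1)) +
    labs(x = NULL, y = NULL, fill = "Spearman") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5))
}

#' Group preference heatmap
#'
#' @param object a `preference_tests` tibble.
#' @param ... unused.
#' @return A ggplot tile map of mean paired difference per group x bait,
#'   with significant preferences outlined.
#' @export
autoplot.preference_tests <- function(object, ...) {
  df <- as_tibble(object)
  ggplot(df, aes(x = .data$bait, y = .data$group,
                 fill = .data$mean_diff)) +
    geom_tile() +
    geom_tile(data = filter(df, .data$preferred), fill = NA,
              color = "black", linewidth = 0.6) +
    scale_fill_gradient2(low = "steelblue", mid = "white",
                         high = "firebrick") +
    labs(x = "bait", y = NULL, fill = "mean z diff") +
    theme_minimal()
}
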