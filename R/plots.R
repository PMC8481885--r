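#' Volcano-style plot of a differential screen
#'
#' t-statistic against -log10 p with the classification thresholds drawn
#' in; points coloured by direction call.
#'
#' @param records Classified tibble from [diff_screen()].
#' @param p_threshold,t_threshold Thresholds to draw; defaults 0.05, 2.
#' @return A ggplot object.
#' @export
plot_differential <- function(records, p_threshold = 0.05, t_threshold = 2) {
  ggplot2::ggplot(records,
                  ggplot2::aes(x = .data$t, y = -log10(.data$p),
                               colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-t_threshold, t_threshold),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(yintercept = -log10(p_threshold),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "t statistic (case - control)",
                  y = expression(-log[10] ~ p), colour = NULL) +
    ggplot2::theme_minimal()
}

#' Degree and betweenness distributions of a ceRNA network
#'
#' Two-panel summary used to eyeball the network's topology: node degree
#' and (log10-scaled) betweenness distributions, split by node type.
#'
#' @param object A `"cerna_network"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cerna_network <- function(object, ...) {
  mt <- network_metrics(object) %>%
    tidyr::pivot_longer(c("degree", "betweenness"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(mt, ggplot2::aes(x = .data$value, fill = .data$type)) +
    ggplot2::geom_histogram(bins = 20, position = "stack") +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = NULL, y = "nodes", fill = "node type") +
    ggplot2::theme_minimal()
}

#' Ranked lncRNA candidates from a biomarker report
#'
#' @param report A `"biomarker_report"`.
#' @param top_n Show at most this many lncRNAs; default 20.
#' @return A ggplot object (lncRNAs ordered by degree).
#' @export
plot_lncrna_ranking <- function(report, top_n = 20) {
  rk <- head(report$lncrna_ranking, top_n)
  rk$lncrna <- factor(rk$lncrna, levels = rev(rk$lncrna))
  ggplot2::ggplot(rk, ggplot2::aes(x = .data$degree, y = .data$lncrna)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "network degree", y = NULL) +
    ggplot2::theme_minimal()
}
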