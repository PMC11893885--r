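# ggplot2 helpers for the main result types.

#' Plot mean temporal profiles of expression clusters
#'
#' @param log2_cpm features x samples log2-CPM matrix
#' @param clusters tibble (feature, cluster)
#' @param samples tibble with sample_id, timepoint
#' @return a ggplot
#' @export
plot_temporal_clusters <- function(log2_cpm, clusters, samples) {
  z <- t(scale(t(log2_cpm[clusters$feature, , drop = FALSE])))
  df <- as_tibble(z, rownames = "feature") |>
    tidyr::pivot_longer(-"feature", names_to = "sample_id", values_to = "z") |>
    left_join(samples[, c("sample_id", "timepoint")], by = "sample_id") |>
    left_join(clusters, by = "feature") |>
    group_by(.data$cluster, .data$feature, .data$timepoint) |>
    summarise(z = mean(.data$z), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$timepoint, .data$z,
                                   group = .data$feature)) +
    ggplot2::geom_line(alpha = 0.2) +
    ggplot2::stat_summary(ggplot2::aes(group = 1), fun = mean,
                          geom = "line", linewidth = 1.2, colour = "red") +
    ggplot2::facet_wrap(~cluster, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "timepoint", y = "z-scored log2 CPM") +
    ggplot2::theme_minimal()
}

#' Histogram of significant interaction distances
#'
#' @param calls an [call_interactions()] result
#' @return a ggplot
#' @export
plot_interaction_distances <- function(calls) {
  sig <- as_tibble(calls[calls$pass_both, ])
  ggplot2::ggplot(sig, ggplot2::aes(log10(abs(.data$dist)))) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::labs(x = "log10 interaction distance (bp)", y = "interactions") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.enhdyn_de <- function(object, ...) {
  ggplot2::ggplot(object$table, ggplot2::aes(.data$p)) +
    ggplot2::geom_histogram(breaks = seq(0, 1, 0.05)) +
    ggplot2::labs(x = "p-value", y = "features",
                  title = "NB ANOVA-like test p-value distribution") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.enhdyn_enrichment <- function(object, ...) {
  df <- tibble(count = object$perm)
  ggplot2::ggplot(df, ggplot2::aes(.data$count)) +
    ggplot2::geom_histogram(binwidth = 1) +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::labs(x = "loci overlapping regions (permutations)",
                  y = "permutations",
                  title = sprintf("observed %d, fold %.2f, p = %.3g",
                                  object$observed, object$fold, object$p)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
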