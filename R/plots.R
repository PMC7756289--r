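#' Plot the top haplotypes of an EM fit or pipeline result
#'
#' Horizontal bar chart of the `k` most frequent haplotypes.
#'
#' @param object An `hla_em` or `hla_pipeline` object.
#' @param k Number of haplotypes to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hla_em
#' @export
autoplot.hla_em <- function(object, k = 15, ...) {
  plot_top_haplotypes(object$freqs, k)
}

#' @rdname autoplot.hla_em
#' @method autoplot hla_pipeline
#' @export
autoplot.hla_pipeline <- function(object, k = 15, ...) {
  plot_top_haplotypes(object$freqs, k)
}

plot_top_haplotypes <- function(freqs, k) {
  top <- top_k(freqs, k)
  top$haplotype <- factor(top$haplotype, levels = rev(top$haplotype))
  ggplot2::ggplot(top,
                  ggplot2::aes(x = .data$frequency, y = .data$haplotype)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "estimated frequency", y = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of a shared frequency profile
#'
#' Tile plot of population-by-key frequencies with rows and columns ordered
#' by UPGMA clustering on Pearson correlation distance (see
#' [profile_cluster_orders()]).
#'
#' @param profile Wide tibble from [shared_profile()].
#' @param cluster Reorder rows/columns by clustering (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_profile_heatmap <- function(profile, cluster = TRUE) {
  long <- tidyr::pivot_longer(profile, -"population",
                              names_to = "key", values_to = "frequency")
  if (cluster) {
    ord <- profile_cluster_orders(profile)
    long$population <- factor(long$population, levels = ord$population_order)
    long$key <- factor(long$key, levels = ord$key_order)
  }
  ggplot2::ggplot(long, ggplot2::aes(x = .data$key, y = .data$population,
                                     fill = .data$frequency)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1,
                                                       vjust = 0.5))
}

#' Plot subsampled diversity statistics with confidence intervals
#'
#' Point-and-interval plot for equal-sample-size singleton comparisons
#' across populations.
#'
#' @param results Tibble binding [subsample_statistic_ci()] rows, with an
#'   added `population` column.
#' @return A ggplot object.
#' @export
plot_diversity_ci <- function(results) {
  stopifnot("population" %in% names(results))
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data$median, y = .data$population)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::labs(x = "% singletons (median, 95% interval)", y = NULL) +
    ggplot2::theme_minimal()
}
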