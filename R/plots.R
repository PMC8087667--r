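#' Plot a pilot-sweep result table
#'
#' Boxplots of a quality metric by pilot size, one panel per metric and
#' colour per generator, mirroring how pilot-study sweeps are usually
#' summarized.
#'
#' @param object A `"pilot_results"` tibble from [run_pilot_experiment()].
#' @param metrics Columns to facet over.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pilot_results <- function(object,
                                   metrics = c("dbi", "ari",
                                               "cluster_count_mad"), ...) {
  df <- dplyr::filter(object, is.na(.data$error))
  df <- tidyr::pivot_longer(df, cols = dplyr::all_of(metrics),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$plate_size),
                                   y = .data$value,
                                   fill = .data$generator)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "pilot size (cells)", y = NULL, fill = "generator") +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a reference clustering embedding
#'
#' @param object A `"ref_clustering"` object.
#' @param ... Unused.
#' @return A ggplot scatter of the 2-d embedding coloured by cluster.
#' @export
autoplot.ref_clustering <- function(object, ...) {
  df <- tidy.ref_clustering(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2,
                                   colour = factor(.data$label))) +
    ggplot2::geom_point(size = 0.7) +
    ggplot2::labs(colour = "cluster") +
    ggplot2::theme_bw()
}
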