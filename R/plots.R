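#' MA plot of a differential count test
#'
#' Mean normalised expression against log2 fold change, features significant
#' at `alpha` (BH-adjusted) highlighted.
#'
#' @param object A `spliceops_nbdiff` from [diff_counts()].
#' @param alpha Significance threshold on `q` (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.spliceops_nbdiff <- function(object, alpha = 0.05, ...) {
  d <- as_tibble(object) |>
    mutate(mean_expr = (.data$base_mean_a + .data$base_mean_b) / 2,
           significant = .data$q < alpha)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean_expr, y = .data$log2_fc,
                                  colour = .data$significant)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "red3")) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "mean normalised count", y = "log2 fold change",
                  colour = paste0("q < ", alpha)) +
    ggplot2::theme_minimal()
}

#' Plot the junction-count spectrum by category
#'
#' @param object A `spliceops_junction_counts` from [count_junction_hits()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.spliceops_junction_counts <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$count, fill = .data$category)) +
    ggplot2::geom_histogram(bins = 30, position = "stack") +
    ggplot2::labs(x = "supporting reads per junction", y = "junctions") +
    ggplot2::theme_minimal()
}

#' Plot inclusion-ratio estimates against middle-exon length
#'
#' @param est Estimates from [quantify_inclusion()].
#' @return A ggplot object.
#' @export
plot_inclusion <- function(est) {
  ggplot2::ggplot(est, ggplot2::aes(x = .data$middle_len, y = .data$ir,
                                    colour = .data$passes_cutoff)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = pmax(0, .data$ir - .data$se),
                                        ymax = pmin(1, .data$ir + .data$se)),
                           width = 0) +
    ggplot2::labs(x = "middle exon length (bp)", y = "inclusion ratio") +
    ggplot2::theme_minimal()
}

#' Plot the PAS hexamer frequency table
#'
#' @param freq Output of [pas_frequency_table()].
#' @return A ggplot object.
#' @export
plot_pas_frequency <- function(freq) {
  ggplot2::ggplot(freq,
                  ggplot2::aes(x = stats::reorder(.data$hexamer, .data$rank),
                               y = .data$n_sites)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "PAS hexamer (rank order)", y = "annotated sites") +
    ggplot2::theme_minimal()
}
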