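#' Replicate scatter of log2 protein intensities
#'
#' The quantitative-QC scatter: one sample's log2 intensities against its
#' duplicate, with the least-squares fit and Pearson r annotated.
#'
#' @param quant Protein quant tibble.
#' @param sample_a,sample_b Samples to compare.
#' @return A ggplot.
#' @export
plot_replicate_scatter <- function(quant, sample_a, sample_b) {
  stats <- replicate_correlation(quant, sample_a, sample_b)
  df <- quant %>%
    filter(.data[[sample_a]] > 0, .data[[sample_b]] > 0) %>%
    mutate(la = log2(.data[[sample_a]]), lb = log2(.data[[sample_b]]))
  ggplot2::ggplot(df, ggplot2::aes(.data$la, .data$lb)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4, colour = "firebrick") +
    ggplot2::annotate("text", -Inf, Inf, hjust = -0.1, vjust = 1.5,
                      label = sprintf("r = %.3f, slope = %.2f",
                                      stats$pearson_r, stats$slope)) +
    ggplot2::labs(x = bquote(log[2] ~ .(sample_a)),
                  y = bquote(log[2] ~ .(sample_b))) +
    ggplot2::theme_minimal()
}

#' Quadrant scatter of protein versus mRNA fold changes
#'
#' @param assignments Tibble from [assign_quadrant()].
#' @return A ggplot with mRNA log2 fold change on the abscissa, protein on
#'   the ordinate, coloured by quadrant.
#' @export
plot_concordance <- function(assignments) {
  ggplot2::ggplot(assignments,
                  ggplot2::aes(.data$mrna_log2fc, .data$protein_log2fc,
                               colour = .data$quadrant)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(
      "1" = "firebrick", "2" = "purple", "3" = "forestgreen",
      "4" = "steelblue", "boundary" = "grey60")) +
    ggplot2::labs(x = expression(log[2] ~ "mRNA fold change"),
                  y = expression(log[2] ~ "protein fold change")) +
    ggplot2::theme_minimal()
}

#' Bar chart of per-category differential counts
#'
#' @param dist Tibble from [category_distribution()] with `n_up`/`n_down`.
#' @return A ggplot with up/down bars per functional category.
#' @export
plot_category_distribution <- function(dist) {
  long <- dist %>%
    tidyr::pivot_longer(c("n_up", "n_down"), names_to = "direction",
                        values_to = "count") %>%
    mutate(direction = sub("n_", "", .data$direction))
  ggplot2::ggplot(long, ggplot2::aes(.data$category, .data$count,
                                     fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(up = "grey55", down = "black")) +
    ggplot2::labs(x = NULL, y = "proteins") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Bar chart of MRM abundance ratios
#'
#' @param mrm An `mrm_result` tibble.
#' @return A ggplot of mean control-normalized ratios with SD error bars.
#' @export
plot_mrm_ratios <- function(mrm) {
  ggplot2::ggplot(as_tibble(mrm),
                  ggplot2::aes(.data$protein_id, .data$mean_ratio,
                               fill = .data$sample)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_ratio - .data$sd_ratio,
                   ymax = .data$mean_ratio + .data$sd_ratio),
      position = ggplot2::position_dodge(0.9), width = 0.3) +
    ggplot2::labs(x = NULL, y = "abundance ratio vs control") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Volcano-style overview of a differential-call result
#'
#' @param object A `diff_calls` object.
#' @param ... Unused.
#' @return A ggplot of log2 mean ratio against -log10 minimum p-value.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.diff_calls <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(log2(.data$mean_ratio),
                                   -log10(.data$min_p),
                                   colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(up = "firebrick",
                                            down = "steelblue",
                                            none = "grey70")) +
    ggplot2::labs(x = expression(log[2] ~ "mean ratio"),
                  y = expression(-log[10] ~ "min p")) +
    ggplot2::theme_minimal()
}
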