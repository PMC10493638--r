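# ggplot2 views of the result tables. Each function takes the tidy table
# produced by the corresponding analysis step and returns a ggplot object.

.bias_palette <- c(
  balanced = "grey60",
  H1D = "#1b9e77", H2D = "#d95f02", H3D = "#7570b3",
  H1S = "#66c2a5", H2S = "#fc8d62", H3S = "#8da0cb"
)

#' Ternary scatter of triad relative expression
#'
#' Projects the ternary coordinates (`e_H1`, `e_H2`, `e_H3`) onto the plane
#' and colours triads by bias group. The three vertices correspond to
#' triads expressed from a single haplotype.
#'
#' @param assignments Classified tibble from [classify_bias()].
#' @param tissue Tissue to plot (default `"combined"` when present,
#'   otherwise all rows).
#' @return A ggplot object.
#' @export
plot_ternary <- function(assignments, tissue = NULL) {
  df <- assignments
  if (!is.null(df[["tissue"]])) {
    if (is.null(tissue) && "combined" %in% df$tissue) tissue <- "combined"
    if (!is.null(tissue)) df <- dplyr::filter(df, .data$tissue == !!tissue)
  }
  df <- df |>
    dplyr::mutate(
      tx = .data$e_H2 + .data$e_H3 / 2,
      ty = sqrt(3) / 2 * .data$e_H3
    )
  frame <- tibble::tibble(
    x = c(0, 1, 0.5, 0), y = c(0, 0, sqrt(3) / 2, 0)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$tx, .data$ty)) +
    ggplot2::geom_path(data = frame, ggplot2::aes(.data$x, .data$y),
                       inherit.aes = FALSE, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$group), size = 0.8,
                        alpha = 0.7) +
    ggplot2::scale_colour_manual(values = .bias_palette) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "bias group",
                  title = "Triad relative expression (H1 left, H2 right, H3 top)")
}

#' Stacked contribution of the seven bias groups per tissue
#'
#' @param group_summary Tibble from [summarize_groups()].
#' @return A ggplot object.
#' @export
plot_group_summary <- function(group_summary) {
  ggplot2::ggplot(
    group_summary,
    ggplot2::aes(.data$tissue, .data$percent,
                 fill = factor(.data$group, levels = rev(bias_groups())))
  ) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = .bias_palette, name = "bias group") +
    ggplot2::labs(x = NULL, y = "% of expressed triads") +
    ggplot2::theme_minimal()
}

#' Ka/Ks distribution per bias group
#'
#' @param kaks Per-triad Ka/Ks tibble joined with assignments, i.e. columns
#'   `group` and `ka_ks_triad` (e.g. built on the way into
#'   [kaks_by_group()]).
#' @return A ggplot object.
#' @export
plot_kaks_groups <- function(kaks) {
  ggplot2::ggplot(
    dplyr::filter(kaks, !is.na(.data$ka_ks_triad)),
    ggplot2::aes(factor(.data$group, levels = bias_groups()),
                 .data$ka_ks_triad, fill = .data$group)
  ) +
    ggplot2::geom_violin(scale = "width", show.legend = FALSE) +
    ggplot2::geom_boxplot(width = 0.15, fill = "white", outlier.size = 0.4) +
    ggplot2::scale_fill_manual(values = .bias_palette) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "Ka/Ks") +
    ggplot2::theme_minimal()
}

#' Windowed density of biased-triad genes along chromosomes
#'
#' @param density Tibble from [biased_gene_density()].
#' @return A ggplot object.
#' @export
plot_bias_density <- function(density) {
  ggplot2::ggplot(
    density,
    ggplot2::aes(.data$window_start / 1e6, .data$n_biased_genes)
  ) +
    ggplot2::geom_col(width = 0.1, fill = "#d95f02") +
    ggplot2::facet_wrap(~chrom, ncol = 1, strip.position = "right") +
    ggplot2::labs(x = "position (Mb)", y = "biased genes / window") +
    ggplot2::theme_minimal()
}
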