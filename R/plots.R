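# ggplot2 views of the main result types

#' Plot a PCoA ordination
#'
#' @param object A `virome_pcoa` object from [beta_ordination()].
#' @param groups Optional tibble `sample_id`, `group` to colour points.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.virome_pcoa <- function(object, groups = NULL, ...) {
  df <- object$coordinates
  if (!is.null(groups)) df <- left_join(df, groups, by = "sample_id")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$axis1, y = .data$axis2)) +
    ggplot2::labs(
      x = sprintf("PCoA 1 (%.1f%%)", 100 * object$relative_eig[1]),
      y = sprintf("PCoA 2 (%.1f%%)", 100 * object$relative_eig[2])
    ) +
    ggplot2::theme_minimal()
  if (!is.null(groups)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), size = 2)
  } else {
    p + ggplot2::geom_point(size = 2)
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Boxplots of alpha-diversity indices by group
#'
#' @param alpha Per-sample alpha tibble from [sample_alpha_diversity()].
#' @param groups Tibble `sample_id`, `group`.
#' @return A ggplot faceted by index.
#' @export
plot_alpha_diversity <- function(alpha, groups) {
  df <- alpha %>%
    left_join(groups, by = "sample_id") %>%
    tidyr::pivot_longer(c("observed", "chao1", "ace", "shannon",
                          "inv_simpson"),
                        names_to = "index", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$value,
                                   fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none") +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Stacked family composition per sample
#'
#' @param family_abundance Tibble `family`, `sample_id`, `relative` from
#'   [summarize_family_abundance()].
#' @return A ggplot.
#' @export
plot_family_abundance <- function(family_abundance) {
  ggplot2::ggplot(family_abundance,
                  ggplot2::aes(x = .data$sample_id, y = .data$relative,
                               fill = .data$family)) +
    ggplot2::geom_col() +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5)) +
    ggplot2::labs(x = NULL, y = "relative abundance")
}
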