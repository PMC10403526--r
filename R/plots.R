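#' Volcano plot of protein-response associations
#'
#' `-log10(p)` against standardized effect size; negative effects
#' associate with resistance, positive with sensitivity. Top hits are
#' labelled.
#'
#' @param results A `plex_assoc` tibble from [fit_univariate()].
#' @param top_k Number of proteins to label.
#' @return A ggplot object.
#' @export
plot_volcano <- function(results, top_k = 10) {
  tab <- volcano_table(results, top_k = top_k)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$effect_size,
                                    y = .data$neg_log10_p)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$top_hit),
                        alpha = 0.6, show.legend = FALSE) +
    ggplot2::geom_text(data = dplyr::filter(tab, .data$top_hit),
                       ggplot2::aes(label = .data$protein_id),
                       vjust = -0.6, size = 2.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "Effect size (response per SD abundance)",
                  y = expression(-log[10] * "(p-value)")) +
    ggplot2::theme_minimal()
}

#' @export
#' @rdname plot_volcano
#' @param object,... `autoplot()` arguments (`object` is the
#'   `plex_assoc`).
autoplot.plex_assoc <- function(object, top_k = 10, ...) {
  plot_volcano(object, top_k = top_k)
}

#' Sample embedding plot
#'
#' Scatter of samples on two principal components, coloured by a design
#' annotation (batch, subtype, ...).
#'
#' @param embedding A `plex_pca` from [pca_embed()].
#' @param design Validated study design.
#' @param colour_by Design column used for colour.
#' @param components Two components to display.
#' @return A ggplot object.
#' @export
plot_embedding <- function(embedding, design, colour_by = "subtype",
                           components = c(1, 2)) {
  sco <- dplyr::left_join(embedding$scores,
                          dplyr::select(design, "sample_id",
                                        dplyr::all_of(colour_by)),
                          by = "sample_id")
  pcs <- paste0("PC", components)
  ev <- 100 * embedding$explained_variance[components]
  ggplot2::ggplot(sco, ggplot2::aes(x = .data[[pcs[1]]], y = .data[[pcs[2]]],
                                    colour = .data[[colour_by]])) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::labs(x = sprintf("%s (%.1f%%)", pcs[1], ev[1]),
                  y = sprintf("%s (%.1f%%)", pcs[2], ev[2]),
                  colour = colour_by) +
    ggplot2::theme_minimal()
}

#' @export
#' @rdname plot_embedding
autoplot.plex_pca <- function(object, design, colour_by = "subtype", ...) {
  plot_embedding(object, design, colour_by = colour_by)
}
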