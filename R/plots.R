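#' Stacked-bar plot of a community partition
#'
#' Per-sample fractions of mappable reads by shared-membership category,
#' the standard way site/season sharing of a community is displayed.
#'
#' @param object A `vh_partition` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot vh_partition
#' @export
autoplot.vh_partition <- function(object, ...) {
  fr <- object$fractions
  xlab <- if (object$grouping == "site") "site" else "season"
  fr$group <- fr[[xlab]]
  ggplot2::ggplot(fr, ggplot2::aes(x = .data$sample_id, y = .data$fraction,
                                   fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$group), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = NULL, y = "fraction of mappable reads",
                  fill = "shared in") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Heatmap of consensus host scores
#'
#' @param object A `vh_host_predictions` object (with attached evidence).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot vh_host_predictions
#' @export
autoplot.vh_host_predictions <- function(object, ...) {
  sc <- tidy(object)
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$taxon_id, y = .data$virus_id,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$evidence_types), size = 2.5,
                       color = "white") +
    ggplot2::scale_fill_viridis_c(limits = c(0, 6)) +
    ggplot2::labs(x = "candidate host taxon", y = "virus",
                  fill = "consensus\nscore") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Bar plot of lineage sizes per depth cutoff
#'
#' @param assignments Tibble from [assign_lineages()].
#' @return A ggplot object.
#' @export
plot_lineage_sizes <- function(assignments) {
  sizes <- dplyr::count(assignments, .data$cutoff, .data$lineage)
  ggplot2::ggplot(sizes, ggplot2::aes(x = .data$lineage, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(ggplot2::vars(.data$cutoff), scales = "free_x",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "lineage", y = "genomes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Coverage-fraction plot for mapped contigs
#'
#' @param profiles Coverage tibble from [map_reads()].
#' @param presence_threshold Presence rule to draw (fraction).
#' @return A ggplot object.
#' @export
plot_coverage <- function(profiles, presence_threshold = 0.75) {
  ggplot2::ggplot(profiles,
                  ggplot2::aes(x = .data$contig_id,
                               y = .data$covered_fraction,
                               fill = .data$present)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = presence_threshold, linetype = 2) +
    ggplot2::labs(x = NULL, y = "fraction of contig covered",
                  fill = "present") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
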