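# ggplot2 displays for the package's result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-gene rearrangement frequencies
#'
#' A bar chart of RF (%) per gene, genes ordered along the reference
#' arrangement (the natural reading order of the circle), faceted by group
#' when the RF table contains several. Genes with missing RF (no occurrence
#' in the group) are dropped from the panel.
#'
#' @param rf An RF table from [rf_table()].
#' @param reference The reference the table was computed on (fixes the gene
#'   ordering on the x axis).
#' @return A ggplot object.
#' @export
plot_rf <- function(rf, reference = typical_vertebrate()) {
  reference <- as_reference(reference)
  d <- rf |>
    dplyr::filter(!is.na(rf_percent)) |>
    dplyr::mutate(label = factor(label, levels = union(reference$label,
                                                       unique(label))))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = label, y = rf_percent)) +
    ggplot2::geom_col(ggplot2::aes(fill = rf_percent), show.legend = FALSE) +
    ggplot2::scale_fill_gradient(low = "grey70", high = "firebrick") +
    ggplot2::labs(x = NULL, y = "RF (%)",
                  title = "Per-gene rearrangement frequency") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
  if (dplyr::n_distinct(d$group) > 1) {
    p <- p + ggplot2::facet_wrap(~group, ncol = 1)
  }
  p
}

#' @describeIn census Bar chart of pattern-class counts, majors ranked and
#'   rare classes pooled by kind.
#' @param object,... An `mgr_census`; further arguments are ignored.
#' @method autoplot mgr_census
#' @export
autoplot.mgr_census <- function(object, ...) {
  d <- tibble::as_tibble(object) |>
    dplyr::mutate(
      shown = ifelse(class == "major", paste0("Pattern ", pattern_rank), class),
      shown = factor(shown, levels = unique(shown))
    )
  ggplot2::ggplot(d, ggplot2::aes(x = shown, y = count, fill = class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "genomes",
                  title = paste0("Arrangement patterns (scope: ",
                                 attr(object, "scope"), ")")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @describeIn clade_enrichment Scatter of clade size against the adjusted
#'   enrichment p-value (-log10), one point per tested node.
#' @param object,... An `mgr_enrichment`; further arguments are ignored.
#' @method autoplot mgr_enrichment
#' @export
autoplot.mgr_enrichment <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = clade_size, y = -log10(p_adj))) +
    ggplot2::geom_point(ggplot2::aes(colour = k_labeled / clade_size)) +
    ggplot2::labs(x = "clade size", y = expression(-log[10](p[adj])),
                  colour = "labelled\nfraction",
                  title = "Hypergeometric clade enrichment") +
    ggplot2::theme_minimal()
}

#' @describeIn rare_rs_summary Scatter of genome RS for the rare-arrangement
#'   species, with the mean as a dashed line.
#' @param object,... An `mgr_rare`; further arguments are ignored.
#' @method autoplot mgr_rare
#' @export
autoplot.mgr_rare <- function(object, ...) {
  d <- tibble::as_tibble(object) |>
    dplyr::arrange(rs) |>
    dplyr::mutate(species_id = factor(species_id, levels = species_id))
  ggplot2::ggplot(d, ggplot2::aes(x = species_id, y = rs, colour = class)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = attr(object, "mean_rs"),
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = NULL, y = "genome RS",
                  title = "RS of rare-arrangement species") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}
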