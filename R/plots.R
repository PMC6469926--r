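#' Plot detection rate against site depth
#'
#' One curve per variant: the empirical fraction of cells in which the
#' variant is detected, in half-open depth bins. Bins are placed at their
#' midpoint; empty bins are dropped. Overlay the closed-form expectation
#' with [detection_probability()] if desired.
#'
#' @param object A `mito_detection_rates` tibble
#'   ([detection_rate_by_depth()]).
#' @param min_cells Hide bins with fewer cells than this (default 1).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mito_detection_rates
#' @export
autoplot.mito_detection_rates <- function(object, min_cells = 1, ...) {
  d <- object[!is.na(object$rate) & object$n_cells >= min_cells, ]
  d$depth_mid <- (d$depth_lo + d$depth_hi) / 2
  ggplot2::ggplot(d, ggplot2::aes(x = .data$depth_mid, y = .data$rate,
                                  colour = .data$variant_id)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_cells), alpha = 0.8) +
    ggplot2::scale_size_area(max_size = 4) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "site depth (bin midpoint)",
                  y = "detection rate",
                  colour = "variant", size = "cells") +
    ggplot2::theme_minimal()
}

#' VAF spectrum of a variant-call table
#'
#' Histogram of variant allele frequencies, coloured by classification;
#' bulk mtDNA call sets are typically bimodal, with a homoplasmic band
#' near 1 (individual-distinguishing, mostly germline) and a heteroplasmic
#' tail at low VAF (clone-distinguishing, somatic).
#'
#' @param calls A variant-call tibble.
#' @param bins Histogram bin count (default 50).
#' @return A ggplot object.
#' @export
plot_vaf_spectrum <- function(calls, bins = 50) {
  ggplot2::ggplot(calls, ggplot2::aes(x = .data$vaf,
                                      fill = .data$classification)) +
    ggplot2::geom_histogram(bins = bins, boundary = 0) +
    ggplot2::labs(x = "variant allele frequency", y = "variants",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Cells-by-variants detection heat map
#'
#' The binary genotype matrix as tiles (detected / not detected), cells in
#' rows ordered by their detection pattern, optionally annotated with
#' clone assignments.
#'
#' @param genotypes A binarized genotype tibble.
#' @param clones Optional `mito_clones` object; cells are ordered and
#'   faceted by assigned label.
#' @return A ggplot object.
#' @export
plot_genotype_heatmap <- function(genotypes, clones = NULL) {
  if (!"detected" %in% names(genotypes)) {
    stop_validation("run binarize_genotypes() first")
  }
  d <- genotypes
  if (!is.null(clones)) {
    d <- dplyr::left_join(d, tidy(clones)[c("cell_id", "label")],
                          by = "cell_id")
  } else {
    d$label <- ""
  }
  d <- dplyr::arrange(d, .data$label, .data$cell_id)
  d$cell_id <- factor(d$cell_id, levels = unique(d$cell_id))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$variant_id,
                                       y = .data$cell_id,
                                       fill = .data$detected)) +
    ggplot2::geom_tile(colour = "grey90") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "white",
                                          `TRUE` = "#2166AC")) +
    ggplot2::labs(x = "mtDNA variant", y = "cell", fill = "detected") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (!is.null(clones)) {
    p <- p + ggplot2::facet_grid(rows = ggplot2::vars(.data$label),
                                 scales = "free_y", space = "free_y")
  }
  p
}
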