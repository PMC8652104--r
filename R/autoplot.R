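# ggplot2 views of the main result types, for interactive work; the
# deterministic SVG renderer (render_pav) remains the canonical static output.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a PAV table as a presence/absence heatmap
#'
#' One tile per (block, genome) cell: absent cells light grey, present cells
#' coloured by the block's core/variable status at `threshold`.
#'
#' @param object A `pav_df` object.
#' @param threshold Core/variable threshold (default 0.95).
#' @param panchromosome Panchromosome to draw; default the first.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pav_df <- function(object, threshold = 0.95,
                            panchromosome = NULL, ...) {
  pc <- panchromosome %||% pav_panchromosomes(object)[1]
  sub <- object[object$panchromosome == pc, , drop = FALSE]
  long <- tidy(sub)
  calls <- classify_pav(sub, threshold)
  long <- dplyr::left_join(long, calls[, c("block_id", "status")], by = "block_id")
  long$fill <- ifelse(!long$present, "absent", tolower(long$status))
  long$genome <- factor(long$genome, levels = rev(pav_genomes(object)))
  ggplot2::ggplot(long, ggplot2::aes(xmin = .data$start, xmax = .data$stop,
                                     ymin = as.integer(.data$genome) - 0.45,
                                     ymax = as.integer(.data$genome) + 0.45,
                                     fill = .data$fill)) +
    ggplot2::geom_rect() +
    ggplot2::scale_fill_manual(values = c(core = "#E69F00",
                                          variable = "#56B4E9",
                                          absent = "#DDDDDD"),
                               name = NULL) +
    ggplot2::scale_y_continuous(breaks = seq_along(levels(long$genome)),
                                labels = levels(long$genome)) +
    ggplot2::labs(x = sprintf("%s position (bp)", pc), y = NULL,
                  title = sprintf("Presence/absence, threshold %.2f", threshold)) +
    ggplot2::theme_minimal()
}

#' Plot the panchromosome overview profile
#'
#' @param pav A `pav_df` object.
#' @param panchromosome Panchromosome to summarize; default the first.
#' @param width_px Number of bins (default 200).
#' @return A ggplot object showing mean presence fraction per bin.
#' @export
plot_overview <- function(pav, panchromosome = NULL, width_px = 200) {
  pc <- panchromosome %||% pav_panchromosomes(pav)[1]
  bins <- overview_bins(pav, pc, width_px)
  ggplot2::ggplot(bins, ggplot2::aes(x = (.data$bp_start + .data$bp_stop) / 2,
                                     y = .data$value)) +
    ggplot2::geom_col(width = bins$bp_stop - bins$bp_start, fill = "#444444") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = sprintf("%s position (bp)", pc),
                  y = "mean presence fraction") +
    ggplot2::theme_minimal()
}
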