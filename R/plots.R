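#' Plot a LOD profile
#'
#' LOD score against physical position, one panel per chromosome, with an
#' optional declaration threshold line.
#'
#' @param object A `qtl_scan` from [scan_qtl()].
#' @param threshold Optional LOD threshold drawn as a dashed line.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot qtl_scan
#' @export
autoplot.qtl_scan <- function(object, threshold = NULL, ...) {
  p <- ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(x = .data$pos_bp / 1e6, y = .data$lod)
  ) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "Physical position (Mb)", y = "LOD",
                  title = paste(attr(object, "trait"), attr(object, "env"))) +
    ggplot2::theme_bw()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold,
                                 linetype = "dashed", colour = "red")
  }
  p
}

#' Plot a recombination bin map
#'
#' Lines stacked vertically, chromosomes side by side, bins coloured by
#' genotype (the standard bin-map graphic: B/Qi319 red, A/Ye478 blue,
#' heterozygous yellow).
#'
#' @param bins A `bin_map` from [build_bins()].
#' @param rils Optional subset of line ids to draw.
#' @return A ggplot object.
#' @export
plot_bin_map <- function(bins, rils = NULL) {
  ids <- rils %||% bin_call_cols(bins)
  long <- bins %>%
    select("bin_id", "chrom", "start_bp", "end_bp", all_of(ids)) %>%
    tidyr::pivot_longer(all_of(ids), names_to = "ril",
                        values_to = "genotype")
  ggplot2::ggplot(long, ggplot2::aes(
    xmin = .data$start_bp / 1e6, xmax = .data$end_bp / 1e6,
    ymin = match(.data$ril, ids) - 0.5, ymax = match(.data$ril, ids) + 0.5,
    fill = .data$genotype
  )) +
    ggplot2::geom_rect() +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom),
                        scales = "free_x", space = "free_x") +
    ggplot2::scale_fill_manual(values = c(
      A = "#3B6FB6", B = "#C0392B", H = "#F1C40F", N = "grey85"
    )) +
    ggplot2::labs(x = "Physical position (Mb)", y = "Line",
                  fill = "Genotype") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.ticks.y = ggplot2::element_blank())
}

#' Plot genetic versus physical marker positions
#'
#' The collinearity diagnostic: cumulative cM against physical midpoint per
#' chromosome. A monotone curve indicates agreement between map and genome
#' order.
#'
#' @param object A `genetic_map` from [build_genetic_map()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot genetic_map
#' @export
autoplot.genetic_map <- function(object, ...) {
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(x = (.data$start_bp + .data$end_bp) / 2e6,
                 y = .data$pos_cm)
  ) +
    ggplot2::geom_point(size = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free") +
    ggplot2::labs(x = "Physical position (Mb)",
                  y = "Genetic position (cM)") +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
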