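# ggplot2 views: per-chromosome log2/mBAF panels, oncoprint matrix,
# risk-transition chart

#' Per-chromosome depth and mirrored-BAF panels
#'
#' The diagnostic view of the caller: binned log2 ratios on top, the
#' mirrored-BAF track underneath, with called events shaded. Returns a
#' patchwork stack when the patchwork package is available, otherwise a list
#' of the two ggplots.
#'
#' @param bins output of [normalize_depth()].
#' @param baf_points output of [compute_baf()].
#' @param chrom chromosome to draw.
#' @param events optional event tibble to shade.
#' @return patchwork object or list of two ggplots.
#' @export
plot_chromosome <- function(bins, baf_points, chrom, events = NULL) {
  b <- dplyr::filter(bins, .data$chrom == !!chrom)
  p <- dplyr::filter(baf_points, .data$chrom == !!chrom, !is.na(.data$baf))
  shade <- if (!is.null(events) && nrow(events) > 0) {
    dplyr::filter(tibble::as_tibble(events), .data$chrom == !!chrom)
  } else NULL
  add_shade <- function(g) {
    if (is.null(shade) || nrow(shade) == 0) return(g)
    g + ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "orange", alpha = 0.15)
  }
  g1 <- ggplot2::ggplot(b, ggplot2::aes(
    x = (.data$bin_start + .data$bin_end) / 2e6, y = .data$log2_ratio)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::labs(x = NULL, y = "log2 ratio",
                  title = paste0("chr", chrom)) +
    ggplot2::theme_minimal()
  g2 <- ggplot2::ggplot(p, ggplot2::aes(x = .data$pos / 1e6,
                                        y = .data$baf)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.4) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2,
                        colour = "grey40") +
    ggplot2::ylim(0.45, 1) +
    ggplot2::labs(x = "position (Mb)", y = "mirrored BAF") +
    ggplot2::theme_minimal()
  g1 <- add_shade(g1); g2 <- add_shade(g2)
  if (requireNamespace("patchwork", quietly = TRUE)) {
    patchwork::wrap_plots(g1, g2, ncol = 1)
  } else list(log2 = g1, baf = g2)
}

#' @export
autoplot.onekaryo_events <- function(object, bins, baf_points, ...) {
  chroms <- unique(object$chrom)
  if (length(chroms) == 0) {
    stop_onekaryo("no events to plot", class = "onekaryo_validation_error")
  }
  plot_chromosome(bins, baf_points, chroms[1], events = object)
}

#' Oncoprint-style mutation tile plot
#'
#' @param mm mutation matrix from [mutation_matrix()].
#' @return ggplot.
#' @export
plot_oncoprint <- function(mm) {
  long <- tidyr::pivot_longer(mm, -"sample_id", names_to = "gene",
                              values_to = "mutated")
  gene_order <- long |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(n = sum(.data$mutated), .groups = "drop") |>
    dplyr::arrange(.data$n)
  long$gene <- factor(long$gene, levels = gene_order$gene)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id, y = .data$gene,
                                     fill = factor(.data$mutated))) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = c(`0` = "grey92", `1` = "#2c7fb8"),
                               guide = "none") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Risk-category transition chart
#'
#' Row-normalized stacked bars: for each baseline category, the share of
#' patients landing in each comparison category.
#'
#' @param comparison a `risk_comparison` from [compare_classifications()].
#' @return ggplot.
#' @export
plot_transitions <- function(comparison) {
  tr <- comparison$transitions
  tr$from <- factor(tr$from, levels = rev(comparison$categories))
  tr$to <- factor(tr$to, levels = comparison$categories)
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$pct, y = .data$from,
                                   fill = .data$to)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "% of patients", y = "baseline category",
                  fill = "reclassified to",
                  title = toupper(comparison$model)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
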