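# Figure builders. Each returns a ggplot object built purely from the tidy
# tables the pipeline writes, so every figure can be regenerated from TSVs.

#' Neutrality plot (GC12 against GC3)
#'
#' @param index_rows A per-gene index tibble; facetted by species when more
#'   than one is present.
#' @return A ggplot object with the fitted regression line.
#' @export
plot_neutrality <- function(index_rows) {
  d <- dplyr::mutate(index_rows, gc12 = (.data$gc1 + .data$gc2) / 2)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$gc3, y = .data$gc12)) +
    ggplot2::geom_point(alpha = 0.7, colour = "#2c7fb8") +
    ggplot2::geom_smooth(
      method = "lm", formula = y ~ x, se = FALSE,
      colour = "black", linewidth = 0.5
    ) +
    ggplot2::facet_wrap(~species_id) +
    ggplot2::labs(x = "GC3 (%)", y = "GC12 (%)") +
    ggplot2::theme_bw()
}

#' ENC-plot with the mutation-only expectation curve
#'
#' @param index_rows A per-gene index tibble.
#' @return A ggplot object; the curve [enc_expected()] is drawn over GC3s.
#' @export
plot_enc <- function(index_rows) {
  curve <- tibble::tibble(
    gc3s = seq(0, 100, by = 0.5),
    enc = enc_expected(seq(0, 1, by = 0.005))
  )
  ggplot2::ggplot(index_rows, ggplot2::aes(x = .data$gc3s, y = .data$enc)) +
    ggplot2::geom_line(
      data = curve, colour = "goldenrod", linewidth = 0.7
    ) +
    ggplot2::geom_point(alpha = 0.7, colour = "#2c7fb8") +
    ggplot2::facet_wrap(~species_id) +
    ggplot2::labs(x = "GC3s (%)", y = "ENC") +
    ggplot2::theme_bw()
}

#' ENC frequency ratio histogram
#'
#' @param histogram The `histogram` tibble from [enc_diagnostics()], with an
#'   optional `species_id` column for facetting.
#' @return A ggplot bar chart of gene counts per ratio bin.
#' @export
plot_enc_ratio_hist <- function(histogram) {
  p <- ggplot2::ggplot(
    histogram,
    ggplot2::aes(x = .data$bin_mid, y = .data$n)
  ) +
    ggplot2::geom_col(fill = "#2c7fb8", colour = "grey30", width = 0.045) +
    ggplot2::labs(x = "ENC ratio (ENCexp - ENCobs)/ENCexp", y = "Genes") +
    ggplot2::theme_bw()
  if ("species_id" %in% names(histogram)) {
    p <- p + ggplot2::facet_wrap(~species_id)
  }
  p
}

#' PR2 bias plot
#'
#' @param points The `points` tibble from [pr2_analysis()], with an optional
#'   `species_id` column for facetting.
#' @return A ggplot scatter with centre lines at 0.5.
#' @export
plot_pr2 <- function(points) {
  p <- ggplot2::ggplot(points, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, colour = "grey40") +
    ggplot2::geom_vline(xintercept = 0.5, linetype = 2, colour = "grey40") +
    ggplot2::geom_point(alpha = 0.7, colour = "#2c7fb8") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "A3s / (A3s + T3s)", y = "G3s / (G3s + C3s)") +
    ggplot2::theme_bw()
  if ("species_id" %in% names(points)) {
    p <- p + ggplot2::facet_wrap(~species_id)
  }
  p
}

#' Stacked RSCU bar chart by amino acid
#'
#' @param rscu_tables A named list of RSCU tibbles (one per species).
#' @return A ggplot stacked bar chart, one bar per amino-acid group.
#' @export
plot_rscu_bars <- function(rscu_tables) {
  d <- dplyr::bind_rows(rscu_tables, .id = "species_id")
  ggplot2::ggplot(
    d,
    ggplot2::aes(x = .data$aa, y = .data$rscu, fill = .data$codon)
  ) +
    ggplot2::geom_col(position = "stack", colour = "grey30",
                      linewidth = 0.1) +
    ggplot2::facet_wrap(~species_id, ncol = 1) +
    ggplot2::guides(fill = "none") +
    ggplot2::labs(x = "Amino acid", y = "RSCU") +
    ggplot2::theme_bw()
}

#' Per-gene GC content heatmap
#'
#' @param index_rows A per-gene index tibble.
#' @return A ggplot tile map of GC1/GC2/GC3/GCall per gene.
#' @export
plot_gc_heatmap <- function(index_rows) {
  d <- tidyr::pivot_longer(
    index_rows[, c("gene_name", "species_id", "gc1", "gc2", "gc3", "gc_all")],
    cols = c("gc1", "gc2", "gc3", "gc_all"),
    names_to = "measure", values_to = "percent"
  )
  ggplot2::ggplot(
    d,
    ggplot2::aes(x = .data$measure, y = .data$gene_name,
                 fill = .data$percent)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "#31a354", high = "#de2d26") +
    ggplot2::facet_wrap(~species_id, nrow = 1) +
    ggplot2::labs(x = NULL, y = NULL, fill = "%") +
    ggplot2::theme_minimal(base_size = 8)
}

.save_svg <- function(plot, path, width = 7, height = 5) {
  grDevices::svg(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  print(plot)
  invisible(path)
}
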