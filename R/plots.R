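#' Volcano plot of a differential-expression contrast
#'
#' @param object A `deg_contrast` from [call_deg()].
#' @param ... Unused.
#' @return A ggplot: log2 fold change against -log10 FDR, coloured by call.
#' @method autoplot deg_contrast
#' @export
autoplot.deg_contrast <- function(object, ...) {
  d <- object$results |>
    filter(is.finite(.data$fold_change), .data$fold_change > 0)
  ggplot2::ggplot(d, ggplot2::aes(x = log2(.data$fold_change),
                                  y = -log10(pmax(.data$fdr, 1e-300)),
                                  colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * log2(object$params$fc),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_hline(yintercept = -log10(object$params$alpha),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(up = "#c0392b", down = "#2980b9",
                                            ns = "grey70")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 FDR",
                  title = paste(object$group_a, "vs", object$group_b)) +
    ggplot2::theme_minimal()
}

#' Plot a windowed coverage or density track
#'
#' @param track Coverage-track tibble (`chrom`, `window_index`, `depth`).
#' @param window Window size in bp (used to label the x axis in Mb).
#' @return A ggplot of depth along each chromosome (one facet per
#'   chromosome).
#' @export
plot_coverage_track <- function(track, window = 1000L) {
  ggplot2::ggplot(track, ggplot2::aes(x = .data$window_index * window / 1e6,
                                      y = .data$depth)) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "depth / density") +
    ggplot2::theme_minimal()
}

#' Map called gene clusters along a chromosome
#'
#' @param clusters Cluster table from [predict_cazgc()].
#' @param genes Gene table used for the call.
#' @return A ggplot showing cluster spans (segments) over gene positions
#'   (rug), one facet per chromosome with clusters.
#' @export
plot_cazgc <- function(clusters, genes) {
  if (nrow(clusters) == 0L) {
    abort("no clusters to plot", class = "mycomine_validation_error")
  }
  g <- genes |> filter(.data$chrom %in% clusters$chrom)
  ggplot2::ggplot() +
    ggplot2::geom_rug(data = g, ggplot2::aes(x = .data$start / 1e6),
                      sides = "b", alpha = 0.4, length = ggplot2::unit(4, "pt")) +
    ggplot2::geom_segment(
      data = clusters,
      ggplot2::aes(x = .data$start / 1e6, xend = .data$end / 1e6,
                   y = 1, yend = 1, colour = .data$cluster_id),
      linewidth = 4
    ) +
    ggplot2::facet_wrap(~chrom, ncol = 1) +
    ggplot2::labs(x = "position (Mb)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   legend.position = "bottom")
}
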