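# ggplot2 views of the main result types. Minimal, publication-shaped:
# a volcano for DE, a tile heatmap for centered expression, a TSS profile
# heatmap, feature-space scatter for the poly-A discriminant, and decay
# curves for half-life series.

#' @exportS3Method ggplot2::autoplot
autoplot.lnc_de <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(.data$p_value),
                                   colour = .data$direction)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(up = "#d7301f", down = "#0570b0",
                                            none = "grey60")) +
    ggplot2::labs(x = "log2 fold change (high vs low MYC)",
                  y = "-log10 p", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Centered expression heatmap
#'
#' @param centered Wide centered matrix from [center_log2fc()], typically
#'   reordered with [heatmap_matrix()].
#' @return A ggplot tile heatmap, transcripts in row order top to bottom.
#' @export
plot_expression_heatmap <- function(centered) {
  long <- tidyr::pivot_longer(centered, -"gene_id", names_to = "sample",
                              values_to = "log2fc")
  long$gene_id <- factor(long$gene_id, levels = rev(centered$gene_id))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample, y = .data$gene_id,
                                     fill = .data$log2fc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#0570b0", mid = "white",
                                  high = "#d7301f") +
    ggplot2::labs(x = NULL, y = NULL, fill = "centered\nlog2FC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' @exportS3Method ggplot2::autoplot
autoplot.lnc_profile <- function(object, ...) {
  flank <- attr(object, "flank"); bin <- attr(object, "bin")
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"gene_id",
                              names_to = "bin_id", values_to = "coverage")
  long$pos <- (as.integer(sub("bin_", "", long$bin_id)) - 0.5) * bin - flank
  long$gene_id <- factor(long$gene_id, levels = rev(object$gene_id))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pos, y = .data$gene_id,
                                     fill = .data$coverage)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "#b30000") +
    ggplot2::labs(x = "distance from TSS (bp, transcription rightward)",
                  y = NULL, fill = "coverage") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Poly-A feature space with the trained decision boundary
#'
#' @param features Feature tibble from [polya_features()].
#' @param d Optional `lnc_lda`; when given, the zero-score boundary is drawn.
#' @return A ggplot scatter of ribo-depleted vs poly-A mean log2 CPM.
#' @export
plot_polya <- function(features, d = NULL) {
  p <- ggplot2::ggplot(features, ggplot2::aes(x = .data$ribo, y = .data$polya)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.5) +
    ggplot2::labs(x = "mean log2 CPM (ribo-depleted)",
                  y = "mean log2 CPM (poly-A)") +
    ggplot2::theme_minimal()
  if (!is.null(d) && abs(d$weights[2]) > 1e-12) {
    # w1*x + w2*y - offset = 0
    p <- p + ggplot2::geom_abline(slope = -d$weights[1] / d$weights[2],
                                  intercept = d$offset / d$weights[2],
                                  linetype = "dashed", colour = "#d7301f")
  }
  p
}

#' Decay curves with fitted half-lives
#'
#' @param series Decay tibble (`gene_id`, `time_min`, `abundance`).
#' @param half_lives Optional output of [estimate_half_life()] used to
#'   annotate facets.
#' @return A ggplot of log2 relative abundance against time, one facet per
#'   gene.
#' @export
plot_decay <- function(series, half_lives = NULL) {
  df <- series
  if (!is.null(half_lives)) {
    lab <- sprintf("%s (t1/2 = %.0f min)", half_lives$gene_id,
                   half_lives$half_life)
    df$gene_id <- factor(df$gene_id, levels = half_lives$gene_id,
                         labels = lab)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_min,
                                   y = log2(.data$abundance))) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4, colour = "#0570b0") +
    ggplot2::facet_wrap(~gene_id) +
    ggplot2::labs(x = "minutes after transcription shutoff",
                  y = "log2 relative abundance") +
    ggplot2::theme_minimal()
}

#' @exportS3Method generics::tidy
tidy.lnc_de <- function(x, ...) tibble::as_tibble(x)

#' @exportS3Method generics::glance
glance.lnc_de <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x), n_significant = sum(x$significant),
                 n_up = sum(x$direction == "up"),
                 n_down = sum(x$direction == "down"),
                 dispersion = attr(x, "dispersion"),
                 fc_threshold = attr(x, "fc_threshold"),
                 p_threshold = attr(x, "p_threshold"))
}
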