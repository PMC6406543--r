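#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_hline
#'   geom_vline geom_errorbar geom_segment labs theme_minimal
#'   scale_color_manual position_dodge
#' @export
ggplot2::autoplot

#' Volcano plot of a stratified DE result
#'
#' One panel per stratum; the dashed guides mark the significance and
#' effect-size filter.
#'
#' @param object A `stratmir_de` object.
#' @param alpha,lfc Filter thresholds drawn as guides (defaults 0.05, 1).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stratmir_de <- function(object, alpha = 0.05, lfc = 1, ...) {
  d <- object$table
  d$hit <- d$p_adj < alpha & abs(d$log2fc) > lfc
  ggplot(d, aes(x = .data$log2fc, y = -log10(.data$p),
                color = .data$hit)) +
    geom_point(size = 1, alpha = 0.7) +
    geom_vline(xintercept = c(-lfc, lfc), linetype = "dashed",
               linewidth = 0.3) +
    ggplot2::facet_wrap(~stratum) +
    scale_color_manual(values = c(`TRUE` = "#C03028", `FALSE` = "grey55"),
                       guide = "none") +
    labs(x = "log2 fold change (case vs control)",
         y = expression(-log[10](p))) +
    theme_minimal()
}

#' Status-by-gender interaction plot
#'
#' Plots per-cell means of -dCt with standard-error bars, one line per
#' gender; crossing lines are the visual signature of a status-by-gender
#' interaction.
#'
#' @param cell_means Output of [qpcr_cell_means()].
#' @return A ggplot object, faceted by target.
#' @export
plot_interaction <- function(cell_means) {
  ggplot(cell_means,
         aes(x = .data$status, y = .data$mean, group = .data$gender,
             color = .data$gender)) +
    geom_line(position = position_dodge(width = 0.1)) +
    geom_point(position = position_dodge(width = 0.1)) +
    geom_errorbar(aes(ymin = .data$mean - .data$se,
                      ymax = .data$mean + .data$se),
                  width = 0.15, position = position_dodge(width = 0.1)) +
    ggplot2::facet_wrap(~target_id) +
    labs(x = NULL, y = expression(-Delta * "Ct (log2 expression)"),
         color = "gender") +
    theme_minimal()
}

#' Plot an overlap network
#'
#' Draws nodes on a circle (deterministic layout) with node size mapped to
#' the miRNA regulator count and edge transparency to Jaccard weight.
#'
#' @param object An `overlap_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.overlap_network <- function(object, ...) {
  nodes <- object$nodes
  n <- nrow(nodes)
  theta <- 2 * pi * (seq_len(n) - 1) / max(n, 1)
  nodes$x <- cos(theta); nodes$y <- sin(theta)
  edges <- object$edges
  if (nrow(edges) > 0L) {
    ia <- match(edges$a, nodes$pathway); ib <- match(edges$b, nodes$pathway)
    edges$x <- nodes$x[ia]; edges$y <- nodes$y[ia]
    edges$xend <- nodes$x[ib]; edges$yend <- nodes$y[ib]
  }
  p <- ggplot(nodes, aes(x = .data$x, y = .data$y))
  if (nrow(edges) > 0L) {
    p <- p + geom_segment(data = edges,
                          aes(xend = .data$xend, yend = .data$yend,
                              alpha = .data$weight),
                          color = "grey40")
  }
  p + geom_point(aes(size = .data$mirna_count), color = "#2C5F8A") +
    ggplot2::geom_text(aes(label = .data$pathway), size = 2.4, vjust = -1.2) +
    ggplot2::coord_equal() +
    labs(size = "miRNA count", alpha = "Jaccard weight") +
    ggplot2::theme_void()
}
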