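#' Volcano plot
#'
#' @param v Output of [volcano()].
#' @param alpha Significance line.
#' @return A ggplot object.
#' @export
plot_volcano <- function(v, alpha = 0.05) {
  ggplot2::ggplot(v, ggplot2::aes(x = .data$log2_fc,
                                  y = -log10(.data$p_value),
                                  colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p",
                  colour = sprintf("p < %g", alpha)) +
    ggplot2::theme_minimal()
}

#' Scatter of a 2-D embedding coloured by group
#'
#' @param embedding A `raman_embedding`.
#' @param groups Group label per sample.
#' @return A ggplot object.
#' @export
plot_embedding <- function(embedding, groups) {
  d <- as.data.frame(embedding$coordinates)
  names(d) <- c("dim1", "dim2")
  d$group <- as.character(groups)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$dim1, y = .data$dim2,
                                  colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = paste0(toupper(embedding$method), " 1"),
                  y = paste0(toupper(embedding$method), " 2")) +
    ggplot2::theme_minimal()
}
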