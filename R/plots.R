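#' @export
autoplot.pathway_scores <- function(object, ...) {
  df <- tidy(object)
  df$sample_id <- factor(df$sample_id,
                         levels = colnames(object$scores)[order(object$labels)])
  ggplot2::ggplot(df, ggplot2::aes(.data$sample_id, .data$pathway_id,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "steelblue", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::facet_grid(. ~ label, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "sample", y = "pathway", fill = "deregulation") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' @export
autoplot.fdr_ratio_result <- function(object, ...) {
  df <- tidy(object)
  df$kind <- ifelse(df$dataset == "real", "real", "mock")
  ggplot2::ggplot(df, ggplot2::aes(.data$dataset, .data$fdr_bar,
                                   fill = .data$kind)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "mean FDR",
                  title = sprintf("%s arm: FDR ratio %.2f", object$arm,
                                  object$ratio)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1),
                   legend.position = "none")
}

#' @export
autoplot.sample_size_curves <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$size, .data$mean_fdr,
                               colour = .data$arm, linetype = .data$arm)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = sprintf("number of %s samples", attr(object, "which")),
                  y = "average mean FDR", colour = NULL, linetype = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.uncertainty_result <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$fraction, .data$detection_rate,
                               colour = .data$what)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "fraction removed",
                  y = sprintf("detection rate (top %d)", attr(object, "top_k")),
                  colour = "removed") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
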