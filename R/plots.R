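#' Plot a confusion matrix heatmap
#'
#' @param x a `cav_metrics` object.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.cav_metrics <- function(x, ...) {
  df <- as.data.frame(as.table(x$confusion))
  names(df) <- c("truth", "predicted", "n")
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(title = paste0(x$level, " confusion (", x$stage, ")"),
                  x = "predicted", y = "truth") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Plot centerlines coloured by branch code (sagittal-ish projection)
#'
#' @param centerlines tibble with `x`, `z` and a code column.
#' @param colour column to colour by.
#' @return a ggplot.
#' @export
plot_centerlines <- function(centerlines, colour = "branch_code") {
  ggplot2::ggplot(centerlines,
                  ggplot2::aes(.data$x, .data$z,
                               group = .data$polyline_id,
                               colour = .data[[colour]])) +
    ggplot2::geom_path(linewidth = 0.4, show.legend = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "z (mm)") +
    ggplot2::theme_minimal()
}

#' Plot the 2-D separability embedding
#'
#' @param sep result of [separability_check()].
#' @param level `"true_chunk"` or `"true_branch"`.
#' @return a ggplot.
#' @export
plot_embedding <- function(sep, level = "true_chunk") {
  emb <- attr(sep, "embedding")
  labs <- attr(sep, "labels")
  if (is.null(emb)) abort("separability result carries no embedding")
  df <- as.data.frame(emb)
  df$label <- labs[[level]]
  ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2,
                                   colour = .data$label)) +
    ggplot2::geom_point(size = 0.5, alpha = 0.7, show.legend = FALSE) +
    ggplot2::theme_minimal() +
    ggplot2::labs(title = paste0("spot embedding coloured by ", level))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
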