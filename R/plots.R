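#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_tile geom_abline labs scale_fill_gradient theme_minimal
#' @export
ggplot2::autoplot

#' Plot methods
#'
#' \code{autoplot()} turns the tabular result objects into standard ggplot2
#' displays: the cumulative variance curve of a PCA summary, per-channel
#' imputation fidelity bars, a row-normalised confusion heatmap, and the
#' full-vs-subset accuracy scatter of a channel ablation.
#'
#' @param object a result object.
#' @param ... unused.
#' @name mmmp-plots
NULL

#' @rdname mmmp-plots
#' @method autoplot pca_summary
#' @export
autoplot.pca_summary <- function(object, ...) {
  ggplot(object$variance, aes(x = .data$component, y = 100 * .data$cum_fraction)) +
    geom_line() + geom_point() +
    labs(x = "principal component", y = "cumulative variance explained (%)") +
    theme_minimal()
}

#' @rdname mmmp-plots
#' @method autoplot fidelity_report
#' @export
autoplot.fidelity_report <- function(object, ...) {
  df <- as_tibble(unclass(object))
  df$channel <- factor(df$channel, levels = df$channel)
  ggplot(df[df$defined, ], aes(x = .data$channel, y = .data$r2)) +
    geom_col() +
    labs(x = NULL, y = expression(imputation ~ r^2)) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' @rdname mmmp-plots
#' @method autoplot confusion_matrix
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  frac <- sweep(object$counts, 1, pmax(rowSums(object$counts), 1), "/")
  df <- as_tibble(as.data.frame(as.table(frac), stringsAsFactors = FALSE))
  names(df) <- c("truth", "predicted", "fraction")
  ggplot(df, aes(x = .data$predicted, y = .data$truth, fill = .data$fraction)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "firebrick", limits = c(0, 1)) +
    labs(x = "predicted feature", y = "annotated feature",
         fill = "row fraction") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Full-panel versus channel-subset accuracy scatter
#'
#' @param comparison the \code{comparison} tibble of
#'   \code{\link{ablate_channels}}.
#' @return A ggplot.
#' @export
plot_ablation <- function(comparison) {
  ggplot(comparison, aes(x = .data$accuracy_subset, y = .data$accuracy_full)) +
    geom_abline(linetype = "dashed", colour = "grey60") +
    geom_point() +
    ggplot2::geom_text(aes(label = .data$feature), vjust = -0.8, size = 3) +
    ggplot2::coord_equal(xlim = c(0, 100), ylim = c(0, 100)) +
    labs(x = "accuracy, channel subset (%)", y = "accuracy, full panel (%)") +
    theme_minimal()
}

#' Display an RGB array produced by the renderers
#'
#' @param rgb h x w x 3 array on the 0-255 scale.
#' @param main plot title.
#' @export
plot_rgb <- function(rgb, main = "") {
  graphics::plot.new()
  graphics::plot.window(c(0, 1), c(0, 1), asp = nrow(rgb) / ncol(rgb))
  graphics::rasterImage(grDevices::as.raster(clip8(rgb) / 255), 0, 0, 1, 1)
  graphics::title(main)
  invisible(NULL)
}
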