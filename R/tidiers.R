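#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy methods for fitted pipeline objects
#'
#' \code{tidy()} returns one row per component / cluster / feature;
#' \code{glance()} a one-row model summary.
#'
#' @param x a fitted object from this package.
#' @param ... unused.
#' @name mmmp-tidiers
NULL

#' @rdname mmmp-tidiers
#' @method tidy pca_summary
#' @export
tidy.pca_summary <- function(x, ...) x$variance

#' @rdname mmmp-tidiers
#' @method glance pca_summary
#' @export
glance.pca_summary <- function(x, ...) {
  tibble(n_components = nrow(x$variance),
         var_pc1 = x$variance$var_fraction[1],
         n_dropped_channels = length(x$dropped_channels))
}

#' @rdname mmmp-tidiers
#' @method tidy cluster_model
#' @export
tidy.cluster_model <- function(x, ...) {
  dplyr::bind_cols(
    tibble(cluster = seq_len(x$k),
           size = as.integer(tabulate(x$assignments, x$k)),
           withinss = x$withinss),
    as_tibble(as.data.frame(x$centroids)))
}

#' @rdname mmmp-tidiers
#' @method glance cluster_model
#' @export
glance.cluster_model <- function(x, ...) {
  tibble(k = x$k, n_pixels = length(x$assignments),
         tot_withinss = x$tot_withinss)
}

#' @rdname mmmp-tidiers
#' @method tidy color_map
#' @export
tidy.color_map <- function(x, ...) x$colors

#' @rdname mmmp-tidiers
#' @method glance color_map
#' @export
glance.color_map <- function(x, ...) {
  tibble(n_clusters = nrow(x$colors), stress = x$stress)
}

#' @rdname mmmp-tidiers
#' @method tidy confusion_matrix
#' @export
tidy.confusion_matrix <- function(x, ...) x$accuracy

#' @rdname mmmp-tidiers
#' @method glance confusion_matrix
#' @export
glance.confusion_matrix <- function(x, ...) {
  tibble(n_features = nrow(x$counts),
         n_pixels = sum(x$counts),
         mean_accuracy = x$mean_accuracy,
         median_accuracy = x$median_accuracy)
}

#' @rdname mmmp-tidiers
#' @method tidy fidelity_report
#' @export
tidy.fidelity_report <- function(x, ...) as_tibble(unclass(x))

#' @rdname mmmp-tidiers
#' @method glance fidelity_report
#' @export
glance.fidelity_report <- function(x, ...) {
  tibble(mean_r2 = attr(x, "mean_r2"),
         n_channels = nrow(x), n_undefined = sum(!x$defined))
}

#' @rdname mmmp-tidiers
#' @method tidy lda_model
#' @export
tidy.lda_model <- function(x, ...) {
  dplyr::bind_cols(tibble(class = x$classes, prior = as.numeric(x$priors)),
                   as_tibble(as.data.frame(x$means)))
}

#' @rdname mmmp-tidiers
#' @method glance lda_model
#' @export
glance.lda_model <- function(x, ...) {
  tibble(n_classes = length(x$classes), n_channels = length(x$channels),
         lambda = x$lambda)
}

#' @rdname mmmp-tidiers
#' @method tidy stitch_result
#' @export
tidy.stitch_result <- function(x, ...) x$offsets

#' @rdname mmmp-tidiers
#' @method glance stitch_result
#' @export
glance.stitch_result <- function(x, ...) {
  tibble(n_tiles = nrow(x$offsets),
         canvas_h = nrow(x$canvas), canvas_w = ncol(x$canvas),
         chosen_overlap = x$chosen_overlap[1],
         n_fallback_pairs = x$pair_flags)
}
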