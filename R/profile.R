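#' PCA summary of a pixel matrix
#'
#' Channels are standardised to zero mean / unit variance (zero-variance
#' channels dropped with a warning) before the decomposition, so that no
#' single bright channel dominates. Per-component pixel-score images are
#' min-max scaled to [0, 255] for export.
#'
#' @param m an \code{mmmp_matrix}.
#' @param images logical; also scatter the per-component scores back into
#'   the canvas frame.
#' @return A \code{pca_summary}: \code{loadings}, \code{variance} tibble
#'   (component, var_fraction, cum_fraction), \code{scores},
#'   \code{score_images} (list, when requested), \code{dropped_channels}.
#' @export
pca_summary <- function(m, images = TRUE) {
  x <- channel_matrix(m)
  if (nrow(x) < 2) abort("need at least 2 pixels for PCA")
  sds <- apply(x, 2, stats::sd)
  dropped <- colnames(x)[sds == 0]
  if (length(dropped)) {
    warn(paste0("dropping zero-variance channel(s): ",
                paste(dropped, collapse = ", ")))
    x <- x[, sds > 0, drop = FALSE]
  }
  if (nrow(x) < ncol(x)) warn("fewer pixels than channels; PCA is rank-deficient")
  fit <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  vf <- fit$sdev^2 / sum(fit$sdev^2)
  variance <- tibble(component = seq_along(vf), var_fraction = vf,
                     cum_fraction = cumsum(vf))
  score_images <- NULL
  if (images) {
    score_images <- lapply(seq_len(ncol(fit$x)), function(k) {
      scatter_to_image(m, rescale_to(fit$x[, k], 0, 255), fill = 0)
    })
    names(score_images) <- paste0("PC", seq_along(score_images))
  }
  structure(list(loadings = fit$rotation, variance = variance,
                 scores = fit$x, score_images = score_images,
                 dropped_channels = dropped),
            class = "pca_summary")
}

#' @export
print.pca_summary <- function(x, ...) {
  v <- x$variance$var_fraction
  cat(sprintf("<pca_summary> %d components; leading variance fractions: %s\n",
              length(v), paste(sprintf("%.1f%%", 100 * utils::head(v, 3)),
                               collapse = ", ")))
  invisible(x)
}

#' Per-pixel k-means molecular profiling
#'
#' Hartigan-Wong k-means on the raw (unscaled) channel intensities, the
#' classical configuration for pixel profiling: \code{k = 100} groups,
#' \code{iter.max = 20}, a single start. Deterministic under \code{seed}.
#' When the matrix holds fewer distinct rows than \code{k}, \code{k} is
#' reduced to that number with a warning.
#'
#' @param m an \code{mmmp_matrix}.
#' @param k number of clusters.
#' @param max_iter maximum Hartigan-Wong iterations.
#' @param restarts number of random starts (\code{nstart}).
#' @param seed integer seed for the centroid initialisation.
#' @param centers optional explicit initial centroid matrix (rows =
#'   centroids); overrides \code{k} and the random initialisation.
#' @return A \code{cluster_model}: \code{centroids} (k x channels matrix),
#'   \code{assignments}, \code{withinss}, \code{tot_withinss}, \code{k},
#'   \code{coords} (pixel coordinates), \code{dims}.
#' @export
kmeans_profiles <- function(m, k = 100, max_iter = 20, restarts = 1,
                            seed = 1L, centers = NULL) {
  x <- channel_matrix(m)
  if (is.null(centers)) {
    if (!is_count(k)) abort("k must be a positive integer")
    n_distinct <- nrow(unique(x))
    if (n_distinct < k) {
      warn(sprintf("only %d distinct pixel profiles; reducing k from %d", n_distinct, k))
      k <- n_distinct
    }
    if (nrow(x) < k) abort("fewer pixels than clusters")
    fit <- with_seed(seed, quiet_kmeans(x, centers = k, iter.max = max_iter,
                                         nstart = restarts,
                                         algorithm = "Hartigan-Wong"))
  } else {
    fit <- quiet_kmeans(x, centers = centers, iter.max = max_iter,
                         algorithm = "Hartigan-Wong")
    k <- nrow(centers)
  }
  structure(list(centroids = fit$centers, assignments = fit$cluster,
                 withinss = fit$withinss, tot_withinss = fit$tot.withinss,
                 k = k, seed = seed,
                 coords = m[c("px_row", "px_col")], dims = attr(m, "dims")),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> k = %d over %d pixels, total WSS = %.4g\n",
              x$k, length(x$assignments), x$tot_withinss))
  invisible(x)
}

#' Similarity-based cluster colour map via nonmetric MDS
#'
#' Embeds the cluster centroids into three dimensions with Kruskal's
#' nonmetric MDS (initialised from classical MDS) and reads the axes as RGB:
#' similar molecular profiles get similar colours. Axes are ordered by the
#' variance of the embedded coordinates and reflected to positive skew, so
#' the mapping is reproducible up to that convention. The embedding is
#' mapped into the colour cube isotropically (all axes share one scale
#' factor, the longest axis spanning 0-255), so colour distances stay
#' proportional to embedded distances. The Kruskal stress of the embedding
#' is reported as a fraction in [0, 1].
#'
#' @param centroids numeric matrix (clusters x channels) or a
#'   \code{cluster_model}.
#' @param maxit isoMDS iteration cap.
#' @return A \code{color_map}: \code{colors} tibble (cluster, R, G, B),
#'   \code{stress}, \code{embedding}.
#' @export
mds_colormap <- function(centroids, maxit = 100) {
  if (inherits(centroids, "cluster_model")) centroids <- centroids$centroids
  centroids <- as.matrix(centroids)
  n <- nrow(centroids)
  if (n < 2) abort("need at least 2 centroids")
  if (nrow(unique(centroids)) == 1) abort("all centroids are identical")
  d <- stats::dist(centroids)
  if (any(d < 1e-9)) {
    warn("duplicate centroids; jittering by epsilon for the embedding")
    centroids <- centroids +
      with_seed(0L, matrix(stats::rnorm(length(centroids), 0, 1e-6), n))
    d <- stats::dist(centroids)
  }
  init <- stats::cmdscale(d, k = min(3, n - 1))
  if (ncol(init) < 3) init <- cbind(init, matrix(0, n, 3 - ncol(init)))
  if (n > 3) {
    fit <- MASS::isoMDS(d, y = init, k = 3, maxit = maxit, trace = FALSE)
    emb <- fit$points
    stress <- fit$stress / 100      # isoMDS reports percent
  } else {
    emb <- init                     # <= 3 points embed exactly; stress 0
    stress <- 0
  }
  # axis order by variance, reflections resolved to positive skew
  vars <- apply(emb, 2, stats::var)
  emb <- emb[, order(vars, decreasing = TRUE), drop = FALSE]
  for (j in 1:3) {
    centred <- emb[, j] - mean(emb[, j])
    if (sum(centred^3) < 0) emb[, j] <- -emb[, j]
  }
  # isotropic scaling into the colour cube: one common factor for all axes,
  # so colour distances remain proportional to embedded distances (per-axis
  # stretching would re-rank them)
  mins <- apply(emb, 2, min)
  ranges <- apply(emb, 2, max) - mins
  s <- 255 / max(ranges, .Machine$double.eps)
  rgb <- sweep(sweep(emb, 2, mins), 2, rep(s, 3), `*`)
  colors <- tibble(cluster = seq_len(n),
                   R = rgb[, 1], G = rgb[, 2], B = rgb[, 3])
  structure(list(colors = colors, stress = stress, embedding = emb),
            class = "color_map")
}

#' @export
print.color_map <- function(x, ...) {
  cat(sprintf("<color_map> %d clusters, stress = %.4g\n",
              nrow(x$colors), x$stress))
  invisible(x)
}

#' Render cluster membership as a colour image
#'
#' @param model a \code{cluster_model}.
#' @param cmap a \code{\link{mds_colormap}} result.
#' @param background RGB triple (0-255) for non-foreground pixels.
#' @return h x w x 3 array on the 0-255 scale.
#' @export
render_cluster_image <- function(model, cmap, background = c(0, 0, 0)) {
  stopifnot(inherits(model, "cluster_model"), inherits(cmap, "color_map"))
  if (!all(unique(model$assignments) %in% cmap$colors$cluster)) {
    abort("assignments contain cluster ids missing from the colour map")
  }
  dims <- model$dims
  out <- array(0, c(dims[1], dims[2], 3))
  lut <- as.matrix(cmap$colors[c("R", "G", "B")])[order(cmap$colors$cluster), , drop = FALSE]
  lin <- (model$coords$px_col - 1L) * dims[1] + model$coords$px_row
  plane <- dims[1] * dims[2]
  for (ch in 1:3) {
    out[(ch - 1L) * plane + seq_len(plane)] <- background[ch]
    out[(ch - 1L) * plane + lin] <- lut[model$assignments, ch]
  }
  out
}

#' Clustering fidelity by imputation
#'
#' Replaces every pixel's intensities with its cluster centroid ("imputed"
#' values) and reports, per channel, the squared Pearson correlation between
#' original and imputed intensities — how much of the per-channel variation
#' the clustering retains. Channels with zero variance in either vector are
#' undefined and excluded from the mean.
#'
#' @param m an \code{mmmp_matrix}.
#' @param model a \code{cluster_model} fitted on \code{m}.
#' @return A \code{fidelity_report} tibble (channel, r2, defined) with
#'   attribute \code{mean_r2}.
#' @export
imputation_r2 <- function(m, model) {
  x <- channel_matrix(m)
  if (length(model$assignments) != nrow(x)) {
    abort("model assignments do not match the matrix rows")
  }
  imputed <- model$centroids[model$assignments, , drop = FALSE]
  r2 <- vapply(seq_len(ncol(x)), function(j) {
    if (stats::sd(x[, j]) == 0 || stats::sd(imputed[, j]) == 0) return(NA_real_)
    stats::cor(x[, j], imputed[, j])^2
  }, numeric(1))
  out <- tibble(channel = colnames(x), r2 = r2, defined = !is.na(r2))
  attr(out, "mean_r2") <- mean(r2, na.rm = TRUE)
  class(out) <- c("fidelity_report", class(out))
  out
}

#' Compile per-sample cluster models into a global centroid matrix
#'
#' Row-concatenates the centroid vectors of every sample's cluster model
#' (102 samples x 100 clusters gives the canonical 10,200-row matrix),
#' hierarchically clusters them (average linkage, Euclidean distance), and
#' fits one pooled MDS colour map — a universal palette under which the same
#' molecular profile receives the same colour in every sample.
#'
#' @param models list of \code{cluster_model}s sharing a channel layout.
#' @param sample_ids identifiers, one per model.
#' @param dendrogram,colormap logical; compute the average-linkage
#'   dendrogram and the pooled MDS palette. Both are quadratic (or worse) in
#'   the total number of centroid vectors, so for compilations beyond a few
#'   thousand rows they can be switched off and run later on a subset.
#' @return A \code{global_profiles}: \code{centroids} tibble (sample,
#'   cluster, channels...), \code{hclust}, \code{colormap} (NULL when
#'   disabled), \code{channels}.
#' @export
compile_global <- function(models, sample_ids = seq_along(models),
                           dendrogram = TRUE, colormap = TRUE) {
  stopifnot(length(models) >= 1, length(sample_ids) == length(models))
  layouts <- lapply(models, function(mod) colnames(mod$centroids))
  if (!all(vapply(layouts, identical, logical(1), layouts[[1]]))) {
    abort("all models must share the same channel layout")
  }
  cen <- purrr::map2_dfr(models, sample_ids, function(mod, id) {
    dplyr::bind_cols(tibble(sample = id, cluster = seq_len(mod$k)),
                     as_tibble(as.data.frame(mod$centroids)))
  })
  mat <- as.matrix(cen[layouts[[1]]])
  hc <- if (dendrogram) stats::hclust(stats::dist(mat), method = "average")
  cmap <- if (colormap) mds_colormap(mat)
  structure(list(centroids = cen, hclust = hc, colormap = cmap,
                 channels = layouts[[1]]),
            class = "global_profiles")
}

#' @export
print.global_profiles <- function(x, ...) {
  cat(sprintf("<global_profiles> %d centroid vectors from %d samples, %d channels\n",
              nrow(x$centroids), dplyr::n_distinct(x$centroids$sample),
              length(x$channels)))
  invisible(x)
}

#' Recolour one sample's clustering with the universal palette
#'
#' @param model a \code{cluster_model} included in the compilation.
#' @param global a \code{\link{compile_global}} result.
#' @param sample_id the model's identifier in the compilation.
#' @param background RGB triple for non-foreground pixels.
#' @return h x w x 3 array on the 0-255 scale.
#' @export
render_with_global <- function(model, global, sample_id,
                               background = c(0, 0, 0)) {
  rows <- which(global$centroids$sample == sample_id)
  if (length(rows) != model$k) abort("sample not found in the global compilation")
  sub <- structure(list(colors = dplyr::mutate(
    global$colormap$colors[rows, ], cluster = seq_along(rows)),
    stress = global$colormap$stress), class = "color_map")
  render_cluster_image(model, sub, background = background)
}
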