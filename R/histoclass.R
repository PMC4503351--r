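#' Annotation set for histological features
#'
#' @param label integer matrix; 0 = unannotated, positive values index
#'   categories.
#' @param names character vector naming every nonzero label (in label
#'   order 1, 2, ...).
#' @param colors optional matrix/data frame of display RGB triples (0-255),
#'   one row per category.
#' @return An \code{annotation_set}.
#' @export
annotation_set <- function(label, names, colors = NULL) {
  label <- matrix(as.integer(label), nrow(label), ncol(label))
  ids <- sort(setdiff(unique(as.vector(label)), 0L))
  if (length(ids) && max(ids) > length(names)) {
    abort("every nonzero label needs a name")
  }
  if (is.null(colors)) {
    hues <- grDevices::col2rgb(grDevices::hcl.colors(max(length(names), 2), "Dark 3"))
    colors <- t(hues)[seq_along(names), , drop = FALSE]
  }
  colors <- as.matrix(colors)
  rownames(colors) <- names
  structure(list(label = label, names = names, colors = colors),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  n <- vapply(seq_along(x$names), function(i) sum(x$label == i), integer(1))
  cat("<annotation_set> ",
      paste(sprintf("%s (%d px)", x$names, n), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Annotation derived from a phantom's ground-truth label image
#'
#' @param truth a \code{phantom_truth}.
#' @param exclude feature names to leave unannotated (default none).
#' @return An \code{annotation_set} over the phantom's features.
#' @export
annotation_from_phantom <- function(truth, exclude = character()) {
  ids <- truth$feature_ids
  feats <- setdiff(names(ids)[order(unlist(ids))], "background")
  label <- truth$label
  for (f in intersect(exclude, feats)) label[label == ids[[f]]] <- 0L
  keep <- setdiff(feats, exclude)
  # re-index so annotated categories are 1..m in feature order
  relab <- matrix(0L, nrow(label), ncol(label))
  for (i in seq_along(keep)) relab[label == ids[[keep[i]]]] <- i
  annotation_set(relab, keep)
}

# Annotation labels aligned with the rows of an mmmp_matrix.
annotation_at_pixels <- function(ann, m) {
  ann$label[cbind(m$px_row, m$px_col)]
}

#' Per-feature molecular profiles with specificity flags
#'
#' Clusters the pixels of each annotated category separately (k-means, as in
#' the per-sample profiling), pools all resulting centroids, and flags a
#' centroid as feature-specific when its nearest neighbour among all other
#' centroids (Euclidean) belongs to the same category — i.e. its profile is
#' not better explained by another feature.
#'
#' @param m an \code{mmmp_matrix}.
#' @param ann an \code{annotation_set}.
#' @param k clusters per category; reduced per category (with a warning)
#'   when a category has fewer distinct pixels.
#' @param max_iter,seed passed to \code{\link{kmeans_profiles}}.
#' @return A \code{feature_profile_set} tibble: feature, cluster, n_pixels,
#'   specific, nearest_feature, plus one column per channel.
#' @export
feature_profiles <- function(m, ann, k = 100, max_iter = 20, seed = 1L) {
  lab <- annotation_at_pixels(ann, m)
  x <- channel_matrix(m)
  out <- list()
  for (i in seq_along(ann$names)) {
    rows <- which(lab == i)
    if (!length(rows)) abort(paste0("category absent from matrix: ", ann$names[i]))
    xi <- x[rows, , drop = FALSE]
    ki <- min(k, nrow(unique(xi)))
    if (ki < k) {
      warn(sprintf("category %s: reducing k from %d to %d distinct profiles",
                   ann$names[i], k, ki))
    }
    fit <- with_seed(seed + i, quiet_kmeans(xi, centers = ki,
                                             iter.max = max_iter,
                                             algorithm = "Hartigan-Wong"))
    out[[i]] <- dplyr::bind_cols(
      tibble(feature = ann$names[i], cluster = seq_len(ki),
             n_pixels = as.integer(fit$size)),
      as_tibble(as.data.frame(fit$centers)))
  }
  res <- dplyr::bind_rows(out)
  cen <- as.matrix(res[colnames(x)])
  d <- as.matrix(stats::dist(cen))
  diag(d) <- Inf
  nn <- apply(d, 1, which.min)
  res <- dplyr::mutate(res,
                       nearest_feature = res$feature[nn],
                       specific = res$feature[nn] == res$feature,
                       .after = "n_pixels")
  class(res) <- c("feature_profile_set", class(res))
  res
}

#' Checkerboard train/test partition of an annotated image
#'
#' Overlays an alternating grid of g x g squares; a pixel at (row, col)
#' belongs to region 1 when \code{floor((row-1)/g) + floor((col-1)/g)} is
#' even, else region 2. Candidates are tried from largest to smallest and
#' the largest g for which both regions contain at least one pixel of every
#' annotated category is selected — the coarsest split that still lets both
#' folds see every feature.
#'
#' @param ann an \code{annotation_set}.
#' @param candidates candidate edge lengths in pixels, default the classic
#'   100 / 50 / 20.
#' @return A \code{partition_grid}: \code{g}, \code{region} (1/2 matrix over
#'   the full canvas), \code{candidates_tried}.
#' @export
checkerboard_partition <- function(ann, candidates = c(100, 50, 20)) {
  if (sum(ann$label > 0) < 2) abort("need at least 2 annotated pixels")
  cats <- which(vapply(seq_along(ann$names),
                       function(i) any(ann$label == i), logical(1)))
  region_for <- function(g) {
    h <- nrow(ann$label); w <- ncol(ann$label)
    br <- (matrix(seq_len(h) - 1L, h, w) %/% g)
    bc <- (matrix(rep(seq_len(w) - 1L, each = h), h, w) %/% g)
    1L + (br + bc) %% 2L
  }
  tried <- sort(candidates, decreasing = TRUE)
  for (g in tried) {
    reg <- region_for(g)
    ok <- all(vapply(cats, function(i) {
      any(reg == 1L & ann$label == i) && any(reg == 2L & ann$label == i)
    }, logical(1)))
    if (ok) {
      return(structure(list(g = g, region = reg, candidates_tried = tried),
                       class = "partition_grid"))
    }
  }
  abort(paste0("no candidate grid size in {", paste(tried, collapse = ", "),
               "} covers every category in both regions; try smaller sizes"))
}

#' Linear discriminant classifier on pixel profiles
#'
#' Classical LDA: per-class mean vectors, a pooled within-class covariance
#' with a relative ridge (\code{lambda * trace(S)/d} added to the diagonal,
#' keeping the matrix positive-definite on degenerate input), and class
#' priors (empirical by default). Prediction is the argmax of the Gaussian
#' discriminant score \code{x' S^-1 mu - mu' S^-1 mu / 2 + log pi}.
#'
#' @param x numeric matrix of training pixels (rows) by channels.
#' @param labels class labels, one per row.
#' @param lambda relative ridge on the pooled covariance.
#' @param priors \code{"empirical"} or \code{"uniform"}.
#' @return An \code{lda_model}.
#' @export
train_lda <- function(x, labels, lambda = 1e-4,
                      priors = c("empirical", "uniform")) {
  priors <- match.arg(priors)
  x <- as.matrix(x)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) abort("need at least 2 classes")
  counts <- table(factor(labels, levels = classes))
  small <- names(counts)[counts < 2]
  if (length(small)) {
    abort(paste0("class(es) with fewer than 2 training pixels: ",
                 paste(small, collapse = ", ")))
  }
  d <- ncol(x)
  means <- do.call(rbind, lapply(classes, function(cl) {
    colMeans(x[labels == cl, , drop = FALSE])
  }))
  rownames(means) <- classes
  S <- matrix(0, d, d)
  for (cl in classes) {
    xc <- sweep(x[labels == cl, , drop = FALSE], 2, means[cl, ])
    S <- S + crossprod(xc)
  }
  S <- S / (nrow(x) - length(classes))
  S <- S + diag(lambda * sum(diag(S)) / d, d)
  Sinv <- solve(S)
  pri <- if (priors == "empirical") as.numeric(counts) / nrow(x)
         else rep(1 / length(classes), length(classes))
  structure(list(classes = classes, means = means, cov = S, cov_inv = Sinv,
                 priors = stats::setNames(pri, classes),
                 channels = colnames(x), lambda = lambda),
            class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model> %d classes on %d channels (priors: %s)\n",
              length(x$classes), length(x$channels),
              paste(sprintf("%s %.2f", x$classes, x$priors), collapse = ", ")))
  invisible(x)
}

# Linear discriminant scores, one column per class.
lda_scores <- function(model, x) {
  W <- model$cov_inv %*% t(model$means)                   # d x C
  b <- -0.5 * colSums(t(model$means) * W) + log(model$priors)
  sweep(as.matrix(x) %*% W, 2, b, "+")
}

#' @param object an \code{lda_model}.
#' @param newdata matrix of pixels by channels (same channel layout).
#' @param ... unused.
#' @return Character vector of predicted class labels.
#' @rdname train_lda
#' @export
predict.lda_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$channels)) {
    abort("newdata channel count does not match the model")
  }
  if (!is.null(colnames(newdata)) &&
      !identical(colnames(newdata), object$channels)) {
    abort("newdata channel layout does not match the model")
  }
  sc <- lda_scores(object, newdata)
  object$classes[max.col(sc, ties.method = "first")]
}

#' Checkerboard-cross-validated feature classification
#'
#' Trains an LDA on the annotated pixels of region 1 and predicts all
#' foreground pixels of region 2, then does the reciprocal, and merges the
#' two disjoint prediction sets. The confusion matrix is computed over
#' annotated pixels only; per-feature accuracy is the percentage of that
#' feature's annotated pixels predicted correctly.
#'
#' @param m an \code{mmmp_matrix}.
#' @param ann an \code{annotation_set}.
#' @param grid a \code{\link{checkerboard_partition}} result.
#' @param channels optional character subset of matrix channels to use.
#' @param lambda,priors passed to \code{\link{train_lda}}.
#' @return A \code{histology_prediction}: \code{predicted} (per-matrix-row
#'   class), \code{image} (predicted label image, 0 outside foreground),
#'   \code{confusion} (a \code{confusion_matrix}), \code{models} (the two
#'   fold models), \code{grid}, \code{channels}.
#' @export
cross_predict <- function(m, ann, grid = checkerboard_partition(ann),
                          channels = NULL, lambda = 1e-4,
                          priors = c("empirical", "uniform")) {
  priors <- match.arg(priors)
  x <- channel_matrix(m)
  if (!is.null(channels)) {
    missing_ch <- setdiff(channels, colnames(x))
    if (length(missing_ch)) {
      abort(paste0("unknown channel(s): ", paste(missing_ch, collapse = ", ")))
    }
    x <- x[, channels, drop = FALSE]
  }
  lab <- annotation_at_pixels(ann, m)
  reg <- grid$region[cbind(m$px_row, m$px_col)]
  pred <- character(nrow(x))
  models <- list()
  for (train_reg in 1:2) {
    test_reg <- 3L - train_reg
    tr <- reg == train_reg & lab > 0
    model <- train_lda(x[tr, , drop = FALSE], ann$names[lab[tr]],
                       lambda = lambda, priors = priors)
    models[[train_reg]] <- model
    te <- reg == test_reg
    pred[te] <- predict(model, x[te, , drop = FALSE])
  }
  pred_id <- match(pred, ann$names)
  img <- scatter_to_image(m, pred_id, fill = 0)
  conf <- confusion_matrix(truth = ann$names[lab[lab > 0]],
                           predicted = pred[lab > 0],
                           classes = ann$names)
  structure(list(predicted = pred, image = img, confusion = conf,
                 models = models, grid = grid,
                 channels = colnames(x)),
            class = "histology_prediction")
}

#' Confusion matrix with per-feature accuracies
#'
#' @param truth,predicted class label vectors over the evaluated pixels.
#' @param classes class ordering for the matrix.
#' @return A \code{confusion_matrix}: \code{counts} (true x predicted),
#'   \code{accuracy} tibble (feature, n, accuracy in percent), and
#'   \code{mean_accuracy} / \code{median_accuracy}.
#' @export
confusion_matrix <- function(truth, predicted, classes = sort(unique(truth))) {
  counts <- table(factor(truth, levels = classes),
                  factor(predicted, levels = classes))
  counts <- unclass(counts)
  n <- rowSums(counts)
  acc <- ifelse(n > 0, 100 * diag(counts) / n, NA_real_)
  structure(list(counts = counts,
                 accuracy = tibble(feature = classes, n = as.integer(n),
                                   accuracy = as.numeric(acc)),
                 mean_accuracy = mean(acc, na.rm = TRUE),
                 median_accuracy = stats::median(acc, na.rm = TRUE)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> %d features; per-feature accuracy mean %.1f%%, median %.1f%%\n",
              nrow(x$counts), x$mean_accuracy, x$median_accuracy))
  print(x$counts)
  invisible(x)
}

#' Channel-ablation comparison of classification accuracy
#'
#' Repeats the checkerboard cross-prediction restricted to a channel subset
#' (e.g. only the hematoxylin & eosin RGB columns) and pairs the per-feature
#' accuracies with the full-panel run.
#'
#' @param m,ann,grid as in \code{\link{cross_predict}}.
#' @param subset character vector of channel names, or \code{"he"} for the
#'   H&E brightfield RGB preset.
#' @param lambda,priors passed through.
#' @return List: \code{full}, \code{subset} (both
#'   \code{histology_prediction}) and \code{comparison} tibble (feature,
#'   accuracy_full, accuracy_subset).
#' @export
ablate_channels <- function(m, ann, grid = checkerboard_partition(ann),
                            subset, lambda = 1e-4,
                            priors = c("empirical", "uniform")) {
  priors <- match.arg(priors)
  if (identical(subset, "he")) {
    subset <- grep("^HE_[RGB]$", channel_names(m), value = TRUE)
    if (!length(subset)) abort("matrix has no HE_R/G/B channels")
  }
  if (!length(subset)) abort("channel subset is empty")
  full <- cross_predict(m, ann, grid, lambda = lambda, priors = priors)
  sub <- cross_predict(m, ann, grid, channels = subset,
                       lambda = lambda, priors = priors)
  comparison <- dplyr::inner_join(
    dplyr::rename(full$confusion$accuracy, accuracy_full = "accuracy"),
    dplyr::rename(sub$confusion$accuracy[c("feature", "accuracy")],
                  accuracy_subset = "accuracy"),
    by = "feature")
  list(full = full, subset = sub, comparison = comparison)
}

#' Apply a trained feature classifier to another sample
#'
#' Predicts every pixel of an unannotated sample with a model trained
#' elsewhere; no accuracy is computed (there is no truth). The channel
#' layouts must match exactly.
#'
#' @param model an \code{lda_model}.
#' @param other_m an \code{mmmp_matrix} from the other sample.
#' @return List: \code{predicted} (class per row), \code{image} (predicted
#'   class-index image; indices into \code{model$classes}).
#' @export
apply_model_cross_sample <- function(model, other_m) {
  x <- channel_matrix(other_m)
  if (!identical(colnames(x), model$channels)) {
    abort("channel layout of other_m does not match the model")
  }
  pred <- predict(model, x)
  img <- scatter_to_image(other_m, match(pred, model$classes), fill = 0)
  list(predicted = pred, image = img)
}
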