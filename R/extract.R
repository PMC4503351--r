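#' Channel panel configuration
#'
#' Orders the columns of the per-pixel data matrix. Each row names one
#' extracted channel: the DAPI counterstain from selected IF cycles, the Cy5
#' antibody channel of every IF cycle, and the R/G/B triple (negated
#' orientation) of every brightfield cycle. With the default 15 IF + 4
#' brightfield layout and DAPI taken from the first and last IF cycles this
#' yields the canonical 15 + 2 + 12 = 29 columns.
#'
#' @param if_stains Cy5 stain names, one per IF cycle (cycle order).
#' @param bf_stains brightfield stain names, one per BF cycle.
#' @param dapi_cycles indices (into the IF cycles) whose DAPI channel is
#'   extracted; default first and last.
#' @return A \code{panel_config} tibble with columns \code{column} (matrix
#'   column name), \code{cycle}, \code{modality}, \code{stain}, \code{role}.
#' @export
panel_config <- function(if_stains = default_if_stains(),
                         bf_stains = default_bf_stains(),
                         dapi_cycles = c(1L, length(if_stains))) {
  n_if <- length(if_stains)
  dapi_cycles <- sort(unique(as.integer(dapi_cycles)))
  if (any(dapi_cycles < 1 | dapi_cycles > n_if)) {
    abort("dapi_cycles must index the IF cycles")
  }
  rows <- dplyr::bind_rows(
    tibble(column = sprintf("DAPI_c%02d", dapi_cycles),
           cycle = dapi_cycles, modality = "IF",
           stain = "DAPI", role = "DAPI"),
    tibble(column = paste0("Cy5_", if_stains),
           cycle = seq_len(n_if), modality = "IF",
           stain = if_stains, role = "Cy5"),
    tibble(column = as.vector(t(outer(bf_stains, c("R", "G", "B"),
                                      paste, sep = "_"))),
           cycle = n_if + rep(seq_along(bf_stains), each = 3),
           modality = "BF",
           stain = rep(bf_stains, each = 3),
           role = rep(c("R", "G", "B"), length(bf_stains)))
  )
  structure(rows, class = c("panel_config", class(rows)))
}

#' Foreground mask of a registered stack
#'
#' Foreground is where the molecular profile is defined in every cycle: the
#' intersection of all per-cycle validity masks, optionally intersected with
#' a tissue test (any channel's min-max-normalised intensity above
#' \code{tissue_threshold}). The default threshold 0 keeps the validity-only
#' rule.
#'
#' @param stack a \code{registered_stack}.
#' @param tissue_threshold normalised intensity in [0, 1); 0 disables the
#'   tissue test.
#' @return Logical matrix of class \code{foreground_mask} with attribute
#'   \code{n_pixels}.
#' @export
compute_foreground <- function(stack, tissue_threshold = 0) {
  stopifnot(inherits(stack, "registered_stack"))
  mask <- Reduce(`&`, stack$validity)
  if (tissue_threshold > 0) {
    tissue <- matrix(FALSE, stack$dims[1], stack$dims[2])
    for (cyc in stack$cycles) {
      for (ch in cyc$channels) {
        r <- range(ch)
        if (r[2] - r[1] <= 0) next
        tissue <- tissue | ((ch - r[1]) / (r[2] - r[1]) > tissue_threshold)
      }
    }
    mask <- mask & tissue
  }
  if (!any(mask)) abort("foreground mask is empty")
  structure(mask, n_pixels = sum(mask), class = c("foreground_mask", "matrix", "array"))
}

#' Build the per-pixel multi-channel data matrix
#'
#' One row per foreground pixel in raster (row-major) order, one column per
#' panel channel, intensities on the native 8-bit scale (brightfield already
#' in the negated orientation). The first two columns \code{px_row},
#' \code{px_col} carry the 1-based pixel coordinates so any column can be
#' scattered back into the image frame.
#'
#' @param stack a \code{registered_stack}.
#' @param mask a \code{\link{compute_foreground}} mask (or any logical
#'   matrix matching the stack dims).
#' @param panel a \code{\link{panel_config}}.
#' @return An \code{mmmp_matrix} tibble with attributes \code{panel} and
#'   \code{dims}.
#' @export
build_matrix <- function(stack, mask = compute_foreground(stack),
                         panel = panel_config()) {
  stopifnot(inherits(stack, "registered_stack"))
  idx <- which(t(mask))                      # raster (row-major) order
  w <- ncol(mask)
  px_row <- (idx - 1L) %/% w + 1L
  px_col <- (idx - 1L) %% w + 1L
  lin <- (px_col - 1L) * nrow(mask) + px_row

  cols <- vector("list", nrow(panel))
  for (k in seq_len(nrow(panel))) {
    p <- panel[k, ]
    if (p$cycle > length(stack$cycles)) {
      abort(paste0("panel channel ", p$column, " refers to missing cycle ", p$cycle))
    }
    cyc <- stack$cycles[[p$cycle]]
    ch_name <- if (p$role == "DAPI") "DAPI" else if (p$role == "Cy5") "Cy5" else p$role
    img <- cyc$channels[[ch_name]]
    if (is.null(img) || cyc$modality != p$modality) {
      abort(paste0("stack has no channel for panel column ", p$column))
    }
    cols[[k]] <- img[lin]
  }
  names(cols) <- panel$column
  out <- tibble(px_row = px_row, px_col = px_col, !!!cols)
  if (!all(is.finite(as.matrix(out)))) abort("non-finite intensity in matrix")
  attr(out, "panel") <- panel
  attr(out, "dims") <- dim(mask)
  class(out) <- c("mmmp_matrix", class(out))
  out
}

#' Construct a pixel matrix from raw components
#'
#' Lower-level constructor used when the channel data do not come from a
#' registered stack (simulation studies, file import).
#'
#' @param channels numeric matrix or data frame, one column per channel.
#' @param coords optional tibble/matrix with pixel (row, col); defaults to a
#'   single-column raster.
#' @param dims canvas c(h, w).
#' @return An \code{mmmp_matrix} tibble.
#' @export
mmmp_matrix <- function(channels, coords = NULL, dims = NULL) {
  channels <- as.data.frame(channels)
  if (is.null(names(channels)) || any(names(channels) == "")) {
    names(channels) <- paste0("ch", seq_along(channels))
  }
  n <- nrow(channels)
  if (is.null(coords)) {
    coords <- tibble(px_row = seq_len(n), px_col = rep(1L, n))
    if (is.null(dims)) dims <- c(n, 1L)
  } else {
    coords <- as.data.frame(coords)
    names(coords) <- c("px_row", "px_col")
    if (is.null(dims)) dims <- c(max(coords$px_row), max(coords$px_col))
  }
  out <- dplyr::bind_cols(as_tibble(coords), as_tibble(channels))
  attr(out, "dims") <- as.integer(dims)
  class(out) <- c("mmmp_matrix", class(out))
  out
}

#' Scatter a matrix column back into the image frame
#'
#' @param m an \code{mmmp_matrix}.
#' @param values numeric vector aligned with the rows of \code{m} (or a
#'   channel name).
#' @param fill background value.
#' @return Numeric matrix in the original canvas frame.
#' @export
scatter_to_image <- function(m, values, fill = NA_real_) {
  dims <- attr(m, "dims")
  if (is.null(dims)) abort("matrix has no recorded canvas dims")
  if (is.character(values)) values <- m[[values]]
  stopifnot(length(values) == nrow(m))
  img <- matrix(fill, dims[1], dims[2])
  img[cbind(m$px_row, m$px_col)] <- values
  img
}
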