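# File interchange: TIFF/PNG images on the 8-bit scale, CSV tables, JSON
# sidecars. Intensities are clipped to [0, 255] only at the file boundary.

clip8 <- function(x) pmin(pmax(x, 0), 255)

#' Write / read a grayscale or RGB image (TIFF or PNG, 0-255 scale)
#'
#' @param image matrix or h x w x 3 array on the 0-255 scale.
#' @param path output path; format chosen by extension (.tif/.tiff/.png).
#' @export
write_image <- function(image, path) {
  x <- clip8(image) / 255
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(x, path)
  } else {
    tiff::writeTIFF(x, path, bits.per.sample = 8L)
  }
  invisible(path)
}

#' @rdname write_image
#' @return \code{read_image()}: the image on the 0-255 scale.
#' @export
read_image <- function(path) {
  x <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  if (length(dim(x)) == 3 && dim(x)[3] == 4) x <- x[, , 1:3]  # drop alpha
  x * 255
}

#' Write a phantom to disk as a cycle image series
#'
#' One TIFF per channel per cycle (IF: DAPI + Cy5; brightfield: a single RGB
#' TIFF written in the conventional bright-background orientation, i.e.
#' negated back from the internal representation), plus a cycle manifest
#' CSV and a ground-truth JSON (feature ids, cycle transforms, seed).
#'
#' @param truth a \code{phantom_truth}.
#' @param dir output directory (created).
#' @return \code{dir}, invisibly.
#' @export
write_phantom <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  for (cyc in truth$cycles) {
    id <- cyc$cycle_id
    if (cyc$modality == "IF") {
      files <- c(DAPI = sprintf("cycle%02d_DAPI.tif", id),
                 Cy5 = sprintf("cycle%02d_Cy5_%s.tif", id, cyc$stain))
      write_image(cyc$channels$DAPI, file.path(dir, files["DAPI"]))
      write_image(cyc$channels$Cy5, file.path(dir, files["Cy5"]))
    } else {
      files <- c(RGB = sprintf("cycle%02d_BF_%s.tif", id, cyc$stain))
      rgb <- simplify2array(cyc$channels[c("R", "G", "B")])
      write_image(negate_brightfield(clip8(rgb)), file.path(dir, files["RGB"]))
    }
    manifest[[id]] <- tibble(cycle = id, modality = cyc$modality,
                             stain = cyc$stain,
                             files = paste(files, collapse = ";"))
  }
  utils::write.csv(dplyr::bind_rows(manifest),
                   file.path(dir, "cycles.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(seed = truth$spec$seed,
         canvas = dim(truth$label),
         feature_ids = truth$feature_ids,
         cycle_transforms = lapply(truth$cycle_transforms, function(tf) {
           list(angle = tf$angle, dr = tf$dr, dc = tf$dc)
         })),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(tibble(value = as.vector(t(truth$label))),
                   file.path(dir, "label_raster.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a phantom cycle series back into memory
#'
#' Brightfield TIFFs (bright background on disk) are negated on read, so the
#' in-memory stack is in the internal dark-background orientation.
#'
#' @param dir directory written by \code{\link{write_phantom}}.
#' @return List of cycle records usable by \code{\link{register_series}}.
#' @export
read_cycle_series <- function(dir) {
  man <- utils::read.csv(file.path(dir, "cycles.csv"), stringsAsFactors = FALSE)
  lapply(seq_len(nrow(man)), function(i) {
    files <- strsplit(man$files[i], ";", fixed = TRUE)[[1]]
    if (man$modality[i] == "IF") {
      list(cycle_id = man$cycle[i], modality = "IF", stain = man$stain[i],
           channels = list(DAPI = read_image(file.path(dir, files[1])),
                           Cy5 = read_image(file.path(dir, files[2]))))
    } else {
      rgb <- negate_brightfield(read_image(file.path(dir, files[1])))
      list(cycle_id = man$cycle[i], modality = "BF", stain = man$stain[i],
           channels = list(R = rgb[, , 1], G = rgb[, , 2], B = rgb[, , 3]))
    }
  })
}

#' Write / read the per-pixel matrix as CSV
#'
#' Header = channel names, first two columns the 1-based pixel coordinates.
#'
#' @param m an \code{mmmp_matrix}.
#' @param path CSV path.
#' @export
write_matrix_csv <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @param dims canvas c(h, w); defaults to the coordinate extent.
#' @export
read_matrix_csv <- function(path, dims = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  out <- as_tibble(df)
  if (is.null(dims)) dims <- c(max(out$px_row), max(out$px_col))
  attr(out, "dims") <- as.integer(dims)
  class(out) <- c("mmmp_matrix", class(out))
  out
}

#' Write / read an annotation as indexed PNG plus JSON legend
#'
#' @param ann an \code{annotation_set}.
#' @param png_path indexed label PNG (label / 255 grayscale).
#' @param legend_path JSON legend mapping index to name and display RGB.
#' @export
write_annotation <- function(ann, png_path, legend_path) {
  png::writePNG(ann$label / 255, png_path)
  jsonlite::write_json(
    purrr::imap(stats::setNames(ann$names, seq_along(ann$names)),
                function(nm, idx) {
                  list(name = nm, color = as.integer(ann$colors[nm, ]))
                }),
    legend_path, auto_unbox = TRUE)
  invisible(png_path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(png_path, legend_path) {
  label <- round(png::readPNG(png_path) * 255)
  legend <- jsonlite::read_json(legend_path)
  ord <- order(as.integer(names(legend)))
  nms <- unname(vapply(legend[ord], function(e) e$name, character(1)))
  cols <- t(vapply(legend[ord], function(e) as.integer(unlist(e$color)),
                   integer(3)))
  annotation_set(label, nms, cols)
}

#' Write a colour map as JSON
#' @param cmap a \code{color_map}.
#' @param path JSON path.
#' @export
write_colormap <- function(cmap, path) {
  jsonlite::write_json(list(stress = cmap$stress, colors = cmap$colors),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a confusion matrix and its per-feature accuracies as CSV
#' @param conf a \code{confusion_matrix}.
#' @param counts_path,accuracy_path CSV paths.
#' @export
write_confusion <- function(conf, counts_path, accuracy_path) {
  utils::write.csv(conf$counts, counts_path)
  utils::write.csv(conf$accuracy, accuracy_path, row.names = FALSE)
  invisible(counts_path)
}
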