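#' Default antibody / histochemistry panel stain names
#'
#' The default panel mirrors a 15-antibody immunofluorescence series (Cy5
#' label, DAPI counterstain) followed by 4 brightfield histochemical stains
#' captured as RGB, the configuration whose extracted matrix has
#' 15 + 2 + 12 = 29 channels.
#'
#' @name panel_defaults
#' @export
default_if_stains <- function(n = 15) {
  stains <- c("Lyve1", "Sparc", "Cd34", "Ace", "Mmp11", "Fzd7", "Cd105",
              "Col4a2", "Ctgf", "bCatenin", "Dkk3", "Cd44", "Desmin",
              "Col1", "Sma")
  if (n > length(stains)) {
    stains <- c(stains, sprintf("IF%02d", seq_len(n - length(stains))))
  }
  stains[seq_len(n)]
}

#' @rdname panel_defaults
#' @param n number of stains requested.
#' @export
default_bf_stains <- function(n = 4) {
  stains <- c("HE", "AlcianBlue", "PAS", "Verhoeff")
  if (n > length(stains)) {
    stains <- c(stains, sprintf("BF%02d", seq_len(n - length(stains))))
  }
  stains[seq_len(n)]
}

phantom_feature_names <- c("background", "ecm", "epithelium", "muscle",
                           "vessel", "nuclei")

#' Default feature-by-channel signature table
#'
#' Mean intensities (0-255) of each synthetic tissue feature in every
#' generated channel. Brightfield channels are expressed in the negated
#' (dark-background) orientation, i.e. higher = more stain: a hematoxylin-rich
#' nucleus that is dark in the raw brightfield image is bright here. Values
#' sketch the qualitative biology of the stains (endothelial markers high in
#' vessels, desmin/SMA in muscle, collagen/SPARC in extracellular matrix,
#' beta-catenin in epithelium, DAPI and hematoxylin in nuclei) with a wide
#' margin between features so that separability is controlled by
#' \code{noise_sd} alone.
#'
#' @param if_stains,bf_stains character vectors of stain names.
#' @return Numeric matrix, rows = features, cols = channels
#'   (\code{DAPI}, one per Cy5 stain, then \code{<stain>_R/_G/_B}).
#' @export
default_signatures <- function(if_stains = default_if_stains(),
                               bf_stains = default_bf_stains()) {
  feats <- phantom_feature_names
  cols <- c("DAPI", if_stains,
            as.vector(t(outer(bf_stains, c("R", "G", "B"), paste, sep = "_"))))
  sig <- matrix(5, length(feats), length(cols), dimnames = list(feats, cols))
  sig["background", ] <- 0
  sig[, "DAPI"] <- c(0, 6, 10, 8, 8, 220)

  cy5 <- list(
    Lyve1 = c(vessel = 150), Sparc = c(ecm = 140, muscle = 40),
    Cd34 = c(vessel = 200), Ace = c(vessel = 110), Mmp11 = c(ecm = 90),
    Fzd7 = c(epithelium = 140), Cd105 = c(vessel = 150),
    Col4a2 = c(vessel = 120, ecm = 50), Ctgf = c(ecm = 110),
    bCatenin = c(epithelium = 200), Dkk3 = c(muscle = 90, epithelium = 30),
    Cd44 = c(epithelium = 120, vessel = 30), Desmin = c(muscle = 200),
    Col1 = c(ecm = 200), Sma = c(muscle = 220, vessel = 90)
  )
  for (s in intersect(if_stains, names(cy5))) {
    sig[names(cy5[[s]]), s] <- cy5[[s]]
  }

  bf <- list(  # negated orientation: rows ecm, epithelium, muscle, vessel, nuclei
    HE         = rbind(ecm = c(70, 110, 90), epithelium = c(60, 90, 70),
                       muscle = c(80, 120, 100), vessel = c(60, 95, 80),
                       nuclei = c(150, 160, 180)),
    AlcianBlue = rbind(ecm = c(18, 25, 30), epithelium = c(40, 90, 140),
                       muscle = c(18, 22, 25), vessel = c(18, 22, 25),
                       nuclei = c(60, 60, 80)),
    PAS        = rbind(ecm = c(60, 40, 50), epithelium = c(130, 90, 110),
                       muscle = c(30, 25, 25), vessel = c(30, 25, 25),
                       nuclei = c(70, 60, 70)),
    Verhoeff   = rbind(ecm = c(25, 22, 22), epithelium = c(20, 20, 20),
                       muscle = c(70, 65, 65), vessel = c(160, 150, 150),
                       nuclei = c(90, 90, 90))
  )
  for (s in intersect(bf_stains, names(bf))) {
    tab <- bf[[s]]
    for (ch in c("R", "G", "B")) {
      sig[rownames(tab), paste(s, ch, sep = "_")] <- tab[, match(ch, c("R", "G", "B"))]
    }
  }
  sig["background", ] <- 0
  sig
}

#' Default phantom feature geometry
#'
#' Parametric primitives standing in for tissue architecture: an ECM field as
#' base layer, smooth-muscle bands, epithelial blobs, lumen (background)
#' blobs, vessel rings (ring interior is lumen), and nuclear disks scattered
#' over tissue. Later entries overwrite earlier ones in the label image.
#' @export
default_features <- function() {
  list(
    ecm        = list(kind = "field"),
    muscle     = list(kind = "bands", n = 2, width = 26),
    epithelium = list(kind = "blobs", n = 3, radius = c(20, 32)),
    background = list(kind = "empty", n = 2, radius = c(10, 16)),
    vessel     = list(kind = "rings", n = 4, radius = c(8, 14), thickness = 4),
    nuclei     = list(kind = "disks", n = 90, radius = c(2.5, 3.5))
  )
}

#' Specification of a synthetic MMMP phantom
#'
#' Bundles everything the generator needs: canvas geometry, the feature set
#' and its channel signatures, per-channel noise, the cycle layout, drift
#' bounds for cycle perturbation, and the tiling parameters. Defaults mirror
#' a 15 IF + 4 brightfield cycle acquisition on a 240 px square canvas.
#'
#' @param canvas integer c(h, w) in pixels.
#' @param features named list of geometry primitives (see
#'   \code{\link{default_features}}).
#' @param signatures feature x channel mean-intensity matrix on the 0-255
#'   scale; see \code{\link{default_signatures}}.
#' @param noise_sd additive Gaussian sd, scalar or named per-channel vector.
#' @param n_if_cycles,n_bf_cycles counts of IF and brightfield cycles.
#' @param if_stains,bf_stains stain names per cycle.
#' @param drift_max maximum per-cycle rigid drift: list(shift = px, angle = deg).
#' @param tile_shape integer c(h, w) of one microscope tile.
#' @param overlap_frac nominal fractional tile overlap, in (0, 0.5).
#' @param jitter_sd stage-jitter sd (px) on tile positions.
#' @param seed integer; every random draw in the phantom flows through it.
#' @return A \code{phantom_spec} object.
#' @export
phantom_spec <- function(canvas = c(240, 240),
                         features = default_features(),
                         if_stains = default_if_stains(n_if_cycles),
                         bf_stains = default_bf_stains(n_bf_cycles),
                         signatures = default_signatures(if_stains, bf_stains),
                         noise_sd = 4,
                         n_if_cycles = 15,
                         n_bf_cycles = 4,
                         drift_max = list(shift = 4, angle = 1.5),
                         tile_shape = c(100, 100),
                         overlap_frac = 0.1,
                         jitter_sd = 2,
                         seed = 1L) {
  if (length(features) == 0) abort("feature_set is empty")
  if (anyDuplicated(names(features))) abort("feature names must be unique")
  if (!(overlap_frac > 0 && overlap_frac < 0.5)) {
    abort("overlap_frac must be in (0, 0.5)")
  }
  if (any(signatures < 0 | signatures > 255)) {
    abort("signature means must lie in [0, 255]")
  }
  if (drift_max$shift < 0 || drift_max$angle < 0) abort("drift_max must be >= 0")
  missing_feat <- setdiff(names(features), rownames(signatures))
  if (length(missing_feat)) {
    abort(paste0("signature table has no row for feature(s): ",
                 paste(missing_feat, collapse = ", ")))
  }
  needed <- c("DAPI", if_stains,
              as.vector(t(outer(bf_stains, c("R", "G", "B"), paste, sep = "_"))))
  missing_ch <- setdiff(needed, colnames(signatures))
  if (length(missing_ch)) {
    abort(paste0("signature table is missing channel(s): ",
                 paste(missing_ch, collapse = ", ")))
  }
  structure(
    list(canvas = as.integer(canvas), features = features,
         signatures = signatures, noise_sd = noise_sd,
         n_if_cycles = as.integer(n_if_cycles),
         n_bf_cycles = as.integer(n_bf_cycles),
         if_stains = if_stains, bf_stains = bf_stains,
         drift_max = drift_max, tile_shape = as.integer(tile_shape),
         overlap_frac = overlap_frac, jitter_sd = jitter_sd,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# --- label-image drawing ----------------------------------------------------

draw_disk <- function(label, ctr, radius, value) {
  h <- nrow(label); w <- ncol(label)
  r0 <- max(1, floor(ctr[1] - radius)); r1 <- min(h, ceiling(ctr[1] + radius))
  c0 <- max(1, floor(ctr[2] - radius)); c1 <- min(w, ceiling(ctr[2] + radius))
  rr <- r0:r1; cc <- c0:c1
  d2 <- outer((rr - ctr[1])^2, (cc - ctr[2])^2, "+")
  sub <- label[rr, cc, drop = FALSE]
  sub[d2 <= radius^2] <- value
  label[rr, cc] <- sub
  label
}

draw_ring <- function(label, ctr, radius, thickness, value, lumen_value) {
  h <- nrow(label); w <- ncol(label)
  r0 <- max(1, floor(ctr[1] - radius)); r1 <- min(h, ceiling(ctr[1] + radius))
  c0 <- max(1, floor(ctr[2] - radius)); c1 <- min(w, ceiling(ctr[2] + radius))
  rr <- r0:r1; cc <- c0:c1
  d2 <- outer((rr - ctr[1])^2, (cc - ctr[2])^2, "+")
  sub <- label[rr, cc, drop = FALSE]
  inner <- max(radius - thickness, 0)
  sub[d2 <= inner^2] <- lumen_value
  sub[d2 <= radius^2 & d2 > inner^2] <- value
  label[rr, cc] <- sub
  label
}

runif_range <- function(n, r) if (length(r) == 1) rep(r, n) else stats::runif(n, r[1], r[2])

draw_label_image <- function(spec) {
  h <- spec$canvas[1]; w <- spec$canvas[2]
  label <- matrix(0L, h, w)
  ids <- phantom_feature_ids(spec)
  for (feat in names(spec$features)) {
    geom <- spec$features[[feat]]
    id <- ids[[feat]]
    switch(geom$kind,
      field = { label[] <- id },
      bands = {
        centers <- stats::runif(geom$n, 1, h)
        for (ctr in centers) {
          r0 <- max(1, round(ctr - geom$width / 2))
          r1 <- min(h, round(ctr + geom$width / 2))
          label[r0:r1, ] <- id
        }
      },
      blobs = ,
      empty = {
        val <- if (geom$kind == "empty") 0L else id
        for (i in seq_len(geom$n)) {
          ctr <- c(stats::runif(1, 1, h), stats::runif(1, 1, w))
          label <- draw_disk(label, ctr, runif_range(1, geom$radius), val)
        }
      },
      rings = {
        for (i in seq_len(geom$n)) {
          rad <- runif_range(1, geom$radius)
          ctr <- c(stats::runif(1, 1 + rad, h - rad), stats::runif(1, 1 + rad, w - rad))
          label <- draw_ring(label, ctr, rad, geom$thickness, id, 0L)
        }
      },
      disks = {
        placed <- 0; tries <- 0
        while (placed < geom$n && tries < geom$n * 20) {
          tries <- tries + 1
          ctr <- c(stats::runif(1, 1, h), stats::runif(1, 1, w))
          at <- label[round(ctr[1]), round(ctr[2])]
          if (at == 0L) next  # nuclei sit on tissue, not in lumen
          label <- draw_disk(label, ctr, runif_range(1, geom$radius), id)
          placed <- placed + 1
        }
      },
      abort(paste0("unknown geometry kind: ", geom$kind))
    )
  }
  label
}

phantom_feature_ids <- function(spec) {
  nm <- names(spec$features)
  ids <- as.list(seq_along(setdiff(nm, "background")))
  names(ids) <- setdiff(nm, "background")
  ids$background <- 0L
  ids
}

# --- phantom generation -----------------------------------------------------

noise_for <- function(spec, channel, n) {
  sd <- spec$noise_sd
  if (!is.null(names(sd))) sd <- if (channel %in% names(sd)) sd[[channel]] else 0
  if (sd <= 0) rep(0, n) else stats::rnorm(n, 0, sd)
}

signature_image <- function(spec, label, channel) {
  feats <- names(spec$features)
  ids <- phantom_feature_ids(spec)
  lut <- numeric(length(feats))
  names(lut) <- feats
  lut[feats] <- spec$signatures[feats, channel]
  # index 1 = label 0 (background)
  by_id <- numeric(length(feats))
  for (f in feats) by_id[ids[[f]] + 1] <- lut[[f]]
  img <- matrix(by_id[label + 1L], nrow(label), ncol(label))
  img + noise_for(spec, channel, length(img))
}

#' Generate a synthetic MMMP phantom with full ground truth
#'
#' Draws the label image from the spec's geometry, then renders every imaging
#' cycle: each IF cycle gets a DAPI and a Cy5 channel, each brightfield cycle
#' an R/G/B triple held internally in the negated (dark-background)
#' orientation. Pixel intensity is the feature's signature mean plus additive
#' Gaussian noise; intensities are kept as doubles and are only clipped to
#' 8-bit on file export. Cycle transforms start as identities and are updated
#' by \code{\link{perturb_cycle}}. Deterministic under the spec's seed.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return A \code{phantom_truth} object: \code{label} (integer feature map),
#'   \code{feature_ids}, \code{cycles} (per-cycle named channel images),
#'   \code{cycle_transforms}, and the originating \code{spec}.
#' @export
make_phantom_core <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    label <- draw_label_image(spec)
    cycles <- vector("list", spec$n_if_cycles + spec$n_bf_cycles)
    for (i in seq_len(spec$n_if_cycles)) {
      cycles[[i]] <- list(
        cycle_id = i, modality = "IF", stain = spec$if_stains[i],
        channels = list(
          DAPI = signature_image(spec, label, "DAPI"),
          Cy5 = signature_image(spec, label, spec$if_stains[i])
        )
      )
    }
    for (j in seq_len(spec$n_bf_cycles)) {
      s <- spec$bf_stains[j]
      cycles[[spec$n_if_cycles + j]] <- list(
        cycle_id = spec$n_if_cycles + j, modality = "BF", stain = s,
        channels = list(
          R = signature_image(spec, label, paste0(s, "_R")),
          G = signature_image(spec, label, paste0(s, "_G")),
          B = signature_image(spec, label, paste0(s, "_B"))
        )
      )
    }
    structure(
      list(spec = spec, label = label,
           feature_ids = phantom_feature_ids(spec),
           cycles = cycles,
           cycle_transforms = replicate(length(cycles), rigid_transform(),
                                        simplify = FALSE)),
      class = "phantom_truth"
    )
  })
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %d x %d canvas, %d features, %d IF + %d BF cycles\n",
              nrow(x$label), ncol(x$label), length(x$feature_ids) - 1,
              x$spec$n_if_cycles, x$spec$n_bf_cycles))
  invisible(x)
}

#' Rigidly perturb one phantom cycle
#'
#' Applies a rigid drift (shift in px, rotation in deg about the canvas
#' centre) to every channel of the cycle, simulating the stage/section
#' misalignment between imaging rounds that registration must undo. The
#' composed true transform is stored in \code{truth$cycle_transforms}.
#'
#' @param truth a \code{phantom_truth}.
#' @param cycle cycle index.
#' @param shift numeric c(dr, dc) in pixels; must satisfy
#'   \code{max(abs(shift)) <= drift_max$shift}.
#' @param angle rotation in degrees; \code{abs(angle) <= drift_max$angle}.
#' @return The updated \code{phantom_truth}.
#' @export
perturb_cycle <- function(truth, cycle, shift = c(0, 0), angle = 0) {
  stopifnot(inherits(truth, "phantom_truth"))
  if (cycle < 1 || cycle > length(truth$cycles)) abort("no such cycle")
  if (max(abs(shift)) > truth$spec$drift_max$shift ||
      abs(angle) > truth$spec$drift_max$angle) {
    abort("requested drift exceeds spec drift_max")
  }
  tf <- rigid_transform(angle, shift[1], shift[2])
  truth$cycles[[cycle]]$channels <- lapply(
    truth$cycles[[cycle]]$channels, warp_rigid, tf = tf, interp = "bilinear")
  truth$cycle_transforms[[cycle]] <-
    compose_transforms(tf, truth$cycle_transforms[[cycle]])
  truth
}

#' Randomly drift every cycle after the first
#'
#' Convenience wrapper over \code{\link{perturb_cycle}}: draws a uniform
#' shift and rotation within the spec's \code{drift_max} for every cycle
#' except the reference (first) one.
#'
#' @param truth a \code{phantom_truth}.
#' @param seed integer seed for the drift draws.
#' @return The updated \code{phantom_truth}.
#' @export
perturb_phantom <- function(truth, seed = truth$spec$seed + 1L) {
  with_seed(seed, {
    for (i in seq_along(truth$cycles)[-1]) {
      sh <- stats::runif(2, -truth$spec$drift_max$shift, truth$spec$drift_max$shift)
      an <- stats::runif(1, -truth$spec$drift_max$angle, truth$spec$drift_max$angle)
      truth <- perturb_cycle(truth, i, sh, an)
    }
    truth
  })
}

#' Cut one phantom cycle into overlapping microscope tiles
#'
#' Lays a grid with nominal fractional overlap over the canvas, adds Gaussian
#' stage jitter (rounded to whole pixels, clamped at the canvas borders),
#' and cuts a grayscale tile at each position: the DAPI channel for IF
#' cycles, the negated-luminance for brightfield cycles. The union of tiles
#' always covers the canvas. True offsets are carried in the layout as
#' \code{truth_row}/\code{truth_col} (phantom-only ground truth).
#'
#' @param truth a \code{phantom_truth}.
#' @param cycle cycle index.
#' @param seed seed for the jitter draws (default derived from the spec seed
#'   and cycle so different cycles jitter differently but reproducibly).
#' @return A \code{tile_set}: \code{tiles} (list of matrices) and
#'   \code{layout} tibble (tile_id, grid_row, grid_col, nominal_row,
#'   nominal_col, truth_row, truth_col).
#' @export
tile_phantom <- function(truth, cycle, seed = truth$spec$seed + 1000L + cycle) {
  stopifnot(inherits(truth, "phantom_truth"))
  if (cycle < 1 || cycle > length(truth$cycles)) abort("no such cycle")
  spec <- truth$spec
  th <- spec$tile_shape[1]; tw <- spec$tile_shape[2]
  h <- spec$canvas[1]; w <- spec$canvas[2]
  if (th > h || tw > w) abort("tile_shape larger than canvas")
  cyc <- truth$cycles[[cycle]]
  img <- if (cyc$modality == "IF") cyc$channels$DAPI else
    (cyc$channels$R + cyc$channels$G + cyc$channels$B) / 3

  grid_starts <- function(extent, tile) {
    step <- max(1L, round(tile * (1 - spec$overlap_frac)))
    n <- ceiling((extent - tile) / step) + 1
    pos <- pmin(1L + (seq_len(n) - 1L) * step, extent - tile + 1L)
    unique(pos)
  }
  rows <- grid_starts(h, th); cols <- grid_starts(w, tw)
  layout <- tidyr::expand_grid(grid_row = seq_along(rows), grid_col = seq_along(cols))
  layout$nominal_row <- rows[layout$grid_row]
  layout$nominal_col <- cols[layout$grid_col]
  with_seed(seed, {
    jit <- function(nom, extent, tile) {
      if (spec$jitter_sd <= 0) return(nom)
      pmin(pmax(nom + round(stats::rnorm(length(nom), 0, spec$jitter_sd)), 1L),
           extent - tile + 1L)
    }
    layout$truth_row <- jit(layout$nominal_row, h, th)
    layout$truth_col <- jit(layout$nominal_col, w, tw)
  })
  layout <- dplyr::mutate(layout, tile_id = dplyr::row_number(),
                          .before = 1)
  tiles <- purrr::pmap(layout, function(truth_row, truth_col, ...) {
    img[truth_row:(truth_row + th - 1), truth_col:(truth_col + tw - 1)]
  })
  tile_set(tiles, layout, cycle_id = cycle, sample_id = "phantom")
}

#' Construct a tile set
#'
#' @param tiles list of equally-shaped grayscale matrices.
#' @param layout tibble with at least tile_id, grid_row, grid_col,
#'   nominal_row, nominal_col.
#' @param cycle_id,sample_id identifiers carried through to stitching.
#' @return A \code{tile_set}.
#' @export
tile_set <- function(tiles, layout, cycle_id = 1L, sample_id = "sample") {
  stopifnot(length(tiles) >= 1)
  dims <- vapply(tiles, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort("all tiles must have the same shape")
  }
  if (anyDuplicated(layout[c("grid_row", "grid_col")])) {
    abort("layout grid positions must be unique")
  }
  structure(list(tiles = tiles, layout = as_tibble(layout),
                 cycle_id = cycle_id, sample_id = sample_id),
            class = "tile_set")
}
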