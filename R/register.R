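#' Negate a brightfield RGB image
#'
#' Transmitted-light histochemistry is acquired bright-background; negation
#' (v -> 255 - v on each 8-bit channel) puts stain where the signal is, so
#' that brightfield cycles are compatible with the fluorescence-style
#' stitching and registration machinery.
#'
#' @param image h x w x 3 array (or matrix) on the 0-255 scale.
#' @return The negated image, same shape.
#' @export
negate_brightfield <- function(image) {
  if (min(image) < 0 || max(image) > 255) {
    abort("negate_brightfield expects 8-bit (0-255) channel values")
  }
  255 - image
}

#' Extract the registration fiducial from one cycle image
#'
#' IF cycles use the DAPI channel (nuclei light up in every round, making
#' DAPI the natural cross-cycle landmark); brightfield cycles use the
#' luminance of the negated RGB. Either is min-max rescaled to [0, 1].
#'
#' @param cycle a cycle record: list with \code{modality} ("IF"/"BF") and
#'   \code{channels} (named list: DAPI/Cy5 or R/G/B in negated orientation).
#' @return Grayscale matrix in [0, 1].
#' @export
extract_fiducial <- function(cycle) {
  img <- switch(cycle$modality,
    IF = cycle$channels$DAPI,
    BF = (cycle$channels$R + cycle$channels$G + cycle$channels$B) / 3,
    abort("modality must be 'IF' or 'BF'")
  )
  if (is.null(img)) abort("cycle is missing its fiducial channel")
  rescale01(img)
}

# Normalised cross-correlation of two images over their joint valid region.
ncc <- function(a, b, valid = NULL) {
  if (!is.null(valid)) { a <- a[valid]; b <- b[valid] }
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa == 0 || sb == 0) return(0)
  mean((a - mean(a)) * (b - mean(b))) / (sa * sb)
}

#' Rigid registration of one image pair
#'
#' Coarse-to-fine search over rotation (about the image centre) with the
#' translation at each candidate angle recovered by sub-pixel phase
#' correlation; the candidate maximising the normalised cross-correlation of
#' the warped moving image against the fixed image wins, and the rotation is
#' refined by parabolic interpolation over the fine grid. Returns the
#' transform that maps the moving image onto the fixed image, flagged when
#' the final similarity falls below \code{min_similarity}.
#'
#' @param fixed,moving same-shaped grayscale matrices.
#' @param rot_range half-width of the rotation search (deg); 0 restricts the
#'   search to pure translation.
#' @param coarse_step,fine_step rotation grid steps (deg).
#' @param min_similarity NCC below which the result is flagged.
#' @return A \code{\link{rigid_transform}} with attribute \code{similarity}.
#' @export
rigid_register_pair <- function(fixed, moving, rot_range = 4,
                                coarse_step = 0.5, fine_step = 0.05,
                                min_similarity = 0.5) {
  stopifnot(all(dim(fixed) == dim(moving)))
  try_angle <- function(angle) {
    rot <- if (angle == 0) moving else
      warp_rigid(moving, rigid_transform(angle = angle))
    pc <- phase_correlate(rot, fixed)
    tf <- rigid_transform(angle = angle, dr = pc$shift[1], dc = pc$shift[2])
    warped <- warp_rigid(moving, tf)
    valid <- warp_validity(dim(fixed), tf)
    list(tf = tf, score = ncc(fixed, warped, valid))
  }
  angles <- if (rot_range > 0) seq(-rot_range, rot_range, by = coarse_step) else 0
  coarse <- lapply(angles, try_angle)
  best_i <- which.max(vapply(coarse, `[[`, numeric(1), "score"))
  best <- coarse[[best_i]]
  if (rot_range > 0 && fine_step < coarse_step) {
    fine_angles <- seq(best$tf$angle - coarse_step, best$tf$angle + coarse_step,
                       by = fine_step)
    fine <- lapply(fine_angles, try_angle)
    scores <- vapply(fine, `[[`, numeric(1), "score")
    fi <- which.max(scores)
    best <- fine[[fi]]
    # parabolic refinement of the rotation angle over the fine grid
    if (fi > 1 && fi < length(fine_angles)) {
      y0 <- scores[fi - 1]; y1 <- scores[fi]; y2 <- scores[fi + 1]
      den <- y0 - 2 * y1 + y2
      if (abs(den) > .Machine$double.eps) {
        a_ref <- fine_angles[fi] + 0.5 * (y0 - y2) / den * fine_step
        cand <- try_angle(a_ref)
        if (cand$score >= best$score) best <- cand
      }
    }
  }
  tf <- best$tf
  tf$flagged <- best$score < min_similarity
  attr(tf, "similarity") <- best$score
  tf
}

#' Register a full multi-cycle series into the first-IF frame
#'
#' Implements the chained alignment scheme of a cyclic staining experiment:
#' (1) IF cycles are registered sequentially on their DAPI fiducials, each to
#' its predecessor, and composed into the first IF frame; (2) brightfield
#' cycles are chained among themselves on their negated-RGB luminance; (3)
#' the first brightfield cycle is bridged rigidly to the last IF cycle (the
#' hematoxylin-rich negated image resembles the DAPI pattern, which is what
#' makes this bridge work); (4) all composed transforms are applied to every
#' channel of every cycle, with validity masks marking pixels whose value is
#' interpolated rather than filled.
#'
#' @param cycles list of cycle records (\code{modality}, \code{channels});
#'   IF cycles must precede the contiguous block of BF cycles.
#' @param rot_range,coarse_step,fine_step,min_similarity passed to
#'   \code{\link{rigid_register_pair}}.
#' @param on_low_similarity \code{"abort"} (default, names the offending
#'   cycle pair) or \code{"flag"}.
#' @return A \code{registered_stack}: \code{cycles} (aligned channels),
#'   \code{transforms} (per-cycle \code{rigid_transform} into the reference
#'   frame; identity for cycle 1), \code{validity} (per-cycle logical masks).
#' @export
register_series <- function(cycles, rot_range = 4, coarse_step = 0.5,
                            fine_step = 0.05, min_similarity = 0.2,
                            on_low_similarity = c("abort", "flag")) {
  on_low_similarity <- match.arg(on_low_similarity)
  mods <- vapply(cycles, `[[`, character(1), "modality")
  if (mods[1] != "IF") abort("the series must start with an IF cycle")
  if (is.unsorted(match(mods, c("IF", "BF")))) {
    abort("brightfield cycles must be contiguous after the IF cycles")
  }
  n <- length(cycles)
  fid <- lapply(cycles, extract_fiducial)
  dims <- dim(fid[[1]])

  reg <- function(i_fixed, i_moving) {
    tf <- rigid_register_pair(fid[[i_fixed]], fid[[i_moving]],
                              rot_range = rot_range, coarse_step = coarse_step,
                              fine_step = fine_step,
                              min_similarity = min_similarity)
    if (tf$flagged && on_low_similarity == "abort") {
      abort(sprintf("registration of cycle %d to cycle %d fell below the similarity threshold (NCC = %.3f)",
                    i_moving, i_fixed, attr(tf, "similarity")))
    }
    tf
  }

  transforms <- vector("list", n)
  transforms[[1]] <- rigid_transform()
  if_idx <- which(mods == "IF"); bf_idx <- which(mods == "BF")
  for (i in if_idx[-1]) {
    transforms[[i]] <- compose_transforms(transforms[[i - 1]], reg(i - 1, i))
  }
  if (length(bf_idx)) {
    bridge <- reg(max(if_idx), bf_idx[1])
    transforms[[bf_idx[1]]] <- compose_transforms(transforms[[max(if_idx)]], bridge)
    for (i in bf_idx[-1]) {
      transforms[[i]] <- compose_transforms(transforms[[i - 1]], reg(i - 1, i))
    }
  }

  aligned <- vector("list", n); validity <- vector("list", n)
  for (i in seq_len(n)) {
    tf <- transforms[[i]]
    aligned[[i]] <- cycles[[i]]
    aligned[[i]]$channels <- lapply(cycles[[i]]$channels, warp_rigid, tf = tf)
    validity[[i]] <- warp_validity(dims, tf)
  }
  structure(list(cycles = aligned, transforms = transforms,
                 validity = validity, dims = dims),
            class = "registered_stack")
}

#' @export
print.registered_stack <- function(x, ...) {
  mods <- vapply(x$cycles, `[[`, character(1), "modality")
  cat(sprintf("<registered_stack> %d cycles (%d IF, %d BF), %d x %d\n",
              length(x$cycles), sum(mods == "IF"), sum(mods == "BF"),
              x$dims[1], x$dims[2]))
  invisible(x)
}

#' Wrap an unperturbed phantom as an identity-registered stack
#'
#' Convenience for analyses that start downstream of registration: treats
#' the phantom's cycles as already aligned (all transforms identity, full
#' validity).
#'
#' @param truth a \code{phantom_truth}.
#' @return A \code{registered_stack}.
#' @export
as_registered_stack <- function(truth) {
  stopifnot(inherits(truth, "phantom_truth"))
  dims <- dim(truth$label)
  structure(list(
    cycles = truth$cycles,
    transforms = replicate(length(truth$cycles), rigid_transform(), simplify = FALSE),
    validity = replicate(length(truth$cycles), matrix(TRUE, dims[1], dims[2]),
                         simplify = FALSE),
    dims = dims), class = "registered_stack")
}
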