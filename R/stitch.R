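# Phase correlation between two same-shaped images.
# Returns the (dr, dc) shift such that  b(x) ~= a(x - shift), with parabolic
# sub-pixel refinement of the correlation peak. The circular wrap ambiguity
# (shift is only defined modulo the image size) is resolved per axis toward
# `expect`, i.e. the returned shift is the wrap candidate closest to it.
phase_surface <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  Fa <- stats::fft(a); Fb <- stats::fft(b)
  cross <- Fb * Conj(Fa)
  mag <- Mod(cross)
  cross <- cross / pmax(mag, .Machine$double.eps)
  Re(stats::fft(cross, inverse = TRUE)) / length(a)
}

# Parabolic sub-pixel refinement of a peak of the correlation surface r,
# then wrap resolution toward `expect`.
surface_peak_shift <- function(r, peak, expect = c(0, 0)) {
  sub <- function(i, n, along) {
    # parabolic interpolation through the peak and its circular neighbours
    idx <- function(k) ((k - 1) %% n) + 1
    if (along == 1) {
      y0 <- r[idx(i - 1), peak[2]]; y1 <- r[i, peak[2]]; y2 <- r[idx(i + 1), peak[2]]
    } else {
      y0 <- r[peak[1], idx(i - 1)]; y1 <- r[peak[1], i]; y2 <- r[peak[1], idx(i + 1)]
    }
    den <- y0 - 2 * y1 + y2
    d <- if (abs(den) < .Machine$double.eps) 0 else 0.5 * (y0 - y2) / den
    max(min(d, 0.5), -0.5)
  }
  shift <- c(peak[1] - 1 + sub(peak[1], nrow(r), 1),
             peak[2] - 1 + sub(peak[2], ncol(r), 2))
  n <- dim(r)
  shift <- shift - n * round((shift - expect) / n)
  list(shift = shift, score = r[peak[1], peak[2]])
}

phase_correlate <- function(a, b, expect = c(0, 0)) {
  r <- phase_surface(a, b)
  peak <- arrayInd(which.max(r), dim(r))
  surface_peak_shift(r, peak, expect)
}

# NCC of the overlapping region of a and b at integer shift s
# (convention: b(x) ~= a(x - s)).
ncc_at_shift <- function(a, b, s) {
  n <- dim(a)
  rlo <- max(1, 1 + s[1]); rhi <- min(n[1], n[1] + s[1])
  clo <- max(1, 1 + s[2]); chi <- min(n[2], n[2] + s[2])
  if (rhi - rlo < 3 || chi - clo < 3) return(-Inf)
  rr <- rlo:rhi; cc <- clo:chi
  ncc(a[rr - s[1], cc - s[2], drop = FALSE], b[rr, cc, drop = FALSE])
}

# Estimate the displacement (origin of B minus origin of A) for one adjacent
# tile pair from their overlap strips. `axis` is 1 when B is below A, 2 when
# B is right of A. Returns NULL when an overlap strip has no variance.
pair_displacement <- function(tile_a, tile_b, axis, strip, prior_px) {
  th <- nrow(tile_a); tw <- ncol(tile_a)
  if (axis == 2) {
    sa <- tile_a[, (tw - strip + 1):tw, drop = FALSE]
    sb <- tile_b[, 1:strip, drop = FALSE]
    nominal <- c(0, tw - strip)
    expect_d <- c(0, tw - prior_px)
  } else {
    sa <- tile_a[(th - strip + 1):th, , drop = FALSE]
    sb <- tile_b[1:strip, , drop = FALSE]
    nominal <- c(th - strip, 0)
    expect_d <- c(th - prior_px, 0)
  }
  if (stats::sd(sa) == 0 || stats::sd(sb) == 0) return(NULL)
  expect <- nominal - expect_d
  r <- phase_surface(sa, sb)
  n <- dim(r)
  # admissible integer shifts: a window around the prior-implied shift
  win <- strip - prior_px
  cand_r <- round(expect[1]) + seq(-win, win)
  cand_c <- round(expect[2]) + seq(-win, win)
  idx_r <- unique((cand_r %% n[1]) + 1L)
  idx_c <- unique((cand_c %% n[2]) + 1L)
  sub <- r[idx_r, idx_c, drop = FALSE]
  # validate the strongest in-window peaks by direct overlap correlation
  k <- min(5L, length(sub))
  ord <- order(sub, decreasing = TRUE)[seq_len(k)]
  best <- NULL
  for (o in ord) {
    p <- arrayInd(o, dim(sub))
    peak <- c(idx_r[p[1]], idx_c[p[2]])
    sh <- surface_peak_shift(r, peak, expect)
    score <- ncc_at_shift(sa, sb, round(sh$shift))
    if (is.null(best) || score > best$score) {
      best <- list(shift = sh$shift, score = score)
    }
  }
  if (best$score < 0.9) {
    # the phase peak was diluted (tiny or low-texture overlap): fall back to
    # scoring every admissible integer shift directly
    grid <- expand.grid(sr = cand_r, sc = cand_c)
    scores <- mapply(function(sr, sc) ncc_at_shift(sa, sb, c(sr, sc)),
                     grid$sr, grid$sc)
    top <- which.max(scores)
    if (is.finite(scores[top]) && scores[top] > best$score) {
      s0 <- c(grid$sr[top], grid$sc[top])
      refine <- function(axis) {
        sm <- s0; sp <- s0
        sm[axis] <- sm[axis] - 1; sp[axis] <- sp[axis] + 1
        y0 <- ncc_at_shift(sa, sb, sm); y1 <- scores[top]
        y2 <- ncc_at_shift(sa, sb, sp)
        den <- y0 - 2 * y1 + y2
        if (!is.finite(y0) || !is.finite(y2) ||
            abs(den) < .Machine$double.eps) return(0)
        max(min(0.5 * (y0 - y2) / den, 0.5), -0.5)
      }
      best <- list(shift = s0 + c(refine(1), refine(2)), score = scores[top])
    }
  }
  list(d = nominal - best$shift, score = best$score)
}

#' Stitch a tile set into one canvas image
#'
#' Estimates the translation between every pair of grid-adjacent tiles by
#' phase correlation of their overlap strips (strip width set by the overlap
#' prior plus a search margin), reconciles all tile offsets globally by
#' least squares over the pairwise constraints anchored at the first tile,
#' and fuses the tiles with linear feather blending (per-pixel weights
#' proportional to the distance from the tile edge). Pairs whose overlap
#' strip has zero variance are flagged and fall back to the displacement
#' implied by the nominal layout.
#'
#' @param tiles a \code{\link{tile_set}}.
#' @param overlap_prior assumed tile overlap; a percentage of the tile edge
#'   by default (\code{units = "percent"}), or pixels.
#' @param units \code{"percent"} or \code{"px"}.
#' @param margin extra strip width (px) beyond the prior, accommodating
#'   stage jitter and a wrong prior.
#' @return A \code{stitch_result}: \code{canvas}, \code{offsets} tibble
#'   (continuous, 1-based canvas positions of each tile's top-left corner),
#'   \code{chosen_overlap}, \code{pair_flags}.
#' @export
stitch_tiles <- function(tiles, overlap_prior = 10, units = c("percent", "px"),
                         margin = 16) {
  stopifnot(inherits(tiles, "tile_set"))
  units <- match.arg(units)
  th <- nrow(tiles$tiles[[1]]); tw <- ncol(tiles$tiles[[1]])
  if (units == "percent") {
    if (!(overlap_prior > 0 && overlap_prior < 50)) {
      abort("overlap_prior (percent) must be in (0, 50)")
    }
    prior_px <- round(c(th, tw) * overlap_prior / 100)
  } else {
    prior_px <- rep(round(overlap_prior), 2)
  }
  lay <- tiles$layout
  n <- nrow(lay)
  if (n == 1) {
    off <- dplyr::mutate(lay[c("tile_id", "grid_row", "grid_col")],
                         row = 1, col = 1, fallback = FALSE)
    return(structure(list(canvas = tiles$tiles[[1]], offsets = off,
                          chosen_overlap = overlap_prior, pair_flags = 0L,
                          candidate_offsets = NULL),
                     class = "stitch_result"))
  }

  # pairwise constraints between grid neighbours
  pairs <- list(); flags <- 0L
  key <- paste(lay$grid_row, lay$grid_col)
  find <- function(r, c) match(paste(r, c), key)
  for (i in seq_len(n)) {
    for (axis in 1:2) {
      j <- if (axis == 1) find(lay$grid_row[i] + 1, lay$grid_col[i])
           else find(lay$grid_row[i], lay$grid_col[i] + 1)
      if (is.na(j)) next
      strip <- min(prior_px[axis] + margin, if (axis == 1) th else tw)
      est <- pair_displacement(tiles$tiles[[i]], tiles$tiles[[j]], axis, strip,
                               prior_px[axis])
      if (is.null(est)) {
        flags <- flags + 1L
        d <- c(lay$nominal_row[j] - lay$nominal_row[i],
               lay$nominal_col[j] - lay$nominal_col[i])
        pairs[[length(pairs) + 1]] <- list(i = i, j = j, d = d, score = 0.05,
                                           fallback = TRUE)
      } else {
        pairs[[length(pairs) + 1]] <- list(i = i, j = j, d = est$d,
                                           score = max(est$score, 0.01),
                                           fallback = FALSE)
      }
    }
  }

  # Weighted least squares: minimise sum over pairs of
  # w_p ||o_j - o_i - d_p||^2 with o_1 anchored. Weights start from the
  # pairwise correlation scores (a near-zero score means the overlap carried
  # no usable texture) and are sharpened by two Huber-style reweighting
  # passes so an isolated bad pair cannot drag its tiles away.
  np <- length(pairs)
  A <- matrix(0, np + 1, n)
  br <- numeric(np + 1); bc <- numeric(np + 1)
  w <- numeric(np + 1)
  for (p in seq_len(np)) {
    A[p, pairs[[p]]$i] <- -1; A[p, pairs[[p]]$j] <- 1
    br[p] <- pairs[[p]]$d[1]; bc[p] <- pairs[[p]]$d[2]
    w[p] <- pairs[[p]]$score
  }
  A[np + 1, 1] <- 1; w[np + 1] <- 1  # anchor
  for (iter in 1:3) {
    sw <- sqrt(w)
    fit_r <- stats::lsfit(A * sw, br * sw, intercept = FALSE)$coefficients
    fit_c <- stats::lsfit(A * sw, bc * sw, intercept = FALSE)$coefficients
    res <- sqrt((A %*% fit_r - br)^2 + (A %*% fit_c - bc)^2)
    w[seq_len(np)] <- w[seq_len(np)] * pmin(1, 2 / pmax(res[seq_len(np)], 1e-9))
  }
  off_r <- fit_r - min(fit_r) + 1
  off_c <- fit_c - min(fit_c) + 1

  canvas <- blend_tiles(tiles$tiles, round(off_r), round(off_c), th, tw)
  off <- tibble(tile_id = lay$tile_id, grid_row = lay$grid_row,
                grid_col = lay$grid_col, row = off_r, col = off_c,
                fallback = FALSE)
  structure(list(canvas = canvas, offsets = off,
                 chosen_overlap = overlap_prior, pair_flags = flags,
                 candidate_offsets = NULL),
            class = "stitch_result")
}

# Feathered linear blending: weight = distance to nearest tile edge (>= 1).
blend_tiles <- function(tiles, off_r, off_c, th, tw) {
  H <- max(off_r) + th - 1; W <- max(off_c) + tw - 1
  acc <- matrix(0, H, W); wacc <- matrix(0, H, W)
  wr <- pmin(seq_len(th), rev(seq_len(th)))
  wc <- pmin(seq_len(tw), rev(seq_len(tw)))
  wt <- outer(wr, wc, pmin)
  for (k in seq_along(tiles)) {
    rr <- off_r[k]:(off_r[k] + th - 1); cc <- off_c[k]:(off_c[k] + tw - 1)
    acc[rr, cc] <- acc[rr, cc] + tiles[[k]] * wt
    wacc[rr, cc] <- wacc[rr, cc] + wt
  }
  acc / pmax(wacc, 1e-12)
}

#' @export
print.stitch_result <- function(x, ...) {
  cat(sprintf("<stitch_result> %d x %d canvas from %d tiles (overlap prior %s)\n",
              nrow(x$canvas), ncol(x$canvas), nrow(x$offsets),
              paste(x$chosen_overlap, collapse = "/")))
  invisible(x)
}

#' Consensus stitching over several overlap priors
#'
#' Runs \code{\link{stitch_tiles}} once per overlap prior, forms the
#' per-tile consensus offset as the coordinate-wise median across runs, and
#' keeps the run whose offsets have the smallest summed Euclidean distance
#' to that consensus. Ties go to the smallest prior.
#'
#' @param tiles a \code{\link{tile_set}}.
#' @param overlap_priors numeric vector of priors (default the classic
#'   5 / 8 / 10 percent).
#' @param units,margin passed to \code{\link{stitch_tiles}}.
#' @return The selected \code{stitch_result}, with \code{chosen_overlap} set
#'   to the winning prior, \code{candidate_offsets} holding every run's
#'   offsets, and \code{consensus_distance} the per-run distances.
#' @export
consensus_stitch <- function(tiles, overlap_priors = c(5, 8, 10),
                             units = c("percent", "px"), margin = 16) {
  if (length(overlap_priors) < 2) abort("need at least 2 overlap priors")
  units <- match.arg(units)
  runs <- lapply(overlap_priors, function(p) {
    stitch_tiles(tiles, overlap_prior = p, units = units, margin = margin)
  })
  offs <- lapply(runs, function(r) as.matrix(r$offsets[c("row", "col")]))
  cons <- apply(simplify2array(offs), c(1, 2), stats::median)
  dist_to_cons <- vapply(offs, function(o) {
    sum(sqrt(rowSums((o - cons)^2)))
  }, numeric(1))
  # argmin with ties broken toward the smallest prior
  ord <- order(dist_to_cons, overlap_priors)
  best <- runs[[ord[1]]]
  best$chosen_overlap <- overlap_priors[ord[1]]
  best$candidate_offsets <- purrr::map2(overlap_priors, runs, function(p, r) {
    dplyr::mutate(r$offsets, overlap_prior = p)
  })
  best$consensus_distance <- tibble(overlap_prior = overlap_priors,
                                    distance = dist_to_cons)
  best
}

#' Centred crop (or pad) of a stitched canvas
#'
#' @param x a \code{stitch_result} or a numeric matrix.
#' @param size output edge length in pixels (square output).
#' @param background fill value used when padding a smaller canvas.
#' @return A \code{size} x \code{size} matrix.
#' @export
crop_canvas <- function(x, size = 2300, background = 0) {
  img <- if (inherits(x, "stitch_result")) x$canvas else x
  h <- nrow(img); w <- ncol(img)
  out <- matrix(background, size, size)
  # source window (centred) and destination window
  src_r <- max(1, floor((h - size) / 2) + 1); n_r <- min(h, size)
  src_c <- max(1, floor((w - size) / 2) + 1); n_c <- min(w, size)
  dst_r <- max(1, floor((size - h) / 2) + 1)
  dst_c <- max(1, floor((size - w) / 2) + 1)
  out[dst_r:(dst_r + n_r - 1), dst_c:(dst_c + n_c - 1)] <-
    img[src_r:(src_r + n_r - 1), src_c:(src_c + n_c - 1)]
  out
}

#' Track tissue cores across cycles from their centroid tables
#'
#' For each cycle, estimates one global 2-D translation to the reference
#' (first) cycle by aligning centroid means and refining on matched pairs,
#' then matches every core to its nearest reference centroid. Cores whose
#' nearest reference centroid is farther than half the minimum inter-core
#' spacing are reported as dropped; two cores claiming the same reference
#' centroid is an error.
#'
#' @param centroids tibble with columns \code{cycle}, \code{core},
#'   \code{row}, \code{col} (one row per detected core per cycle).
#' @return List with \code{shifts} (tibble: cycle, dr, dc) and
#'   \code{matches} (tibble: cycle, core, ref_core, distance, dropped).
#' @export
align_core_grid <- function(centroids) {
  centroids <- as_tibble(centroids)
  stopifnot(all(c("cycle", "core", "row", "col") %in% names(centroids)))
  cyc_ids <- sort(unique(centroids$cycle))
  ref <- centroids[centroids$cycle == cyc_ids[1], ]
  if (nrow(ref) < 1) abort("reference cycle has no cores")
  refm <- as.matrix(ref[c("row", "col")])
  spacing <- if (nrow(ref) > 1) min(stats::dist(refm)) else Inf
  thr <- spacing / 2

  shifts <- list(); matches <- list()
  for (cy in cyc_ids) {
    cur <- centroids[centroids$cycle == cy, ]
    curm <- as.matrix(cur[c("row", "col")])
    shift <- colMeans(refm) - colMeans(curm)
    for (pass in 1:2) {
      moved <- sweep(curm, 2, shift, "+")
      d <- as.matrix(stats::dist(rbind(moved, refm)))[seq_len(nrow(moved)),
                                                      nrow(moved) + seq_len(nrow(refm)),
                                                      drop = FALSE]
      nn <- apply(d, 1, which.min)
      nnd <- d[cbind(seq_along(nn), nn)]
      keep <- nnd <= thr
      if (pass == 1 && any(keep)) {
        shift <- colMeans(refm[nn[keep], , drop = FALSE] - curm[keep, , drop = FALSE])
      }
    }
    dup <- nn[keep][duplicated(nn[keep])]
    if (length(dup)) {
      abort(paste0("ambiguous core matching in cycle ", cy,
                   ": reference core(s) ", paste(unique(dup), collapse = ", "),
                   " claimed by multiple cores"))
    }
    shifts[[length(shifts) + 1]] <- tibble(cycle = cy, dr = shift[1], dc = shift[2])
    matches[[length(matches) + 1]] <- tibble(
      cycle = cy, core = cur$core,
      ref_core = ifelse(keep, ref$core[nn], NA_integer_),
      distance = nnd, dropped = !keep)
  }
  list(shifts = dplyr::bind_rows(shifts), matches = dplyr::bind_rows(matches))
}
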