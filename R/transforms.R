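#' Rigid (rotation + translation) image transform
#'
#' A rigid transform maps pixel coordinates \code{p = (row, col)} to
#' \code{R(p - c) + c + t}, where \code{R} is a rotation by \code{angle}
#' degrees (counter-clockwise in image axes), \code{c} the image centre and
#' \code{t = (dr, dc)} a translation in pixels. All cross-cycle alignment in
#' the package is expressed with these transforms; rotation is always about
#' the canvas centre so that transforms for a given canvas compose cleanly.
#'
#' @param angle rotation in degrees.
#' @param dr,dc translation in pixels along rows / columns.
#' @param flagged logical; set by registration when the similarity score of
#'   the pair that produced the transform was below threshold.
#' @return An object of class \code{rigid_transform}.
#' @export
rigid_transform <- function(angle = 0, dr = 0, dc = 0, flagged = FALSE) {
  stopifnot(is.numeric(angle), is.numeric(dr), is.numeric(dc))
  structure(
    list(angle = as.numeric(angle), dr = as.numeric(dr), dc = as.numeric(dc),
         flagged = isTRUE(flagged)),
    class = "rigid_transform"
  )
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> angle = %.4f deg, shift = (%.3f, %.3f) px%s\n",
              x$angle, x$dr, x$dc, if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

rot_mat <- function(angle_deg) {
  a <- angle_deg * pi / 180
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
}

#' Compose two rigid transforms
#'
#' \code{compose_transforms(a, b)} is the transform that applies \code{b}
#' first, then \code{a} (function composition \code{a \%o\% b}).
#'
#' @param a,b \code{rigid_transform} objects.
#' @return A \code{rigid_transform}.
#' @export
compose_transforms <- function(a, b) {
  Ra <- rot_mat(a$angle)
  t_new <- Ra %*% c(b$dr, b$dc) + c(a$dr, a$dc)
  rigid_transform(a$angle + b$angle, t_new[1], t_new[2],
                  flagged = a$flagged || b$flagged)
}

#' Invert a rigid transform
#' @param tf a \code{rigid_transform}.
#' @return The inverse \code{rigid_transform}.
#' @export
invert_transform <- function(tf) {
  Rinv <- rot_mat(-tf$angle)
  t_new <- -Rinv %*% c(tf$dr, tf$dc)
  rigid_transform(-tf$angle, t_new[1], t_new[2], flagged = tf$flagged)
}

#' Apply a rigid transform to an image
#'
#' Resamples \code{image} so that the output at coordinate \code{p} holds the
#' input value at \code{T^{-1}(p)}. Output pixels whose pre-image falls
#' outside the source canvas take \code{fill}; \code{warp_validity()} returns
#' the corresponding in-bounds mask.
#'
#' @param image numeric matrix (grayscale) or h x w x c array.
#' @param tf a \code{rigid_transform}.
#' @param interp \code{"bilinear"} for intensities, \code{"nearest"} for
#'   label images.
#' @param fill value for pixels mapped from outside the canvas.
#' @return Transformed image with the same dimensions.
#' @export
warp_rigid <- function(image, tf, interp = c("bilinear", "nearest"), fill = 0) {
  interp <- match.arg(interp)
  if (length(dim(image)) == 3) {
    out <- image
    for (ch in seq_len(dim(image)[3])) {
      out[, , ch] <- warp_rigid(image[, , ch], tf, interp = interp, fill = fill)
    }
    return(out)
  }
  h <- nrow(image); w <- ncol(image)
  src <- inverse_coords(h, w, tf)
  sr <- src$r; sc <- src$c
  out <- matrix(fill, h, w)
  if (interp == "nearest") {
    ri <- round(sr); ci <- round(sc)
    ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
    out[ok] <- image[cbind(ri[ok], ci[ok])]
  } else {
    r0 <- floor(sr); c0 <- floor(sc)
    fr <- sr - r0; fc <- sc - c0
    ok <- r0 >= 1 & r0 + 1 <= h & c0 >= 1 & c0 + 1 <= w
    # clamp coordinates that sit exactly on the last row/col
    edge <- sr >= 1 & sr <= h & sc >= 1 & sc <= w & !ok
    i00 <- cbind(r0[ok], c0[ok]); i01 <- cbind(r0[ok], c0[ok] + 1)
    i10 <- cbind(r0[ok] + 1, c0[ok]); i11 <- cbind(r0[ok] + 1, c0[ok] + 1)
    out[ok] <- image[i00] * (1 - fr[ok]) * (1 - fc[ok]) +
      image[i01] * (1 - fr[ok]) * fc[ok] +
      image[i10] * fr[ok] * (1 - fc[ok]) +
      image[i11] * fr[ok] * fc[ok]
    if (any(edge)) {
      ri <- pmin(pmax(round(sr[edge]), 1), h)
      ci <- pmin(pmax(round(sc[edge]), 1), w)
      out[edge] <- image[cbind(ri, ci)]
    }
  }
  out
}

# Pre-image coordinates of every output pixel under tf (vectorised).
inverse_coords <- function(h, w, tf) {
  ctr <- c((h + 1) / 2, (w + 1) / 2)
  inv <- invert_transform(tf)
  R <- rot_mat(inv$angle)
  rr <- matrix(seq_len(h), h, w) - ctr[1]
  cc <- matrix(rep(seq_len(w), each = h), h, w) - ctr[2]
  pr <- R[1, 1] * rr + R[1, 2] * cc + ctr[1] + inv$dr
  pc <- R[2, 1] * rr + R[2, 2] * cc + ctr[2] + inv$dc
  list(r = pr, c = pc)
}

#' Validity mask of a rigid warp
#'
#' TRUE where the inverse transform stays inside the source canvas, i.e.
#' where \code{warp_rigid()} produced an interpolated (not filled) value.
#'
#' @param dims integer c(h, w) of the canvas.
#' @param tf a \code{rigid_transform}.
#' @return Logical h x w matrix.
#' @export
warp_validity <- function(dims, tf) {
  src <- inverse_coords(dims[1], dims[2], tf)
  src$r >= 1 & src$r <= dims[1] & src$c >= 1 & src$c <= dims[2]
}
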