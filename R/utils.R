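#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @keywords internal
"_PACKAGE"

# Rescale a numeric vector/matrix to [0, 1] by min-max.
rescale01 <- function(x) {
  r <- range(x, finite = TRUE)
  if (!is.finite(r[1]) || r[2] - r[1] <= 0) {
    abort("cannot min-max rescale a constant (zero-range) image")
  }
  (x - r[1]) / (r[2] - r[1])
}

# Min-max rescale to [lo, hi]; constant input maps to the midpoint.
rescale_to <- function(x, lo, hi) {
  r <- range(x, finite = TRUE)
  if (r[2] - r[1] <= .Machine$double.eps * max(1, abs(r[2]))) {
    return(rep((lo + hi) / 2, length(x)))
  }
  lo + (x - r[1]) / (r[2] - r[1]) * (hi - lo)
}

# Luminance of an h x w x 3 array (plain channel mean).
luminance <- function(rgb) {
  stopifnot(length(dim(rgb)) == 3, dim(rgb)[3] == 3)
  (rgb[, , 1] + rgb[, , 2] + rgb[, , 3]) / 3
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x == round(x) && x >= 1

# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# stats::kmeans warns when the capped iteration budget (iter.max = 20 is part
# of the method configuration) stops Hartigan-Wong early; that is expected
# behaviour here, not a user-facing problem.
quiet_kmeans <- function(...) {
  withCallingHandlers(
    stats::kmeans(...),
    warning = function(w) {
      if (grepl("Quick-TRANSfer|did not converge", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
}

# Channel-matrix view of an mmmp_matrix tibble (drops the pixel coordinates).
channel_matrix <- function(m) {
  ch <- channel_names(m)
  out <- as.matrix(m[ch])
  storage.mode(out) <- "double"
  out
}

channel_names <- function(m) {
  setdiff(names(m), c("px_row", "px_col"))
}
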