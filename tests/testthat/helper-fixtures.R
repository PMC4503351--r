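# Shared fixtures, built once per test run. Everything is generated in code;
# no files ship with the tests.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A small full-panel phantom (all 6 features, 15 IF + 4 BF cycles).
std_phantom <- function() {
  cached("std_phantom", make_phantom_core(phantom_spec(seed = 2L)))
}

std_matrix <- function() {
  cached("std_matrix", {
    tr <- std_phantom()
    build_matrix(as_registered_stack(tr),
                 panel = panel_config(tr$spec$if_stains, tr$spec$bf_stains))
  })
}

# A light phantom for geometry-only tests (2 IF + 1 BF cycles).
tiny_spec <- function(...) {
  args <- utils::modifyList(
    list(canvas = c(120, 120), n_if_cycles = 2, n_bf_cycles = 1,
         noise_sd = 2, seed = 7L),
    list(...))
  do.call(phantom_spec, args)
}

# Brute-force oracle: the integer translation in a window that maximises the
# normalised cross-correlation of the overlapping region of two images.
# Convention matches the stitcher: returns s with b(x) ~= a(x - s).
oracle_best_shift <- function(a, b, centre = c(0, 0), win = 8) {
  best <- NULL
  for (sr in (centre[1] - win):(centre[1] + win)) {
    for (sc in (centre[2] - win):(centre[2] + win)) {
      n <- dim(a)
      rlo <- max(1, 1 + sr); rhi <- min(n[1], n[1] + sr)
      clo <- max(1, 1 + sc); chi <- min(n[2], n[2] + sc)
      if (rhi - rlo < 3 || chi - clo < 3) next
      av <- as.vector(a[(rlo:rhi) - sr, (clo:chi) - sc])
      bv <- as.vector(b[rlo:rhi, clo:chi])
      if (sd(av) == 0 || sd(bv) == 0) next
      s <- cor(av, bv)
      if (is.null(best) || s > best$score) best <- list(shift = c(sr, sc), score = s)
    }
  }
  best
}

# Noiseless phantom whose matrix rows are exactly the signature vectors.
noiseless_phantom <- function(seed = 5L) {
  cached(paste0("noiseless_", seed),
         make_phantom_core(phantom_spec(noise_sd = 0, seed = seed)))
}

noiseless_matrix <- function(seed = 5L) {
  cached(paste0("noiseless_matrix_", seed), {
    tr <- noiseless_phantom(seed)
    build_matrix(as_registered_stack(tr),
                 panel = panel_config(tr$spec$if_stains, tr$spec$bf_stains))
  })
}

# Signature vectors over the extracted panel columns, one row per feature.
panel_signatures <- function(spec) {
  pan <- panel_config(spec$if_stains, spec$bf_stains)
  src <- ifelse(pan$role == "DAPI", "DAPI",
                ifelse(pan$role == "Cy5", pan$stain,
                       paste(pan$stain, pan$role, sep = "_")))
  sig <- spec$signatures[, src, drop = FALSE]
  colnames(sig) <- pan$column
  sig
}
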