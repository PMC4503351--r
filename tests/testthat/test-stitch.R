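make_tile_phantom <- function(seed, noise_sd = 2, jitter_sd = 2,
                              canvas = c(280, 280)) {
  spec <- phantom_spec(canvas = canvas, n_if_cycles = 1, n_bf_cycles = 0,
                       bf_stains = character(), noise_sd = noise_sd,
                       jitter_sd = jitter_sd, seed = seed)
  tr <- make_phantom_core(spec)
  list(truth = tr, tiles = tile_phantom(tr, 1))
}

offset_error <- function(result, tiles) {
  est <- as.matrix(result$offsets[c("row", "col")])
  tru <- as.matrix(tiles$layout[c("truth_row", "truth_col")])
  # offsets are defined up to a global shift
  max(abs(sweep(est, 2, colMeans(est)) - sweep(tru, 2, colMeans(tru))))
}

test_that("a single tile stitches to itself", {
  img <- matrix(runif(100), 10, 10)
  ts <- tile_set(list(img), tibble::tibble(tile_id = 1, grid_row = 1,
                                           grid_col = 1, nominal_row = 1,
                                           nominal_col = 1))
  res <- stitch_tiles(ts, 10)
  expect_equal(res$canvas, img)
  expect_equal(nrow(res$offsets), 1)
})

test_that("unjittered noiseless tiles are recovered exactly and the crop is bit-exact", {
  p <- make_tile_phantom(3, noise_sd = 0, jitter_sd = 0)
  res <- stitch_tiles(p$tiles, 10)
  est <- as.matrix(res$offsets[c("row", "col")])
  tru <- as.matrix(p$tiles$layout[c("truth_row", "truth_col")])
  expect_lt(max(abs(est - tru)), 0.25)
  cropped <- crop_canvas(res, 280)
  expect_equal(cropped, p$truth$cycles[[1]]$channels$DAPI)
})

test_that("jittered 3x3 grids are recovered within 1 px and agree with the brute-force oracle", {
  for (seed in c(11, 27, 123)) {
    p <- make_tile_phantom(seed)
    res <- consensus_stitch(p$tiles)
    expect_lt(offset_error(res, p$tiles), 1)
  }
  # oracle check on one adjacent pair: exhaustive integer translation search
  p <- make_tile_phantom(11)
  lay <- p$tiles$layout
  a <- p$tiles$tiles[[1]]; b <- p$tiles$tiles[[2]]   # horizontal neighbours
  strip <- 26
  sa <- a[, (ncol(a) - strip + 1):ncol(a)]
  sb <- b[, 1:strip]
  oracle <- oracle_best_shift(sa, sb, centre = c(0, -16), win = 12)
  true_d <- c(lay$truth_row[2] - lay$truth_row[1],
              lay$truth_col[2] - lay$truth_col[1])
  oracle_d <- c(0, ncol(a) - strip) - oracle$shift
  expect_equal(oracle_d, true_d)
})

test_that("consensus selection follows the median rule with smallest-prior ties", {
  # near-identical runs: every run close to the consensus
  p <- make_tile_phantom(3, noise_sd = 0, jitter_sd = 0)
  res <- consensus_stitch(p$tiles, overlap_priors = c(8, 5, 10))
  expect_true(all(res$consensus_distance$distance < 1))
  expect_true(res$chosen_overlap %in% c(5, 8, 10))

  # exact ties (flat tiles force every run onto the nominal fallback):
  # the smallest prior wins regardless of listed order
  flat <- matrix(7, 60, 60)
  lay <- tidyr::expand_grid(grid_row = 1:2, grid_col = 1:2)
  lay$tile_id <- 1:4
  lay$nominal_row <- ifelse(lay$grid_row == 1, 1, 55)
  lay$nominal_col <- ifelse(lay$grid_col == 1, 1, 55)
  ts <- tile_set(replicate(4, flat, simplify = FALSE), lay)
  r1 <- consensus_stitch(ts, overlap_priors = c(8, 5, 10))
  expect_equal(r1$chosen_overlap, 5)
  r2 <- consensus_stitch(ts, overlap_priors = c(10, 8, 5))
  expect_equal(r2$chosen_overlap, 5)
  expect_equal(r1$consensus_distance$distance[r1$consensus_distance$overlap_prior == 5], 0)
})

test_that("an outlier run loses the consensus to the agreeing runs", {
  # hand-computed: two runs agree, one is off by 10 px on one tile; the
  # median equals the agreeing offsets, so their distance is 0 and the
  # outlier's is 10
  offs <- list(
    cbind(row = c(1, 1), col = c(1, 91)),
    cbind(row = c(1, 1), col = c(1, 91)),
    cbind(row = c(1, 1), col = c(1, 101))
  )
  cons <- apply(simplify2array(offs), c(1, 2), median)
  d <- vapply(offs, function(o) sum(sqrt(rowSums((o - cons)^2))), numeric(1))
  expect_equal(d, c(0, 0, 10))
})

test_that("zero-variance overlap falls back to the nominal layout", {
  flat <- matrix(5, 60, 60)
  lay <- tidyr::expand_grid(grid_row = 1:2, grid_col = 1:2)
  lay$tile_id <- 1:4
  lay$nominal_row <- ifelse(lay$grid_row == 1, 1, 55)
  lay$nominal_col <- ifelse(lay$grid_col == 1, 1, 55)
  ts <- tile_set(replicate(4, flat, simplify = FALSE), lay)
  res <- stitch_tiles(ts, 10)
  expect_gt(res$pair_flags, 0)
  off <- res$offsets
  expect_equal(unname(off$row[off$grid_row == 2] - off$row[off$grid_row == 1]),
               c(54, 54), tolerance = 1e-6)
})

test_that("crop_canvas centres, pads, and respects the classic 2300 px default", {
  img <- matrix(seq_len(2400 * 2400), 2400, 2400)
  out <- crop_canvas(img)
  expect_equal(dim(out), c(2300, 2300))
  expect_equal(out[1, 1], img[51, 51])
  # identity when already at size
  small <- matrix(runif(100), 10, 10)
  expect_equal(crop_canvas(small, 10), small)
  # padding: original centred, background value elsewhere
  padded <- crop_canvas(small, 14, background = -1)
  expect_equal(dim(padded), c(14, 14))
  expect_equal(padded[3:12, 3:12], small)
  expect_true(all(padded[1:2, ] == -1))
})

test_that("core grid alignment recovers translations and flags dropped cores", {
  grid <- tidyr::expand_grid(r = c(100, 400, 700), c = c(100, 400, 700))
  ref <- tibble::tibble(cycle = 1, core = 1:9, row = grid$r, col = grid$c)
  shifted <- dplyr::mutate(ref, cycle = 2, row = row + 40, col = col - 15)
  out <- align_core_grid(dplyr::bind_rows(ref, shifted))
  sh <- out$shifts[out$shifts$cycle == 2, ]
  expect_equal(unname(c(sh$dr, sh$dc)), c(-40, 15), tolerance = 1e-9)
  expect_false(any(out$matches$dropped))
  expect_equal(out$matches$ref_core[out$matches$cycle == 2], 1:9)

  # identical tables: identity correspondence, zero shift
  out0 <- align_core_grid(dplyr::bind_rows(ref, dplyr::mutate(ref, cycle = 2)))
  expect_equal(max(abs(c(out0$shifts$dr, out0$shifts$dc))), 0)

  # one core missing in cycle 3: the rest still match 1:1
  miss <- dplyr::filter(dplyr::mutate(ref, cycle = 3, row = row + 5), core != 5)
  out3 <- align_core_grid(dplyr::bind_rows(ref, miss))
  m3 <- out3$matches[out3$matches$cycle == 3, ]
  expect_false(any(m3$dropped))
  expect_equal(sort(m3$ref_core), setdiff(1:9, 5))
})
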