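test_that("PCA variance fractions behave on rank-1, isotropic, and any data", {
  # rank-1: two perfectly collinear channels
  set.seed(1)
  a <- rnorm(500)
  m1 <- mmmp_matrix(cbind(x = a, y = 2 * a + 3))
  p1 <- pca_summary(m1, images = FALSE)
  expect_equal(p1$variance$var_fraction[1], 1, tolerance = 1e-12)

  # isotropic 3-channel Gaussian: fractions near 1/3
  n <- 20000
  m2 <- mmmp_matrix(matrix(rnorm(3 * n), n, 3))
  p2 <- pca_summary(m2, images = FALSE)
  expect_true(all(abs(p2$variance$var_fraction - 1 / 3) < 3 / sqrt(n)))

  # completeness: cumulative variance reaches 100%
  m3 <- std_matrix()
  p3 <- pca_summary(m3, images = FALSE)
  expect_equal(dplyr::last(p3$variance$cum_fraction), 1, tolerance = 1e-12)
  expect_true(all(diff(p3$variance$cum_fraction) >= -1e-15))
})

test_that("zero-variance channels are dropped with a warning", {
  m <- mmmp_matrix(cbind(x = rnorm(50), flat = rep(2, 50)))
  expect_warning(p <- pca_summary(m, images = FALSE), "zero-variance")
  expect_equal(p$dropped_channels, "flat")
})

test_that("k-means on {0,1,10,11} with k=2 matches the exhaustive-partition oracle", {
  pts <- c(0, 1, 10, 11)
  # oracle: enumerate all 2-partitions, minimise within-cluster SS
  best <- NULL
  for (assign_mask in 1:(2^4 - 2)) {
    grp <- as.logical(bitwAnd(assign_mask, 2^(0:3)))
    if (!any(grp) || all(grp)) next
    wss <- sum((pts[grp] - mean(pts[grp]))^2) +
      sum((pts[!grp] - mean(pts[!grp]))^2)
    if (is.null(best) || wss < best$wss) best <- list(grp = grp, wss = wss)
  }
  expect_equal(sort(pts[best$grp]), c(0, 1))

  km <- kmeans_profiles(mmmp_matrix(cbind(v = pts)), k = 2, seed = 4)
  expect_equal(sort(as.vector(km$centroids)), c(0.5, 10.5))
  expect_equal(km$assignments[1], km$assignments[2])
  expect_equal(km$assignments[3], km$assignments[4])
  expect_false(km$assignments[1] == km$assignments[3])
  expect_equal(km$tot_withinss, best$wss)
})

test_that("centroid-seeded k-means on the noiseless phantom recovers the feature partition", {
  tr <- noiseless_phantom()
  m <- noiseless_matrix()
  sig <- panel_signatures(tr$spec)
  km <- kmeans_profiles(m, centers = sig)
  lab <- tr$label[cbind(m$px_row, m$px_col)]
  # each signature is its own centroid: partition matches the label image
  # up to the feature <-> cluster naming
  tab <- table(lab, km$assignments)
  expect_equal(sum(tab > 0), nrow(sig))
  expect_true(all(colSums(tab > 0) == 1))
  # assignments are nearest-centroid for every pixel
  x <- as.matrix(m[colnames(sig)])
  d2 <- outer(rowSums(x^2), rep(1, nrow(km$centroids))) -
    2 * x %*% t(km$centroids) +
    outer(rep(1, nrow(x)), rowSums(km$centroids^2))
  expect_equal(unname(km$assignments), unname(apply(d2, 1, which.min)))
})

test_that("k is reduced with a warning when distinct profiles run out", {
  m <- mmmp_matrix(cbind(v = rep(c(0, 5), each = 10)))
  expect_warning(km <- kmeans_profiles(m, k = 5, seed = 1), "reducing k")
  expect_equal(km$k, 2)
})

test_that("imputation r-squared: exact, chance, and the hand-computed example", {
  # exact: every pixel equals its centroid
  tr <- noiseless_phantom()
  m <- noiseless_matrix()
  km <- kmeans_profiles(m, centers = panel_signatures(tr$spec))
  fr <- imputation_r2(m, km)
  expect_equal(fr$r2[fr$defined], rep(1, sum(fr$defined)), tolerance = 1e-12)

  # hand-computed 4-point example: imputed {0.5, 0.5, 10.5, 10.5}
  m4 <- mmmp_matrix(cbind(v = c(0, 1, 10, 11)))
  km4 <- kmeans_profiles(m4, k = 2, seed = 1)
  fr4 <- imputation_r2(m4, km4)
  expect_equal(round(fr4$r2[1], 2), 0.99)
  # independent computation: cor(orig, imputed)^2 from first principles
  imp <- ifelse(c(0, 1, 10, 11) < 5, 0.5, 10.5)
  expect_equal(fr4$r2[1], cor(c(0, 1, 10, 11), imp)^2)

  # shuffled assignments: correlation collapses toward zero
  set.seed(8)
  big <- std_matrix()
  kmb <- kmeans_profiles(big, k = 20, seed = 2)
  kmb$assignments <- sample(kmb$assignments)
  frs <- imputation_r2(big, kmb)
  expect_lt(max(frs$r2[frs$defined]), 0.02)
})

test_that("MDS colour map embeds intrinsically 3-D centroids with zero stress", {
  set.seed(11)
  cen <- matrix(rnorm(30 * 3), 30, 3) %*% matrix(rnorm(9), 3, 3)
  cmap <- mds_colormap(cen)
  expect_lt(cmap$stress, 1e-3)
  dc <- as.vector(dist(cen))
  dcol <- as.vector(dist(as.matrix(cmap$colors[c("R", "G", "B")])))
  expect_equal(cor(dc, dcol, method = "spearman"), 1, tolerance = 1e-9)
})

test_that("MDS colours reflect centroid similarity structure", {
  # two clusters: opposite ends of the first axis
  two <- mds_colormap(rbind(c(0, 0), c(10, 10)))
  expect_equal(sort(two$colors$R), c(0, 255))

  # A and B close, C far: colour distances rank the same way
  cen <- rbind(A = c(0, 0, 0), B = c(1, 0, 0), C = c(20, 20, 20))
  cmap <- mds_colormap(cen)
  cols <- as.matrix(cmap$colors[c("R", "G", "B")])
  dAB <- sqrt(sum((cols[1, ] - cols[2, ])^2))
  dAC <- sqrt(sum((cols[1, ] - cols[3, ])^2))
  expect_lt(dAB, dAC)

  # permutation of cluster order permutes colours identically
  set.seed(3)
  cen2 <- matrix(runif(60), 12, 5)
  perm <- sample(12)
  c1 <- mds_colormap(cen2)
  c2 <- mds_colormap(cen2[perm, ])
  expect_equal(as.matrix(c2$colors[c("R", "G", "B")]),
               as.matrix(c1$colors[c("R", "G", "B")])[perm, ],
               tolerance = 1e-6)

  expect_error(mds_colormap(rbind(c(1, 1), c(1, 1))), "identical")
})

test_that("cluster rendering colours regions by assignment and background", {
  tr <- noiseless_phantom()
  m <- noiseless_matrix()
  km <- kmeans_profiles(m, centers = panel_signatures(tr$spec))
  cmap <- mds_colormap(km)
  img <- render_cluster_image(km, cmap, background = c(9, 9, 9))
  # every label region is a single colour that matches its cluster's colour
  lab <- tr$label[cbind(m$px_row, m$px_col)]
  for (f in unique(lab)) {
    px <- which(lab == f)
    cl <- km$assignments[px[1]]
    expect_true(all(km$assignments[px] == cl))
    rgb_at <- img[cbind(m$px_row[px[1]], m$px_col[px[1]], 1:3)]
    expect_equal(unname(rgb_at),
                 unname(unlist(cmap$colors[cl, c("R", "G", "B")])))
  }
})

test_that("global compilation concatenates centroids and shares the palette", {
  m <- std_matrix()
  k1 <- kmeans_profiles(m, k = 3, seed = 1)
  k2 <- kmeans_profiles(m, k = 3, seed = 2)
  # different seeds can still converge to coincident centroids, which the
  # pooled embedding resolves by jittering
  g <- suppressWarnings(compile_global(list(k1, k2), sample_ids = c("s1", "s2")))
  expect_equal(nrow(g$centroids), 6)
  expect_s3_class(g$hclust, "hclust")

  # identical centroid vectors receive identical colours under the pooled map
  km <- kmeans_profiles(m, k = 4, seed = 5)
  expect_warning(g2 <- compile_global(list(km, km), sample_ids = c("a", "b")),
                 "duplicate centroids")
  cols <- as.matrix(g2$colormap$colors[c("R", "G", "B")])
  expect_equal(cols[1:4, ], cols[5:8, ], tolerance = 1e-6)

  # channel mismatch is an error
  k_bad <- k1
  colnames(k_bad$centroids)[1] <- "other"
  expect_error(compile_global(list(k1, k_bad)), "channel layout")
})
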