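two_class_matrix <- function(n = 400, sep = 10, sd = 1, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(2 * n, 0, sd), n, 2),
             matrix(rnorm(2 * n, sep, sd), n, 2))
  colnames(x) <- c("chA", "chB")
  list(x = x, labels = rep(c("a", "b"), each = n))
}

test_that("checkerboard parity rule holds for every pixel", {
  lab <- matrix(1L, 130, 110)
  ann <- annotation_set(lab, "only")
  grid <- checkerboard_partition(ann, candidates = c(100, 50, 20))
  expect_equal(grid$g, 100)   # single category: coverage always holds
  idx <- which(lab > -1, arr.ind = TRUE)
  parity <- ((idx[, 1] - 1) %/% grid$g + (idx[, 2] - 1) %/% grid$g) %% 2
  expect_equal(as.vector(grid$region[idx]), as.vector(1L + parity))
})

test_that("the largest feasible grid size is selected, independent of candidate order", {
  # a rare category confined to one 100 px square but spanning two 50 px
  # squares of opposite parity forces g = 50
  lab <- matrix(1L, 200, 200)
  lab[30:40, 40:60] <- 2L    # crosses the col=50 boundary: blocks (0,0),(0,1)
  ann <- annotation_set(lab, c("common", "rare"))
  g1 <- checkerboard_partition(ann, candidates = c(100, 50, 20))
  expect_equal(g1$g, 50)
  g2 <- checkerboard_partition(ann, candidates = c(20, 100, 50))
  expect_equal(g2$g, 50)
  # parity check for the rare block at g = 50: (0,0) even -> region 1,
  # (0,1) odd -> region 2
  expect_equal(unique(as.vector(g1$region[30:40, 40:49])), 1L)
  expect_equal(unique(as.vector(g1$region[30:40, 51:60])), 2L)
})

test_that("no feasible grid size is a clear error", {
  lab <- matrix(0L, 60, 60)
  lab[1:5, 1:5] <- 1L   # one tiny blob inside a single 20 px block
  lab[1:5, 8:12] <- 2L
  ann <- annotation_set(lab, c("a", "b"))
  expect_error(checkerboard_partition(ann, candidates = c(100, 50, 20)),
               "smaller")
})

test_that("LDA boundary for two 1-D Gaussians sits at the midpoint", {
  set.seed(2)
  x <- cbind(v = c(rnorm(2000, 0), rnorm(2000, 10)))
  model <- train_lda(x, rep(c("lo", "hi"), each = 2000))
  probe <- cbind(v = seq(4, 6, by = 0.01))
  pred <- predict(model, probe)
  boundary <- probe[max(which(pred == "lo")), 1]
  expect_lt(abs(boundary - 5), 0.2)
})

test_that("LDA predictions match the brute-force discriminant-score oracle and MASS::lda", {
  d <- two_class_matrix(n = 500, sep = 4, sd = 2, seed = 3)
  model <- train_lda(d$x, d$labels)
  pred <- predict(model, d$x)

  # oracle: recompute the Gaussian discriminant score per pixel from scratch
  mu_a <- colMeans(d$x[d$labels == "a", ])
  mu_b <- colMeans(d$x[d$labels == "b", ])
  S <- (crossprod(sweep(d$x[d$labels == "a", ], 2, mu_a)) +
        crossprod(sweep(d$x[d$labels == "b", ], 2, mu_b))) / (nrow(d$x) - 2)
  S <- S + diag(1e-4 * sum(diag(S)) / 2, 2)
  Sinv <- solve(S)
  score <- function(x, mu, prior) {
    as.numeric(x %*% Sinv %*% mu) -
      0.5 * drop(t(mu) %*% Sinv %*% mu) + log(prior)
  }
  oracle <- ifelse(score(d$x, mu_a, 0.5) >= score(d$x, mu_b, 0.5), "a", "b")
  expect_identical(pred, unname(oracle))

  # independent library cross-check (equal-covariance LDA, same priors)
  mass_fit <- MASS::lda(d$x, grouping = d$labels)
  mass_pred <- as.character(predict(mass_fit, d$x)$class)
  expect_gt(mean(pred == mass_pred), 0.999)
})

test_that("degenerate training sets are refused with the class named", {
  x <- cbind(v = c(0, 0.1, 5))
  expect_error(train_lda(x, c("a", "a", "b")), "fewer than 2.*b")
  expect_error(train_lda(x, c("a", "a", "a")), "2 classes")
})

test_that("checkerboard cross-prediction is perfect on separable phantom features", {
  tr <- std_phantom()
  m <- std_matrix()
  ann <- annotation_from_phantom(tr)
  grid <- checkerboard_partition(ann)
  cp <- cross_predict(m, ann, grid)
  expect_true(all(cp$confusion$accuracy$accuracy == 100))
  # counting identity: confusion row sums equal annotated pixel counts
  lab <- tr$label[cbind(m$px_row, m$px_col)]
  ann_lab <- annotation_from_phantom(tr)$label[cbind(m$px_row, m$px_col)]
  counts <- table(factor(ann$names[ann_lab[ann_lab > 0]], levels = ann$names))
  expect_equal(unname(rowSums(cp$confusion$counts)), as.vector(counts))
})

test_that("train and test folds are pixel-disjoint in both directions", {
  tr <- std_phantom()
  m <- std_matrix()
  ann <- annotation_from_phantom(tr)
  grid <- checkerboard_partition(ann)
  reg <- grid$region[cbind(m$px_row, m$px_col)]
  expect_true(all(reg %in% 1:2))
  expect_equal(sum(reg == 1) + sum(reg == 2), nrow(m))
})

test_that("shuffled labels classify at chance level", {
  set.seed(4)
  n <- 3000
  x <- cbind(a = rnorm(n), b = rnorm(n))
  lab_img <- matrix(sample(1:3, n, replace = TRUE), 50, 60)
  ann <- annotation_set(lab_img, c("f1", "f2", "f3"))
  m <- mmmp_matrix(x, coords = which(lab_img > 0, arr.ind = TRUE),
                   dims = c(50, 60))
  grid <- checkerboard_partition(ann, candidates = c(20, 10))
  cp <- cross_predict(m, ann, grid, priors = "uniform")
  expect_lt(abs(cp$confusion$mean_accuracy - 100 / 3), 6)
})

test_that("feature profiles flag specificity via nearest centroids", {
  # disjoint, well-separated signatures: every centroid is feature-specific
  set.seed(5)
  x <- rbind(matrix(rnorm(600, 0, 0.5), 300, 2),
             matrix(rnorm(600, 50, 0.5), 300, 2))
  colnames(x) <- c("c1", "c2")
  lab_img <- matrix(rep(1:2, each = 300), 30, 20)
  ann <- annotation_set(lab_img, c("a", "b"))
  m <- mmmp_matrix(x, coords = which(lab_img > 0, arr.ind = TRUE),
                   dims = dim(lab_img))
  fp <- feature_profiles(m, ann, k = 5, seed = 1)
  expect_true(all(fp$specific))
  # brute-force verification of the nearest-neighbour rule
  cen <- as.matrix(fp[c("c1", "c2")])
  d <- as.matrix(dist(cen)); diag(d) <- Inf
  expect_equal(fp$specific, fp$feature[apply(d, 1, which.min)] == fp$feature)

  # identical distributions: specificity collapses — the two categories'
  # centroid sets interleave, so nearest neighbours come from the other set
  # far more often than for separated categories
  x2 <- matrix(rnorm(1200), 600, 2); colnames(x2) <- c("c1", "c2")
  m2 <- mmmp_matrix(x2, coords = which(lab_img > 0, arr.ind = TRUE),
                    dims = dim(lab_img))
  fp2 <- feature_profiles(m2, ann, k = 20, seed = 2)
  expect_lt(mean(fp2$specific), 0.4)

  # one category: trivially all specific
  ann1 <- annotation_set(matrix(1L, 30, 20), "only")
  fp1 <- feature_profiles(m, ann1, k = 4, seed = 3)
  expect_true(all(fp1$specific))
})

test_that("ablating with the full panel is a no-op; dropping the only informative channel is not", {
  # two features differ only in channel "key"; a third is always separable
  set.seed(6)
  n <- 1200
  lab_img <- matrix(sample(1:3, n, replace = TRUE), 30, 40)
  idx <- which(lab_img > 0, arr.ind = TRUE)
  lab <- lab_img[idx]
  key <- ifelse(lab == 1, 0, ifelse(lab == 2, 20, 10)) + rnorm(n)
  other <- ifelse(lab == 3, 40, 0) + rnorm(n)
  x <- cbind(key = key, other = other)
  ann <- annotation_set(lab_img, c("f1", "f2", "f3"))
  m <- mmmp_matrix(x, coords = idx, dims = dim(lab_img))
  grid <- checkerboard_partition(ann, candidates = c(10, 5))
  ab <- ablate_channels(m, ann, grid, subset = c("key", "other"))
  expect_equal(ab$full$confusion$counts, ab$subset$confusion$counts)

  ab2 <- ablate_channels(m, ann, grid, subset = "other")
  pair <- ab2$comparison[ab2$comparison$feature %in% c("f1", "f2"), ]
  expect_true(all(pair$accuracy_full > 95))
  expect_lt(mean(pair$accuracy_subset), 65)   # toward the 50% pair-chance level
  expect_gt(ab2$comparison$accuracy_subset[3], 95)  # f3 is unaffected
})

test_that("cross-sample application reproduces predictions and enforces the channel contract", {
  tr <- std_phantom()
  m <- std_matrix()
  ann <- annotation_from_phantom(tr)
  grid <- checkerboard_partition(ann)
  cp <- cross_predict(m, ann, grid)
  model <- cp$models[[1]]
  rep_pred <- apply_model_cross_sample(model, m)
  # region-2 pixels were predicted by model 1 in cross_predict
  reg <- grid$region[cbind(m$px_row, m$px_col)]
  expect_equal(rep_pred$predicted[reg == 2], cp$predicted[reg == 2])

  m_perm <- m[, c("px_row", "px_col", rev(setdiff(names(m), c("px_row", "px_col"))))]
  attr(m_perm, "dims") <- attr(m, "dims")
  class(m_perm) <- class(m)
  expect_error(apply_model_cross_sample(model, m_perm), "channel layout")
})

test_that("a second phantom from the same generative spec classifies almost as well", {
  tr1 <- std_phantom()
  m1 <- std_matrix()
  ann1 <- annotation_from_phantom(tr1)
  grid1 <- checkerboard_partition(ann1)
  cp1 <- cross_predict(m1, ann1, grid1)

  spec2 <- phantom_spec(seed = 31L)
  tr2 <- make_phantom_core(spec2)
  m2 <- build_matrix(as_registered_stack(tr2),
                     panel = panel_config(spec2$if_stains, spec2$bf_stains))
  pred2 <- apply_model_cross_sample(cp1$models[[1]], m2)
  ann2 <- annotation_from_phantom(tr2)
  lab2 <- ann2$label[cbind(m2$px_row, m2$px_col)]
  keep <- lab2 > 0
  conf2 <- confusion_matrix(ann2$names[lab2[keep]], pred2$predicted[keep],
                            classes = ann2$names)
  expect_gte(conf2$median_accuracy, cp1$confusion$median_accuracy - 5)
})
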