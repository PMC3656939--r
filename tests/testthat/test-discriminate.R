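## synthetic Gaussian feature sets for classifier tests
blob_set <- function(n_per, centers, sd = 1, seed = 1, d = 27, repeat_id = 1) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_along(centers), function(i)
    matrix(stats::rnorm(n_per[i] * d, mean = centers[[i]], sd = sd),
           ncol = d)))
  labeled_feature_set(x, rep(names(centers), n_per), repeat_id = repeat_id)
}

test_that("z-scoring uses training statistics only", {
  set.seed(2)
  tr <- matrix(stats::rnorm(200, 5, 3), ncol = 4)
  z <- zscore_train_apply(tr, tr)
  expect_lt(max(abs(colMeans(z$test))), 1e-12)
  expect_equal(apply(z$train, 2, stats::sd), rep(1, 4), ignore_attr = TRUE)

  te <- tr + 2
  z2 <- zscore_train_apply(tr, te)
  expect_equal(z2$test, z$test + rep(2 / z$scale, each = nrow(te)),
               tolerance = 1e-12, ignore_attr = TRUE)

  trc <- cbind(tr, 7)
  expect_warning(zc <- zscore_train_apply(trc, trc), "zero-variance")
  expect_true(all(zc$train[, 5] == 7))
})

test_that("SVM separates separable classes and is chance-level on identical ones", {
  sep <- blob_set(c(60, 60), list(A = 0, B = 10), seed = 3)
  m <- train_svm(sep)
  res <- classify_unseen(m, sep)
  expect_gte(res$overall, 95)
  expect_equal(classify_unseen(m, sep)$overall, 100)

  expect_error(train_svm(labeled_feature_set(matrix(stats::rnorm(50), 10),
                                             rep("A", 10))), "2 classes")

  ## identical distributions: held-out accuracy is chance
  tr <- blob_set(c(500, 500), list(A = 0, B = 0), seed = 4)
  te <- blob_set(c(500, 500), list(A = 0, B = 0), seed = 5, repeat_id = 2)
  m0 <- train_svm(tr)
  expect_lt(abs(classify_unseen(m0, te)$overall - 50), 5)

  ## relabeling classes permutes predictions identically
  tr_sw <- labeled_feature_set(sep$features,
                               c(A = "B", B = "A")[sep$labels])
  m_sw <- train_svm(tr_sw)
  p1 <- classify_unseen(m, sep)$predicted
  p2 <- classify_unseen(m_sw, sep)$predicted
  expect_identical(unname(c(A = "B", B = "A")[p1]), p2)
})

test_that("per-region and overall rates follow their definitions", {
  sep <- blob_set(c(40, 60), list(A = 0, B = 8), seed = 6)
  m <- train_svm(sep)
  res <- classify_unseen(m, sep)
  expect_equal(unname(res$per_region), c(100, 100))

  ## two-class complement: permuted test labels flip the overall rate
  flipped <- labeled_feature_set(sep$features,
                                 c(A = "B", B = "A")[sep$labels],
                                 repeat_id = 2)
  expect_equal(classify_unseen(m, flipped)$overall, 100 - res$overall)
})

test_that("pairwise matrix is symmetric, balanced and reports exclusions", {
  tr <- blob_set(c(80, 80, 80), list(A = 0, B = 8, C = -8), seed = 7)
  te <- blob_set(c(80, 80, 80), list(A = 0, B = 8, C = -8), seed = 8,
                 repeat_id = 2)
  pm <- pairwise_matrix(tr, te)
  expect_identical(pm$rates, t(pm$rates))
  expect_true(all(is.na(diag(pm$rates))))
  expect_true(all(pm$rates[upper.tri(pm$rates)] >= 95))

  pm2 <- pairwise_matrix(tr, te, regions = c("A", "B", "D"))
  expect_identical(pm2$excluded, "D")
  expect_equal(dim(pm2$rates), c(2, 2))

  ## identical distributions with 10:1 imbalance: the balanced rate stays
  ## near chance instead of rewarding majority voting
  tri <- blob_set(c(300, 30), list(A = 0, B = 0), seed = 9)
  tei <- blob_set(c(300, 30), list(A = 0, B = 0), seed = 10, repeat_id = 2)
  pmi <- pairwise_matrix(tri, tei)
  expect_lt(abs(pmi$rates["A", "B"] - 50), 12)
})

test_that("k-means parcellation recovers blobs and orders centres on a line", {
  x <- blob_set(c(50, 50, 50), list(A = 0, B = 12, C = 24), seed = 11)
  km <- kmeans_parcellate(x$features, 3, seed = 5)
  expect_equal(adjusted_rand(km$labels, x$labels), 1.0)
  expect_identical(kmeans_parcellate(x$features, 3, seed = 5)$labels,
                   km$labels)
  expect_error(kmeans_parcellate(x$features, 200, seed = 1), "exceeds")
  expect_error(kmeans_parcellate(x$features, 1, seed = 1), "k must be")

  ## centres on a line: ordered ids are monotone and the chain length is the
  ## line length
  set.seed(12)
  centers <- seq(0, 45, by = 5)
  pts <- do.call(rbind, lapply(centers, function(c)
    cbind(stats::rnorm(40, c, 0.1), stats::rnorm(40, 0, 0.1))))
  km2 <- kmeans_parcellate(pts, 10, seed = 3, standardize = FALSE)
  mean_x <- tapply(pts[, 1], km2$labels, mean)
  ord_x <- as.numeric(mean_x[order(as.integer(names(mean_x)))])
  expect_true(all(diff(ord_x) > 0) || all(diff(ord_x) < 0))
  expect_equal(km2$chain_length, max(centers) - min(centers),
               tolerance = 0.05)
})

test_that("intrinsic dimension counts components to the variance threshold", {
  set.seed(13)
  basis <- matrix(stats::rnorm(27 * 3), nrow = 3)
  x <- matrix(stats::rnorm(300 * 3), ncol = 3) %*% basis
  x <- x + matrix(stats::rnorm(length(x), sd = 1e-4), nrow = nrow(x))
  expect_equal(as.integer(intrinsic_dimension(x)), 3)
  expect_equal(as.integer(intrinsic_dimension(cbind(x, x[, 1]))), 3)
  full <- matrix(stats::rnorm(100 * 6), ncol = 6)
  expect_equal(as.integer(intrinsic_dimension(full, 1.0)), 6)
})

test_that("an unseen region inherits the nearest trained labels", {
  tr <- blob_set(c(100, 100, 100), list(A = 0, B = 10, C = 20), seed = 14)
  m <- train_svm(tr)

  d_like_a <- blob_set(c(200), list(D = 0), seed = 15)
  probe <- unseen_region_probe(m, d_like_a$features)
  expect_gte(probe$fractions[["A"]], 0.9)
  expect_true(all(probe$assigned %in% c("A", "B", "C")))

  ## a region centred exactly between two close classes splits its labels
  tr2 <- blob_set(c(200, 200), list(A = 0, B = 2), seed = 21)
  m2 <- train_svm(tr2)
  d_mid <- blob_set(c(400), list(D = 1), seed = 16)
  probe2 <- unseen_region_probe(m2, d_mid$features)
  expect_lt(abs(probe2$fractions[["A"]] - 0.5), 0.1)
  expect_lt(abs(probe2$fractions[["B"]] - 0.5), 0.1)

  empty <- unseen_region_probe(m, tr$features[0, , drop = FALSE])
  expect_length(empty$assigned, 0)
  expect_length(empty$fractions, 0)

  ## adjacency report: contiguous vertices assigned to one label form one
  ## component
  surf <- make_ribbon_surfaces(10, 4, fold_amplitude = 0)
  feats <- blob_set(c(40), list(D = 0), seed = 17)$features
  probe3 <- unseen_region_probe(m, feats, vertex_index = 1:40,
                                faces = surf$faces)
  expect_equal(probe3$largest_component[["A"]],
               sum(probe3$assigned == "A"), tolerance = 0.2)
})

test_that("no test-set information leaks into training", {
  tr <- blob_set(c(80, 80), list(A = 0, B = 6), seed = 18)
  te <- blob_set(c(80, 80), list(A = 0, B = 6), seed = 19, repeat_id = 2)
  z1 <- zscore_train_apply(tr$features, te$features)
  z2 <- zscore_train_apply(tr$features, te$features + 100)
  expect_identical(z1$center, z2$center)
  expect_identical(z1$scale, z2$scale)
  expect_identical(z1$train, z2$train)

  m <- train_svm(labeled_feature_set(z1$train, tr$labels))
  ok <- classify_unseen(m, labeled_feature_set(z1$test, te$labels,
                                               repeat_id = 2))
  perm <- classify_unseen(m, labeled_feature_set(z1$test, rev(te$labels),
                                                 repeat_id = 2))
  expect_identical(ok$predicted, perm$predicted)  # model untouched
  expect_false(isTRUE(all.equal(ok$overall, perm$overall)))
})
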