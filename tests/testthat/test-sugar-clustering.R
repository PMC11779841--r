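test_that("ratio features drop sugars with missing values and log why", {
  tabs <- two_family_tables()
  medium <- tabs$medium
  medium$integral[medium$sugar == "B3" & medium$day == 4] <- NA
  expect_message(
    feats <- compute_ratio_features(tabs$biofilm, medium, days = 2:5),
    "B3"
  )
  expect_false("B3" %in% rownames(feats))
  expect_equal(attr(feats, "dropped")[["B3"]],
               "missing medium value on day 4")
  # zero medium integral is an error naming the cell
  medium2 <- tabs$medium
  medium2$integral[medium2$sugar == "A1" & medium2$day == 3] <- 0
  expect_error(compute_ratio_features(tabs$biofilm, medium2, days = 2:5),
               "A1 on day 3")
})

test_that("standardization gives population z-scores and round-trips", {
  m <- cbind(a = c(1, 2, 3), b = c(10, 20, 60))
  z <- standardize_features(m)
  expect_equal(unname(z[, "a"]), c(-1.2247449, 0, 1.2247449),
               tolerance = 1e-6)
  expect_equal(colMeans(z), c(a = 0, b = 0), tolerance = 1e-9)
  expect_equal(sqrt(colMeans(z^2)), c(a = 1, b = 1), tolerance = 1e-9)
  back <- unstandardize_features(z)
  expect_equal(unname(back), unname(m), tolerance = 1e-12)
  expect_error(standardize_features(cbind(a = c(1, 1, 1), b = 1:3)),
               "constant column")
})

test_that("two-component PCA matches a spectral-decomposition oracle", {
  # rank-1 data: first component carries all variance
  r1 <- outer(c(1, 2, 3, 4), c(1, 0.5))
  p1 <- pca_2d(r1)
  expect_equal(p1$explained_variance[1], 1.0, tolerance = 1e-12)
  # toy matrix: eigenvalues of the covariance matrix as oracle
  m <- cbind(c(2, 0, -2), c(1, -2, 1))
  p <- pca_2d(m)
  ev_oracle <- eigen(stats::cov(m))$values
  sdev2 <- p$explained_variance * sum(ev_oracle)
  expect_equal(sdev2, ev_oracle, tolerance = 1e-10)
  expect_true(all(diff(p$explained_variance) <= 1e-12))
  expect_lte(sum(p$explained_variance), 1 + 1e-12)
  expect_error(pca_2d(m[1:2, ]), ">= 3 rows")
})

test_that("PCA scores are invariant under row reordering", {
  tabs <- two_family_tables()
  z <- standardize_features(compute_ratio_features(tabs$biofilm, tabs$medium,
                                                   days = 2:5))
  p1 <- pca_2d(z)
  perm <- c(4, 1, 6, 2, 5, 3)
  p2 <- pca_2d(z[perm, ])
  expect_equal(p2$scores[rownames(p1$scores), ], p1$scores,
               tolerance = 1e-10)
})

test_that("well-separated families are recovered exactly", {
  tabs <- two_family_tables()
  res <- cluster_sugars(tabs$biofilm, tabs$medium, days = 2:5,
                        k_range = 2:4, seed = 0)
  expect_equal(res$k, 2)
  ari <- mclust::adjustedRandIndex(res$labels[names(tabs$family)],
                                   tabs$family)
  expect_equal(ari, 1.0)
  # determinism under a fixed seed
  res2 <- cluster_sugars(tabs$biofilm, tabs$medium, days = 2:5,
                         k_range = 2:4, seed = 0)
  expect_identical(res$labels, res2$labels)
})

test_that("silhouette selection finds four well-separated blobs", {
  blobs <- four_blobs()
  res <- cluster_scores(blobs$points, k_range = 2:6, seed = 0)
  expect_equal(res$k, 4)
  expect_equal(mclust::adjustedRandIndex(res$labels, blobs$labels), 1.0)
})

test_that("k override and degenerate geometries are handled", {
  blobs <- four_blobs()
  res <- cluster_scores(blobs$points, k_range = 2:6, seed = 0, k = 3)
  expect_equal(res$k, 3)
  expect_true(res$forced)
  # duplicate points: silhouette may be undefined, reported as NA not error
  pts <- rbind(a = c(0, 0), b = c(0, 0), c = c(0, 0), d = c(1, 1))
  res2 <- cluster_scores(pts, k_range = 2:3, seed = 0, k = 2)
  expect_true(is.numeric(res2$silhouettes))
  expect_error(cluster_scores(pts, k_range = 2:10), "smaller than")
})

test_that("default scenario clustering recovers the four sugar families", {
  sc <- build_scenario(noiseless_config(64))
  tabs <- emit_sugar_tables(sc)
  res <- suppressMessages(
    cluster_sugars(tabs$biofilm, tabs$medium, days = 2:5, k_range = 2:6,
                   seed = 0, k = 4)
  )
  truth <- tabs$cluster[names(res$labels)]
  expect_equal(mclust::adjustedRandIndex(res$labels, truth), 1.0)
  # GlcN never enters (missing from medium)
  expect_false("GlcN" %in% names(res$labels))
})

test_that("reference PCA check reports unavailability without a table", {
  res <- reference_pca_variance(NULL)
  expect_false(res$available)
  expect_match(res$reason, "no reference ratio table")
  # with a table, the two-component variance is computed
  tabs <- two_family_tables()
  feats <- compute_ratio_features(tabs$biofilm, tabs$medium, days = 2:5)
  df <- data.frame(sugar = rownames(feats), unclass(feats))
  res2 <- reference_pca_variance(df)
  expect_true(res2$available)
  expect_gt(res2$explained_variance_2, 90)
  expect_lte(res2$explained_variance_2, 100)
})
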