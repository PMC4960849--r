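test_that("gini matches hand-computed cases and the evenness orientation", {
  expect_equal(gini(rep(3, 5)), 0)
  expect_equal(gini(c(7, 0, 0, 0)), 0.75)   # one dominant feature, n = 4
  expect_equal(gini(c(3, 1)), 0.25)         # sum|d| = 4, 2 n sum x = 16
  m <- matrix(c(3, 1), 2, 1, dimnames = list(c("a", "b"), "S1"))
  idx <- community_indices(m)
  expect_equal(idx$gini, 0.25)
  expect_equal(idx$evenness_pct, 75)
  expect_equal(idx$richness, 2L)
})

test_that("fast gini equals the pairwise oracle and is scale invariant", {
  set.seed(42)
  for (i in 1:300) {
    x <- rexp(sample(2:40, 1))
    if (runif(1) < 0.3) x[sample(length(x), 1)] <- 0
    g <- gini(x)
    expect_equal(g, gini_pairwise(x), tolerance = 1e-10)
    expect_equal(gini(x * runif(1, 0.1, 50)), g, tolerance = 1e-10)
    expect_gte(g, 0)
    expect_lte(g, 1 - 1 / length(x))
  }
})

test_that("all-zero samples are rejected by community_indices", {
  m <- matrix(c(1, 2, 0, 0), 2, 2, dimnames = list(c("a", "b"), c("S1", "S2")))
  expect_error(community_indices(m), "S2")
})

test_that("z-scored rows have mean 0 and population sd 1; constants drop", {
  expect_equal(zscore_rows(matrix(c(1, 3), 1, 2,
                                  dimnames = list("f", NULL)))[1, ],
               c(-1, 1))
  set.seed(5)
  m <- matrix(rnorm(60), 6, 10, dimnames = list(paste0("f", 1:6), NULL))
  z <- zscore_rows(m)
  expect_lt(max(abs(rowMeans(z))), 1e-12)
  expect_lt(max(abs(sqrt(rowMeans(z^2)) - 1)), 1e-12)
  m2 <- rbind(m, const = rep(2, 10))
  expect_warning(z2 <- zscore_rows(m2), "const")
  expect_equal(nrow(z2), 6L)
})

test_that("identical samples merge first; clustering ignores column order", {
  m <- cbind(S1 = c(1, 2, 3), S2 = c(1, 2, 3), S3 = c(9, 1, 0))
  rownames(m) <- paste0("f", 1:3)
  cl <- hierarchical_cluster(m, k = 2)
  merge1 <- cl$hclust$merge[1, ]
  expect_setequal(cl$hclust$labels[-merge1], c("S1", "S2"))
  expect_equal(cl$hclust$height[1], 0)
  # merge heights non-decreasing for average linkage on metric distances
  expect_true(all(diff(cl$hclust$height) >= -1e-12))
  cl2 <- hierarchical_cluster(m[, c("S3", "S1", "S2")], k = 2)
  expect_equal(cl$labels[c("S1", "S2", "S3")] == cl$labels["S1"],
               cl2$labels[c("S1", "S2", "S3")] == cl2$labels["S1"])
  expect_error(hierarchical_cluster(m[, 1, drop = FALSE]), "2 samples")
})

test_that("permutation test attains the minimum p on separated groups", {
  set.seed(8)
  m <- cbind(matrix(rnorm(100, 0), 10, 10), matrix(rnorm(100, 8), 10, 10))
  colnames(m) <- paste0("S", 1:20)
  labels <- rep(c("a", "b"), each = 10)
  pt <- cluster_permutation_test(m, labels, n_perm = 999, seed = 3)
  expect_equal(pt$p_value, 1 / 1000)
  # every sample duplicated in the other group: no separation signal
  dup <- cbind(m[, 1:10], m[, 1:10])
  colnames(dup) <- paste0("S", 1:20)
  pt2 <- cluster_permutation_test(dup, labels, n_perm = 199, seed = 3)
  expect_lte(pt2$statistic, 0)
  expect_gt(pt2$p_value, 0.05)
  expect_error(cluster_permutation_test(m, labels, n_perm = 0), "n_perm")
  expect_error(cluster_permutation_test(m, rep("a", 20), 99), "2 groups")
})

test_that("permutation p-values are reproducible and seed-sensitive", {
  set.seed(12)
  m <- matrix(rnorm(60), 5, 12, dimnames = list(NULL, paste0("S", 1:12)))
  labels <- rep(c("a", "b"), each = 6)
  p1 <- cluster_permutation_test(m, labels, 199, seed = 7)$p_value
  p2 <- cluster_permutation_test(m, labels, 199, seed = 7)$p_value
  expect_identical(p1, p2)
})

test_that("PCA is exact: variance sums to 100, full reconstruction, collinear case", {
  set.seed(9)
  m <- matrix(rnorm(80), 8, 10,
              dimnames = list(paste0("f", 1:8), paste0("S", 1:10)))
  pc <- pca(m, n_components = 8)
  expect_lt(abs(sum(pc$variance_explained_pct) - 100), 1e-6)
  expect_true(all(diff(pc$variance_explained_pct) <= 1e-9))
  recon <- pc$scores %*% t(pc$loadings)
  centred <- t(m) - matrix(pc$center, 10, 8, byrow = TRUE)
  expect_lt(max(abs(recon - centred)), 1e-8)
  # samples on a line -> first component explains everything
  line <- outer(c(1, 2, 3), seq(0, 5, length.out = 6))
  rownames(line) <- paste0("f", 1:3); colnames(line) <- paste0("S", 1:6)
  expect_equal(pca(line)$variance_explained_pct[1], 100, tolerance = 1e-9)
  expect_error(pca(m, 0), "positive")
})

test_that("PCA scores do not depend on feature row order (up to sign)", {
  set.seed(10)
  m <- matrix(rnorm(50), 5, 10,
              dimnames = list(paste0("f", 1:5), paste0("S", 1:10)))
  a <- pca(m, 2)$scores
  b <- pca(m[sample(5), ], 2)$scores
  for (j in 1:2)
    expect_true(max(abs(a[, j] - b[, j])) < 1e-9 ||
                  max(abs(a[, j] + b[, j])) < 1e-9)
})

test_that("richness rises with spectral depth on synthetic data", {
  # deeper sampling detects more orders (the saturation behaviour)
  cfg_lo <- sim_config(n_samples_per_group = 2, n_spectra_per_sample = 150,
                       n_metaproteins = 150, n_orders = 30)
  cfg_hi <- sim_config(n_samples_per_group = 2, n_spectra_per_sample = 3000,
                       n_metaproteins = 150, n_orders = 30)
  rich <- function(cfg, s) {
    st <- simulate_study(cfg, seed = s)
    res <- suppressWarnings(analyze_study(st, n_perm = 9, seed = s,
                                          min_pct = 0))
    mean(res$indices$richness)
  }
  expect_gt(mean(vapply(1:3, function(s) rich(cfg_hi, s), numeric(1))),
            mean(vapply(1:3, function(s) rich(cfg_lo, s), numeric(1))))
})
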