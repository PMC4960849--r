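test_that("spearman handles perfect monotone and the textbook rank case", {
  x <- c(2, 5, 9, 11, 20)
  expect_equal(spearman(x, x^3 + 1)$rho, 1)
  expect_equal(spearman(x, -sqrt(x))$rho, -1)
  # 1 - 6*sum(d^2)/(n(n^2-1)) with sum(d^2) = 4 (padded to n = 5 with a
  # fixed point to satisfy the minimum length)
  r <- spearman(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))$rho
  expect_equal(r, 1 - 6 * 4 / (5 * 24))
  expect_error(spearman(c(1, 1, 1, 1, 1), 1:5), "constant")
  expect_error(spearman(1:4, 4:1), "at least 5")
})

test_that("spearman is symmetric and invariant under monotone transforms", {
  set.seed(31)
  for (i in 1:20) {
    x <- rnorm(12); y <- rnorm(12)
    a <- spearman(x, y)
    expect_equal(a$rho, spearman(y, x)$rho)
    expect_equal(a$rho, spearman(exp(x), y)$rho)
    expect_equal(a$p_value, spearman(x, y^3)$p_value)
  }
})

test_that("t-approximation p agrees with R's cor.test estimate of rho", {
  set.seed(32)
  x <- rnorm(20); y <- x + rnorm(20)
  ours <- spearman(x, y)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(ours$rho, unname(ref$estimate))
})

test_that("exact permutation p is close to the t approximation at small n", {
  set.seed(33)
  x <- rnorm(7); y <- x + rnorm(7, 0, 2)
  pe <- spearman(x, y, p_method = "exact")$p_value
  pt_ <- spearman(x, y, p_method = "t")$p_value
  expect_lt(abs(pe - pt_), 0.12)
  expect_error(spearman(rnorm(9), rnorm(9), p_method = "exact"), "n <= 8")
})

test_that("correlation screen flags planted associations and non-evaluable pairs", {
  m <- matrix(c(1, 2, 3, 4, 5, 6,
                2, 2, 2, 2, 2, 2), nrow = 2, byrow = TRUE,
              dimnames = list(c("up", "flat"), paste0("S", 1:6)))
  params <- data.frame(sample_id = paste0("S", 1:6),
                       TAN = c(10, 20, 30, 40, 50, 60),
                       broken = c(1, 2, NA, NA, NA, NA),
                       stringsAsFactors = FALSE)
  res <- correlation_screen(m, params)
  up_tan <- res[res$feature == "up" & res$parameter == "TAN", ]
  expect_equal(up_tan$rho, 1)
  expect_equal(up_tan$significant_at, "0.01")
  expect_false(res$evaluable[res$feature == "flat" & res$parameter == "TAN"])
  expect_false(any(res$evaluable[res$parameter == "broken"]))
})

test_that("network edges shrink monotonically as alpha tightens", {
  set.seed(34)
  m <- matrix(rnorm(300), 15, 20,
              dimnames = list(paste0("f", 1:15), paste0("S", 1:20)))
  m[1, ] <- m[1, ] + 3 * seq_len(20)
  params <- data.frame(sample_id = paste0("S", 1:20),
                       TAN = seq_len(20) + rnorm(20, 0, 2),
                       pH = rnorm(20))
  res <- correlation_screen(m, params)
  n05 <- build_network(res, 0.05)
  n01 <- build_network(res, 0.01)
  expect_lte(nrow(n01$edges), nrow(n05$edges))
  key <- function(n) paste(n$edges$u, n$edges$v)
  expect_true(all(key(n01) %in% key(n05)))
  # all parameters present as nodes; degrees match edge incidence
  expect_true(all(c("TAN", "pH") %in% n05$nodes$id))
  for (i in seq_len(nrow(n05$nodes)))
    expect_equal(n05$nodes$degree[i],
                 sum(n05$edges$u == n05$nodes$id[i] |
                       n05$edges$v == n05$nodes$id[i]))
})

test_that("parameter binarization applies thresholds with ties going low", {
  labs <- binarize_parameter(c(2000, 5000), 4200)
  expect_equal(as.character(labs), c("low", "high"))
  labs2 <- binarize_parameter(c(1, 2, 3, 4), "median")  # median 2.5
  expect_equal(as.character(labs2), c("low", "low", "high", "high"))
  expect_equal(attr(labs2, "threshold"), 2.5)
  expect_equal(attr(labs2, "threshold_source"), "median")
  expect_equal(as.character(binarize_parameter(c(4200, 4201), 4200)),
               c("low", "high"))
  expect_error(binarize_parameter(c(NA_real_, NA_real_), 1), "missing")
})

test_that("CART separates a perfectly informative feature at depth 1", {
  X <- cbind(noise = rnorm(10), signal = c(1:5, 11:15))
  y <- rep(c("low", "high"), each = 5)
  set.seed(35)
  tree <- fit_decision_tree(X, y)
  expect_equal(tree$feature_names[tree$root$feature], "signal")
  expect_equal(tree$root$cut, 8)  # midpoint between 5 and 11
  expect_equal(tree_depth(tree), 1L)
  expect_equal(mean(predict_tree(tree, X) != y), 0)
  # single-class labels: a single leaf, not an error
  leaf <- fit_decision_tree(X, rep("a", 10))
  expect_true(leaf$root$leaf)
})

test_that("CART ties break deterministically toward the lower feature index", {
  X <- cbind(f1 = c(0, 0, 1, 1), f2 = c(0, 0, 1, 1))
  y <- c("a", "a", "b", "b")
  tree <- fit_decision_tree(X, y, min_leaf = 1)
  expect_equal(tree$feature_names[tree$root$feature], "f1")
})

test_that("CART training error is non-increasing in max_depth", {
  set.seed(36)
  X <- matrix(rnorm(200), 40, 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  y <- factor(ifelse(X[, 2] + 0.8 * rnorm(40) > 0, "high", "low"))
  errs <- vapply(1:4, function(d) {
    tr <- fit_decision_tree(X, y, max_depth = d, min_leaf = 2)
    mean(predict_tree(tr, X) != y)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("CART agrees with rpart on a clean two-feature problem", {
  skip_if_not_installed("rpart")
  set.seed(37)
  X <- data.frame(f1 = rnorm(60), f2 = rnorm(60))
  y <- factor(ifelse(X$f2 > 0.3, "high", "low"))
  ours <- fit_decision_tree(as.matrix(X), y, max_depth = 1, min_leaf = 5)
  rp <- rpart::rpart(y ~ ., data = X, method = "class",
                     control = rpart::rpart.control(maxdepth = 1, cp = 0,
                                                    minbucket = 5, minsplit = 2,
                                                    xval = 0))
  expect_equal(ours$feature_names[ours$root$feature],
               as.character(rp$frame$var[1]))
  expect_equal(ours$root$cut, rp$splits[1, "index"], tolerance = 1e-9)
})

test_that("train/test split is stratified, 60/40 sized, and seed-stable", {
  set.seed(38)
  X <- matrix(rnorm(200), 40, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- rep(c("low", "high"), each = 20)
  r1 <- train_test_marker(X, y, seed = 5)
  r2 <- train_test_marker(X, y, seed = 5)
  expect_identical(r1$train_idx, r2$train_idx)
  expect_identical(r1$marker, r2$marker)
  expect_equal(length(r1$train_idx), 24L)
  expect_equal(length(r1$test_idx), 16L)
  expect_equal(unname(table(y[r1$train_idx])), c(12L, 12L), ignore_attr = TRUE)
})

test_that("perfectly separable data give zero test error", {
  X <- cbind(sig = c(rnorm(20, 0), rnorm(20, 10)), junk = rnorm(40))
  y <- rep(c("low", "high"), each = 20)
  r <- train_test_marker(X, y, seed = 9)
  expect_equal(r$test_error, 0)
  expect_equal(r$marker, "sig")
})
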