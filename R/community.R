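#' Community indices, clustering and ordination
#'
#' Richness (number of detected order-level features) and Gini-based
#' evenness per sample, feature-wise z-scoring, agglomerative clustering
#' of samples (euclidean distance, average linkage) with a permutation
#' test for group separation, and PCA with variance explained and
#' loadings.
#'
#' @name community_stats
NULL

#' Gini coefficient of an abundance vector
#'
#' Mean absolute difference form: `sum_ij |x_i - x_j| / (2 n sum x)`.
#' Computed via the O(n log n) sorted identity; the O(n^2) pairwise form
#' is kept in [gini_pairwise()] as the cross-check oracle. Zeros count as
#' real (detected-absent) entries by default. 0 for a perfectly even
#' vector; upper bound (n-1)/n.
#'
#' @param x non-negative abundance vector with positive sum.
#' @param include_zeros keep zero entries (default TRUE).
#' @return Gini coefficient in `[0, 1)`.
#' @export
gini <- function(x, include_zeros = TRUE) {
  if (any(x < 0)) stopf("gini: negative abundances")
  if (!include_zeros) x <- x[x > 0]
  n <- length(x)
  s <- sum(x)
  if (n == 0L || s <= 0) stopf("gini: vector must have positive total")
  xs <- sort(x)
  2 * sum(seq_len(n) * xs) / (n * s) - (n + 1) / n
}

#' @rdname gini
#' @export
gini_pairwise <- function(x, include_zeros = TRUE) {
  if (!include_zeros) x <- x[x > 0]
  n <- length(x)
  sum(abs(outer(x, x, "-"))) / (2 * n * sum(x))
}

#' Per-sample richness and evenness
#'
#' Richness is the number of features detected (> 0) in the sample of the
#' (typically 1%-filtered) order matrix; evenness is `100 * (1 - Gini)`
#' over the sample's retained feature vector, so a perfectly even
#' community scores 100. The raw Gini is reported alongside.
#'
#' @param m order-level abundance matrix (percent, features x samples).
#' @param n_spectra optional named vector of per-sample spectral depth.
#' @param include_zeros include zero entries in the Gini vector.
#' @return data.frame (sample_id, richness, gini, evenness_pct,
#'   n_spectra).
#' @export
community_indices <- function(m, n_spectra = NULL, include_zeros = TRUE) {
  zero <- colSums(m) <= 0
  if (any(zero))
    stopf("all-zero sample(s): %s", paste(colnames(m)[zero], collapse = ", "))
  g <- apply(m, 2, gini, include_zeros = include_zeros)
  data.frame(sample_id = colnames(m),
             richness = unname(colSums(m > 0)),
             gini = unname(g),
             evenness_pct = unname(100 * (1 - g)),
             n_spectra = if (is.null(n_spectra)) NA_real_
               else unname(n_spectra[colnames(m)]),
             stringsAsFactors = FALSE)
}

#' Z-score each feature row
#'
#' Centres each row to mean 0 and scales to standard deviation 1
#' (population sd by default, matching clustergram-style heat maps).
#' Constant rows have no defined z-score and are dropped with a warning.
#'
#' @param m numeric matrix (features x samples).
#' @param population use population (1/n) sd; FALSE for sample sd.
#' @return z-scored matrix (possibly fewer rows).
#' @export
zscore_rows <- function(m, population = TRUE) {
  mu <- rowMeans(m)
  cen <- m - mu
  s <- sqrt(rowMeans(cen^2))
  if (!population) s <- s * sqrt(ncol(m) / (ncol(m) - 1))
  const <- s == 0
  if (any(const)) {
    warnf("dropping %d constant row(s) with undefined z-score: %s",
          sum(const), paste(head(rownames(m)[const], 5), collapse = ", "))
    cen <- cen[!const, , drop = FALSE]
    s <- s[!const]
  }
  cen / s
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering over the sample columns (euclidean distance,
#' average linkage by default, as in clustergram heat maps). Input is
#' typically the z-scored abundance matrix.
#'
#' @param m matrix, features x samples.
#' @param metric distance metric for [stats::dist()].
#' @param linkage agglomeration method for [stats::hclust()].
#' @param k optional number of flat clusters to cut.
#' @return list (class `cluster_result`): `hclust`, `labels` (if `k`
#'   given), `settings`.
#' @export
hierarchical_cluster <- function(m, metric = "euclidean",
                                 linkage = "average", k = NULL) {
  if (ncol(m) < 2) stopf("clustering needs at least 2 samples")
  d <- dist(t(m), method = metric)
  hc <- hclust(d, method = linkage)
  labels <- if (!is.null(k)) cutree(hc, k = k) else NULL
  structure(list(hclust = hc, labels = labels,
                 settings = list(metric = metric, linkage = linkage, k = k)),
            class = "cluster_result")
}

#' Permutation test for group separation
#'
#' Statistic: mean between-group euclidean distance minus mean
#' within-group distance over sample columns. The p-value is
#' `(1 + #[T_perm >= T_obs]) / (1 + n_perm)` over random label
#' permutations (1000 replications in the original workflow).
#'
#' @param m matrix, features x samples.
#' @param labels group label per sample (>= 2 groups, each >= 2 samples).
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @param metric distance metric.
#' @return list (class `perm_test`): `statistic`, `p_value`, `n_perm`,
#'   `seed`.
#' @export
cluster_permutation_test <- function(m, labels, n_perm = 1000, seed = 1,
                                     metric = "euclidean") {
  if (n_perm < 1) stopf("n_perm must be >= 1")
  labels <- as.character(labels)
  tab <- table(labels)
  if (length(tab) < 2) stopf("need at least 2 groups")
  if (any(tab < 2)) stopf("every group needs at least 2 samples")
  if (length(labels) != ncol(m)) stopf("one label per sample column required")
  D <- as.matrix(dist(t(m), method = metric))
  off <- upper.tri(D)
  stat <- function(g) {
    same <- outer(g, g, "==")[off]
    mean(D[off][!same]) - mean(D[off][same])
  }
  t_obs <- stat(labels)
  t_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    stat(sample(labels)), numeric(1)))
  structure(list(statistic = t_obs,
                 p_value = (1 + sum(t_perm >= t_obs)) / (1 + n_perm),
                 n_perm = n_perm, seed = seed,
                 perm_statistics = t_perm),
            class = "perm_test")
}

#' Principal component analysis of samples
#'
#' PCA of the centred samples x features matrix (no scaling): scores per
#' sample, loadings per feature, and percent variance explained per
#' component (non-increasing; sums to 100 over all components).
#'
#' @param m matrix, features x samples.
#' @param n_components number of components to retain (default: all).
#' @return list (class `pca_result`): `scores` (samples x components),
#'   `loadings` (features x components), `variance_explained_pct`,
#'   `center`.
#' @export
pca <- function(m, n_components = NULL) {
  X <- t(m)  # samples x features
  full <- min(dim(X)) - 0L
  if (is.null(n_components)) n_components <- full
  if (n_components <= 0) stopf("n_components must be positive")
  n_components <- min(n_components, full)
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  ve <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  keep <- seq_len(min(n_components, ncol(pc$x)))
  structure(list(scores = pc$x[, keep, drop = FALSE],
                 loadings = pc$rotation[, keep, drop = FALSE],
                 variance_explained_pct = ve,
                 center = pc$center),
            class = "pca_result")
}
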