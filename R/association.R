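#' Parameter associations, correlation networks and marker trees
#'
#' Spearman rank correlations of features against process parameters
#' (dual significance levels 0.05 / 0.01, no multiplicity correction by
#' default, mirroring the original dual-alpha reporting), a signed
#' correlation network for graph export, and CART decision-tree discovery
#' of marker metaproteins for binarized process conditions with a 60/40
#' train/test split.
#'
#' @name association
NULL

#' Spearman rank correlation with p-value
#'
#' rho is the Pearson correlation of midranks (ties averaged). The
#' p-value uses the t approximation `t = rho * sqrt((n-2)/(1-rho^2))` on
#' n-2 degrees of freedom; for n <= 8 an exact permutation p-value over
#' all n! rank permutations is available via `p_method = "exact"`.
#'
#' @param x,y numeric vectors of equal length >= 5 (pairs with missing
#'   values are dropped).
#' @param p_method "t" (default) or "exact" (n <= 8).
#' @return list(rho, p_value, n).
#' @export
spearman <- function(x, y, p_method = c("t", "exact")) {
  p_method <- match.arg(p_method)
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5) stopf("spearman needs at least 5 complete pairs (have %d)", n)
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stopf("spearman: constant vector, rho undefined")
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (p_method == "exact") {
    if (n > 8) stopf("exact permutation p only for n <= 8")
    perms <- permutations_of(n)
    rhos <- apply(perms, 1, function(p) cor(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * pt(-abs(t_stat), df = n - 2)
    }
  }
  list(rho = rho, p_value = p, n = n)
}

permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (i in seq_len(n)) {
    rows <- nrow(sub)
    block <- cbind(rep.int(i, rows), sub + (sub >= i))
    out[r + seq_len(rows), ] <- block
    r <- r + rows
  }
  out
}

#' Correlate features with process parameters
#'
#' Computes Spearman rho and p for every feature x numeric-parameter pair
#' (and optionally every feature x feature pair), pairwise-dropping
#' missing parameter values. Pairs with fewer than 5 complete
#' observations, or with a constant vector, are flagged not evaluable.
#'
#' @param m abundance matrix (features x samples).
#' @param parameters parameter table with `sample_id` matching the matrix
#'   columns.
#' @param feature_pairs also correlate features with each other.
#' @param adjust optional p-adjustment method (e.g. "BH") applied on top;
#'   raw p-values are always reported.
#' @return data.frame (feature, parameter, rho, p_value, p_adjusted, n,
#'   significant_at, evaluable); significant_at is "0.01", "0.05" or
#'   "none" from the raw p.
#' @export
correlation_screen <- function(m, parameters, feature_pairs = FALSE,
                               adjust = NULL) {
  params <- as.data.frame(parameters)
  rows <- match(colnames(m), params$sample_id)
  if (any(is.na(rows)))
    stopf("parameter table lacks sample(s): %s",
          paste(colnames(m)[is.na(rows)], collapse = ", "))
  params <- params[rows, , drop = FALSE]
  num_cols <- names(params)[vapply(params, is.numeric, logical(1))]
  pairs <- expand.grid(feature = rownames(m), parameter = num_cols,
                       stringsAsFactors = FALSE)
  if (feature_pairs && nrow(m) > 1) {
    fp <- t(utils::combn(rownames(m), 2))
    pairs <- rbind(pairs, data.frame(feature = fp[, 1], parameter = fp[, 2],
                                     stringsAsFactors = FALSE))
  }
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    f <- pairs$feature[i]; p <- pairs$parameter[i]
    x <- m[f, ]
    y <- if (p %in% num_cols) params[[p]] else m[p, ]
    ok <- complete.cases(x, y)
    if (sum(ok) < 5 || length(unique(x[ok])) < 2 || length(unique(y[ok])) < 2)
      return(data.frame(feature = f, parameter = p, rho = NA_real_,
                        p_value = NA_real_, n = sum(ok), evaluable = FALSE,
                        stringsAsFactors = FALSE))
    sp <- spearman(x, y)
    data.frame(feature = f, parameter = p, rho = sp$rho, p_value = sp$p_value,
               n = sp$n, evaluable = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- if (!is.null(adjust))
    stats::p.adjust(out$p_value, method = adjust) else out$p_value
  out$significant_at <- ifelse(!out$evaluable | is.na(out$p_value), "none",
                        ifelse(out$p_value <= 0.01, "0.01",
                        ifelse(out$p_value <= 0.05, "0.05", "none")))
  out
}

#' Build a signed correlation network
#'
#' Edges are feature-parameter (and feature-feature) correlations passing
#' the chosen significance level; the edge sign is the sign of rho. All
#' parameters appear as nodes even when unconnected; node degree is
#' recorded (node size in the original graphs).
#'
#' @param correlations output of [correlation_screen()].
#' @param alpha significance level, 0.05 or 0.01.
#' @param parameter_ids ids to always include as parameter nodes.
#' @param node_kind function mapping a feature id to a node kind
#'   (default: everything not a parameter is "taxon").
#' @return `correlation_network`: list(nodes, edges, alpha).
#' @export
build_network <- function(correlations, alpha = 0.05,
                          parameter_ids = unique(correlations$parameter),
                          node_kind = function(id) "taxon") {
  if (!alpha %in% c(0.05, 0.01))
    stopf("alpha must be 0.05 or 0.01")
  ok <- correlations$evaluable & !is.na(correlations$p_value) &
    correlations$p_value <= alpha
  edges <- correlations[ok, , drop = FALSE]
  edges <- data.frame(u = edges$feature, v = edges$parameter,
                      rho = edges$rho, sign = as.integer(sign(edges$rho)),
                      p = edges$p_value, stringsAsFactors = FALSE)
  ids <- unique(c(parameter_ids, edges$u, edges$v))
  kind <- ifelse(ids %in% parameter_ids, "parameter",
                 vapply(ids, node_kind, character(1)))
  degree <- vapply(ids, function(i) sum(edges$u == i | edges$v == i),
                   integer(1))
  nodes <- data.frame(id = ids, kind = unname(kind), degree = unname(degree),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, alpha = alpha),
            class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  cat(sprintf("correlation network: %d nodes, %d edges (alpha = %s)\n",
              nrow(x$nodes), nrow(x$edges), format(x$alpha)))
  invisible(x)
}

#' Binarize a process parameter into high/low
#'
#' Classification thresholds are taken from the literature where
#' available (TAN 4200 mg/L, alternatively 3000 mg/L; 40 degC as the
#' thermophile boundary); otherwise the parameter's median over
#' non-missing samples is used. A value strictly above the threshold is
#' "high"; values at the threshold are "low".
#'
#' @param values numeric parameter values.
#' @param threshold a number, or "median".
#' @return factor with levels low/high (NA for missing values) and
#'   attributes `threshold` / `threshold_source`.
#' @export
binarize_parameter <- function(values, threshold = "median") {
  if (all(is.na(values))) stopf("all parameter values missing")
  src <- if (identical(threshold, "median")) "median" else "literature"
  thr <- if (identical(threshold, "median"))
    median(values, na.rm = TRUE) else as.numeric(threshold)
  out <- factor(ifelse(values > thr, "high", "low"), levels = c("low", "high"))
  attr(out, "threshold") <- thr
  attr(out, "threshold_source") <- src
  out
}

#' Literature classification thresholds shipped with the package
#' @return named list of thresholds (others default to "median").
#' @export
default_thresholds <- function() {
  list(TAN = 4200,          # mg/L (alternative in the literature: 3000)
       temperature = 40)    # degC, thermophile boundary
}

## ---- CART ------------------------------------------------------------

node_impurity <- function(y, levels) {
  p <- tabulate(y, nbins = levels) / length(y)
  1 - sum(p^2)
}

best_split <- function(X, y, levels, min_leaf) {
  n <- nrow(X)
  parent <- node_impurity(y, levels)
  best <- NULL
  for (j in seq_len(ncol(X))) {
    v <- X[, j]
    uv <- sort(unique(v))
    if (length(uv) < 2) next
    cuts <- (uv[-1] + uv[-length(uv)]) / 2
    for (cut in cuts) {
      left <- v <= cut
      nl <- sum(left)
      if (nl < min_leaf || n - nl < min_leaf) next
      dec <- parent - (nl / n) * node_impurity(y[left], levels) -
        ((n - nl) / n) * node_impurity(y[!left], levels)
      # strict improvement; ties keep the earlier (lower feature index,
      # lower cut) candidate -> deterministic trees
      if (is.null(best) || dec > best$dec + 1e-12)
        best <- list(feature = j, cut = cut, dec = dec)
    }
  }
  best
}

grow_tree <- function(X, y, levels, depth, max_depth, min_leaf) {
  counts <- tabulate(y, nbins = levels)
  leaf <- list(leaf = TRUE, class = which.max(counts), counts = counts)
  if (depth >= max_depth || length(unique(y)) < 2 || nrow(X) < 2 * min_leaf)
    return(leaf)
  sp <- best_split(X, y, levels, min_leaf)
  if (is.null(sp) || sp$dec <= 1e-12) return(leaf)
  left <- X[, sp$feature] <= sp$cut
  list(leaf = FALSE, feature = sp$feature, cut = sp$cut, counts = counts,
       impurity_decrease = sp$dec,
       left = grow_tree(X[left, , drop = FALSE], y[left], levels,
                        depth + 1L, max_depth, min_leaf),
       right = grow_tree(X[!left, , drop = FALSE], y[!left], levels,
                         depth + 1L, max_depth, min_leaf))
}

#' Fit a CART classification tree
#'
#' Binary splits chosen to maximize the Gini-impurity decrease,
#' exhaustively over features and midpoints between sorted distinct
#' values; growth stops at `max_depth` or when a child would fall below
#' `min_leaf` samples. Ties are broken deterministically (lower feature
#' index, then lower cut), so fitting needs no randomness. Single-class
#' labels yield a single-leaf tree.
#'
#' @param X samples x features numeric matrix.
#' @param y class labels (factor or coercible).
#' @param max_depth maximum depth (default 3).
#' @param min_leaf minimum samples per leaf (default 2).
#' @return `cart_tree`: nested split list plus `feature_names`,
#'   `classes`.
#' @export
fit_decision_tree <- function(X, y, max_depth = 3, min_leaf = 2) {
  X <- as.matrix(X)
  y <- factor(y)
  yi <- as.integer(y)
  root <- grow_tree(X, yi, nlevels(y), 0L, max_depth, min_leaf)
  structure(list(root = root, feature_names = colnames(X),
                 classes = levels(y),
                 settings = list(max_depth = max_depth, min_leaf = min_leaf)),
            class = "cart_tree")
}

#' @rdname fit_decision_tree
#' @param tree a fitted `cart_tree`.
#' @param newdata samples x features matrix.
#' @return factor of predicted classes.
#' @export
predict_tree <- function(tree, newdata) {
  newdata <- as.matrix(newdata)
  walk <- function(node, x) {
    while (!node$leaf)
      node <- if (x[node$feature] <= node$cut) node$left else node$right
    node$class
  }
  cls <- vapply(seq_len(nrow(newdata)), function(i)
    walk(tree$root, newdata[i, ]), integer(1))
  factor(tree$classes[cls], levels = tree$classes)
}

#' @rdname fit_decision_tree
#' @export
tree_depth <- function(tree) {
  rec <- function(node) if (node$leaf) 0L else
    1L + max(rec(node$left), rec(node$right))
  rec(tree$root)
}

root_feature <- function(tree) {
  if (tree$root$leaf) NA_character_
  else tree$feature_names[tree$root$feature]
}

#' Marker discovery with a stratified 60/40 split
#'
#' Randomly splits samples into 60% training and 40% test (stratified by
#' class), fits a CART tree on the training set and reports training and
#' test error; the proposed marker is the root-split feature. If a class
#' is absent from the training split (only possible for single-member
#' classes), the split is redrawn with the next seed.
#'
#' @param X samples x features matrix.
#' @param y class labels.
#' @param train_frac training fraction (default 0.6).
#' @param seed integer seed for the split.
#' @param max_depth,min_leaf passed to [fit_decision_tree()].
#' @return `marker_result`: list(marker, tree, train_error, test_error,
#'   train_idx, test_idx, seed).
#' @export
train_test_marker <- function(X, y, train_frac = 0.6, seed = 1,
                              max_depth = 3, min_leaf = 2) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) < 2) stopf("need at least 2 classes")
  if (any(table(y) < 5))
    warnf("fewer than 5 samples in class(es): %s",
          paste(names(table(y))[table(y) < 5], collapse = ", "))
  n <- length(y)
  draw <- function(s) with_seed(s, {
    idx <- unlist(lapply(levels(y), function(cl) {
      i <- which(y == cl)
      sample(i, max(1L, round(train_frac * length(i))))
    }))
    sort(idx)
  })
  s <- seed
  repeat {
    train_idx <- draw(s)
    if (all(levels(y) %in% y[train_idx]) && length(train_idx) < n) break
    s <- s + 1L
  }
  test_idx <- setdiff(seq_len(n), train_idx)
  tree <- fit_decision_tree(X[train_idx, , drop = FALSE], y[train_idx],
                            max_depth = max_depth, min_leaf = min_leaf)
  err <- function(idx) mean(predict_tree(tree, X[idx, , drop = FALSE]) != y[idx])
  structure(list(marker = root_feature(tree), tree = tree,
                 train_error = err(train_idx), test_error = err(test_idx),
                 train_idx = train_idx, test_idx = test_idx, seed = s),
            class = "marker_result")
}
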