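# In-package CART engine.
#
# A single weighted regression-tree builder backs the decision-tree,
# random-forest, AdaBoost and gradient-boosting catalog members (the
# environment ships no tree learner, so the primitive is built here once).
# Squared-error impurity on a 0/1 target is equivalent to Gini for
# classification splits; boosting overrides leaf values with Newton steps.

# Fit a regression tree on (X, y, w). Returns parallel node vectors; node 1
# is the root. `hess` (optional) supplies per-row curvature for Newton leaf
# values sum(grad)/(sum(hess)+lambda) used by gradient boosting.
fit_reg_tree <- function(X, y, w, max_depth = 6L, min_node = 10L,
                         mtry = ncol(X), hess = NULL, lambda = 0) {
  n <- nrow(X)
  p <- ncol(X)
  nodes <- new.env(parent = emptyenv())
  nodes$feature <- integer(0); nodes$split <- numeric(0)
  nodes$left <- integer(0); nodes$right <- integer(0)
  nodes$value <- numeric(0); nodes$is_leaf <- logical(0)

  leaf_value <- function(idx) {
    if (is.null(hess)) {
      sum(w[idx] * y[idx]) / sum(w[idx])
    } else {
      sum(w[idx] * y[idx]) / (sum(hess[idx]) + lambda)
    }
  }

  new_node <- function() {
    i <- length(nodes$feature) + 1L
    nodes$feature[i] <- 0L; nodes$split[i] <- 0
    nodes$left[i] <- 0L; nodes$right[i] <- 0L
    nodes$value[i] <- 0; nodes$is_leaf[i] <- TRUE
    i
  }

  best_split <- function(idx, feats) {
    wy <- w[idx] * y[idx]
    W <- sum(w[idx]); T <- sum(wy)
    base <- T^2 / W
    best <- list(gain = 1e-12, feature = 0L, split = NA_real_)
    for (f in feats) {
      x <- X[idx, f]
      o <- order(x)
      xs <- x[o]
      cw <- cumsum(w[idx][o])
      ct <- cumsum(wy[o])
      m <- length(xs)
      valid <- which(xs[-m] < xs[-1])
      valid <- valid[valid >= min_node & (m - valid) >= min_node]
      if (!length(valid)) next
      gain <- ct[valid]^2 / cw[valid] +
        (T - ct[valid])^2 / pmax(W - cw[valid], 1e-12) - base
      k <- which.max(gain)
      if (gain[k] > best$gain) {
        best <- list(gain = gain[k], feature = f,
                     split = (xs[valid[k]] + xs[valid[k] + 1L]) / 2)
      }
    }
    best
  }

  grow <- function(idx, depth) {
    node <- new_node()
    nodes$value[node] <- leaf_value(idx)
    if (depth >= max_depth || length(idx) < 2L * min_node ||
        abs(max(y[idx]) - min(y[idx])) < 1e-12) {
      return(node)
    }
    feats <- if (mtry < p) sample.int(p, mtry) else seq_len(p)
    sp <- best_split(idx, feats)
    if (sp$feature == 0L) return(node)
    go_left <- X[idx, sp$feature] <= sp$split
    nodes$is_leaf[node] <- FALSE
    nodes$feature[node] <- sp$feature
    nodes$split[node] <- sp$split
    l <- grow(idx[go_left], depth + 1L)
    r <- grow(idx[!go_left], depth + 1L)
    nodes$left[node] <- l
    nodes$right[node] <- r
    node
  }

  grow(seq_len(n), 0L)
  list(feature = nodes$feature, split = nodes$split, left = nodes$left,
       right = nodes$right, value = nodes$value, is_leaf = nodes$is_leaf)
}

# route every row of X to its leaf; returns leaf node ids
tree_leaves <- function(tree, X) {
  idx <- rep(1L, nrow(X))
  repeat {
    open <- which(!tree$is_leaf[idx])
    if (!length(open)) break
    node <- idx[open]
    xv <- X[cbind(open, tree$feature[node])]
    idx[open] <- ifelse(xv <= tree$split[node], tree$left[node], tree$right[node])
  }
  idx
}

predict_tree <- function(tree, X) tree$value[tree_leaves(tree, X)]

# Gradient boosting with logistic loss and Newton leaf values. `style`
# switches the growth defaults between the package's xgboost-like and
# lightgbm-like catalog entries.
fit_gbm <- function(X, y, w, n_rounds = 60L, learning_rate = 0.3,
                    max_depth = 3L, min_node = 10L, lambda = 1,
                    subsample = 1) {
  n <- nrow(X)
  p0 <- sum(w * y) / sum(w)
  p0 <- min(max(p0, 1e-6), 1 - 1e-6)
  f0 <- qlogis(p0)
  F <- rep(f0, n)
  trees <- vector("list", n_rounds)
  for (t in seq_len(n_rounds)) {
    p <- plogis(F)
    grad <- w * (y - p)
    h <- pmax(w * p * (1 - p), 1e-12)
    rows <- if (subsample < 1) sample.int(n, max(2L, floor(subsample * n))) else seq_len(n)
    tr <- fit_reg_tree(X[rows, , drop = FALSE], (y - p)[rows], w[rows],
                       max_depth = max_depth, min_node = min_node,
                       hess = NULL)
    # Newton leaf values over the full sample routed through the tree
    lv <- tree_leaves(tr, X)
    for (leaf in unique(lv)) {
      sel <- lv == leaf
      tr$value[leaf] <- sum(grad[sel]) / (sum(h[sel]) + lambda)
    }
    F <- F + learning_rate * tr$value[lv]
    trees[[t]] <- tr
  }
  list(f0 = f0, learning_rate = learning_rate, trees = trees)
}

predict_gbm <- function(model, X) {
  F <- rep(model$f0, nrow(X))
  for (tr in model$trees) F <- F + model$learning_rate * predict_tree(tr, X)
  plogis(F)
}
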