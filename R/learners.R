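#' The nine-algorithm learner catalog
#'
#' Stable order; it defines the Q-table column order used by the ensemble
#' composer.
#'
#' @return Character vector of 9 algorithm ids.
#' @export
learner_catalog <- function() {
  c("logistic_regression", "random_forest", "naive_bayes",
    "gradient_boosting_xgb", "gradient_boosting_lgbm", "knn",
    "decision_tree", "adaboost", "dwnn")
}

#' Specify a learner
#'
#' @param algorithm One of [learner_catalog()].
#' @param hyperparameters Named list overriding the algorithm's documented
#'   defaults (library-standard values; the originating study never lists
#'   per-algorithm settings).
#' @param seed Integer seed; fitting is deterministic given it.
#' @return A `learner_spec`.
#' @export
learner_spec <- function(algorithm, hyperparameters = list(), seed = 1L) {
  if (!algorithm %in% learner_catalog()) {
    stopf("unknown algorithm '%s'; see learner_catalog()", algorithm)
  }
  structure(list(algorithm = algorithm, hyperparameters = hyperparameters,
                 seed = as.integer(seed)),
            class = "learner_spec")
}

#' Inverse-frequency class weights
#'
#' Per-class weight `n / (n_classes * n_c)`, so the weighted sample count
#' equals n and the minority/majority weight ratio is the inverse frequency
#' ratio. Used to counter label imbalance during training.
#'
#' @param labels 0/1 vector containing both classes.
#' @return Named numeric vector `c("0" = w0, "1" = w1)`.
#' @export
class_weights <- function(labels) {
  tab <- table(factor(labels, levels = c(0, 1)))
  if (any(tab == 0)) stopf("class_weights requires both classes present")
  n <- sum(tab)
  w <- n / (2 * as.numeric(tab))
  setNames(w, c("0", "1"))
}

default_hyper <- function(algorithm) {
  switch(algorithm,
    logistic_regression   = list(),
    random_forest         = list(n_trees = 40L, max_depth = 10L, min_node = 5L),
    naive_bayes           = list(),
    gradient_boosting_xgb = list(n_rounds = 60L, learning_rate = 0.3,
                                 max_depth = 3L, min_node = 10L, lambda = 1),
    gradient_boosting_lgbm = list(n_rounds = 80L, learning_rate = 0.1,
                                  max_depth = 6L, min_node = 20L, lambda = 0,
                                  subsample = 0.9),
    knn                   = list(k = 15L),
    decision_tree         = list(max_depth = 8L, min_node = 10L),
    adaboost              = list(n_rounds = 50L, max_depth = 2L),
    dwnn                  = list())
}

#' Fit a catalog learner
#'
#' @param spec A [learner_spec()].
#' @param X Numeric feature matrix (rows = entries).
#' @param y 0/1 labels, length `nrow(X)`.
#' @param weights Optional per-sample weights (see [class_weights()]).
#' @return A fitted `modsew_learner` handle exposing [predict_proba()].
#' @export
fit_learner <- function(spec, X, y, weights = NULL) {
  stopifnot(inherits(spec, "learner_spec"))
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stopf("X has %d rows but y has %d labels", nrow(X), length(y))
  w <- weights %||% rep(1, length(y))
  hp <- modifyList(default_hyper(spec$algorithm), spec$hyperparameters)
  fitted <- with_seed(spec$seed, switch(spec$algorithm,
    logistic_regression = fit_logreg(X, y, w),
    random_forest = fit_rf(X, y, w, hp),
    naive_bayes = fit_nb(X, y, w),
    gradient_boosting_xgb = fit_gbm(X, y, w, hp$n_rounds, hp$learning_rate,
                                    hp$max_depth, hp$min_node, hp$lambda),
    gradient_boosting_lgbm = fit_gbm(X, y, w, hp$n_rounds, hp$learning_rate,
                                     hp$max_depth, hp$min_node, hp$lambda,
                                     hp$subsample),
    knn = fit_knn(X, y, w, hp),
    decision_tree = fit_reg_tree(X, y, w, hp$max_depth, hp$min_node),
    adaboost = fit_adaboost(X, y, w, hp),
    dwnn = {
      arch_hp <- hp
      arch_hp$seed <- spec$seed
      arch <- do.call(dwnn_arch, arch_hp)
      train_dwnn(build_dwnn(ncol(X), arch), X, y, w)
    }))
  structure(list(algorithm = spec$algorithm, spec = spec, model = fitted,
                 n_features = ncol(X), feature_names = colnames(X)),
            class = c(paste0("modsew_", spec$algorithm), "modsew_learner"))
}

#' Predicted probability of the positive class
#'
#' @param object A fitted learner / ensemble handle.
#' @param X Feature matrix.
#' @param ... Unused.
#' @return Numeric vector in \[0, 1\], one per row.
#' @export
predict_proba <- function(object, X, ...) UseMethod("predict_proba")

#' @export
predict_proba.modsew_learner <- function(object, X, ...) {
  X <- as.matrix(X)
  if (ncol(X) != object$n_features) {
    stopf("model expects %d features, got %d", object$n_features, ncol(X))
  }
  m <- object$model
  p <- switch(object$algorithm,
    logistic_regression = predict_logreg(m, X),
    random_forest = predict_rf(m, X),
    naive_bayes = predict_nb(m, X),
    gradient_boosting_xgb = predict_gbm(m, X),
    gradient_boosting_lgbm = predict_gbm(m, X),
    knn = predict_knn(m, X),
    decision_tree = pmin(pmax(predict_tree(m, X), 0), 1),
    adaboost = predict_adaboost(m, X),
    dwnn = dwnn_forward(m, X)$prob)
  pmin(pmax(p, 0), 1)
}

#' @export
predict_proba.dwnn <- function(object, X, ...) {
  dwnn_forward(object, as.matrix(X))$prob
}

# ---- individual algorithms ------------------------------------------------

fit_logreg <- function(X, y, w) {
  fit <- suppressWarnings(glm.fit(cbind(`(Intercept)` = 1, X), y, weights = w,
                                  family = binomial()))
  coefs <- fit$coefficients
  coefs[is.na(coefs)] <- 0
  list(coef = coefs)
}

predict_logreg <- function(m, X) plogis(drop(cbind(1, X) %*% m$coef))

fit_nb <- function(X, y, w) {
  stats_for <- function(cls) {
    idx <- y == cls
    ws <- w[idx] / sum(w[idx])
    mu <- colSums(X[idx, , drop = FALSE] * ws)
    va <- colSums(sweep(X[idx, , drop = FALSE], 2, mu)^2 * ws)
    list(mu = mu, var = pmax(va, 1e-9 * max(apply(X, 2, var), 1)))
  }
  list(prior1 = sum(w[y == 1]) / sum(w), c0 = stats_for(0), c1 = stats_for(1))
}

predict_nb <- function(m, X) {
  ll <- function(cl) {
    rowSums(sweep(sweep(X, 2, cl$mu)^2, 2, -2 * cl$var, "/") -
              matrix(0.5 * log(2 * pi * cl$var), nrow(X), ncol(X), byrow = TRUE))
  }
  l1 <- ll(m$c1) + log(m$prior1)
  l0 <- ll(m$c0) + log(1 - m$prior1)
  plogis(l1 - l0)
}

fit_knn <- function(X, y, w, hp) {
  ctr <- colMeans(X)
  scl <- pmax(apply(X, 2, sd), 1e-8)
  list(X = sweep(sweep(X, 2, ctr), 2, scl, "/"), y = y, w = w,
       k = min(hp$k, nrow(X)), center = ctr, scale = scl)
}

predict_knn <- function(m, X) {
  Xs <- sweep(sweep(X, 2, m$center), 2, m$scale, "/")
  d2 <- outer(rowSums(Xs^2), rowSums(m$X^2), "+") - 2 * tcrossprod(Xs, m$X)
  apply(d2, 1, function(d) {
    nn <- order(d)[seq_len(m$k)]
    sum(m$w[nn] * m$y[nn]) / sum(m$w[nn])
  })
}

fit_rf <- function(X, y, w, hp) {
  n <- nrow(X)
  mtry <- max(1L, floor(sqrt(ncol(X))))
  trees <- lapply(seq_len(hp$n_trees), function(t) {
    rows <- sample.int(n, n, replace = TRUE)
    fit_reg_tree(X[rows, , drop = FALSE], y[rows], w[rows],
                 max_depth = hp$max_depth, min_node = hp$min_node, mtry = mtry)
  })
  list(trees = trees)
}

predict_rf <- function(m, X) {
  preds <- vapply(m$trees, function(tr) predict_tree(tr, X), numeric(nrow(X)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = nrow(X))
  pmin(pmax(rowMeans(preds), 0), 1)
}

# discrete AdaBoost with shallow CART weak learners; probability via the
# logistic link of the aggregated margin
fit_adaboost <- function(X, y, w, hp) {
  n <- nrow(X)
  d <- w / sum(w)
  ys <- 2 * y - 1
  rounds <- list()
  for (t in seq_len(hp$n_rounds)) {
    tr <- fit_reg_tree(X, y, d, max_depth = hp$max_depth,
                       min_node = max(5L, floor(n / 50)))
    pred <- ifelse(predict_tree(tr, X) >= 0.5, 1, -1)
    err <- sum(d[pred != ys])
    err <- min(max(err, 1e-10), 1 - 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    rounds[[t]] <- list(tree = tr, alpha = alpha)
    d <- d * exp(-alpha * ys * pred)
    d <- d / sum(d)
    if (err >= 0.5 || err < 1e-9) break
  }
  list(rounds = rounds)
}

predict_adaboost <- function(m, X) {
  F <- rep(0, nrow(X))
  for (r in m$rounds) {
    F <- F + r$alpha * ifelse(predict_tree(r$tree, X) >= 0.5, 1, -1)
  }
  plogis(2 * F)
}

# ---- cross-validation -----------------------------------------------------

#' Out-of-fold probability predictions
#'
#' k-fold cross-validated predictions; with `groups` supplied (patient ids)
#' the folds are group-wise, so no patient appears on both sides of any fold.
#'
#' @param spec A [learner_spec()].
#' @param X,y Training data.
#' @param k Folds (default 5).
#' @param seed Fold-assignment seed.
#' @param groups Optional grouping vector (length `nrow(X)`).
#' @param weights Optional sample weights.
#' @return Numeric vector of out-of-fold probabilities, one per row.
#' @export
oof_predictions <- function(spec, X, y, k = 5L, seed = 1L, groups = NULL,
                            weights = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k < 2L) stopf("k must be >= 2")
  if (k > n) stopf("k = %d exceeds n = %d", k, n)
  fold <- with_seed(seed, {
    if (is.null(groups)) {
      sample(rep_len(seq_len(k), n))
    } else {
      g <- unique(groups)
      gf <- setNames(sample(rep_len(seq_len(k), length(g))), g)
      unname(gf[as.character(groups)])
    }
  })
  out <- rep(NA_real_, n)
  for (f in seq_len(k)) {
    test <- fold == f
    if (!any(test) || all(test)) next
    fit <- fit_learner(spec, X[!test, , drop = FALSE], y[!test],
                       weights = weights[!test])
    out[test] <- predict_proba(fit, X[test, , drop = FALSE])
  }
  out
}
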