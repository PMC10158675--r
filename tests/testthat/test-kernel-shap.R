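test_that("the Shapley kernel weight follows the closed form", {
  expect_equal(kernel_weight(4, 2), 3 / (6 * 2 * 2))   # 0.125
  expect_equal(kernel_weight(2, 1), 0.5)
  for (M in c(5, 9)) {
    s <- 1:(M - 1)
    expect_equal(kernel_weight(M, s), kernel_weight(M, M - s))  # symmetry
  }
  expect_error(kernel_weight(4, 0), "constraints")
  expect_error(kernel_weight(4, 4), "constraints")
})

test_that("enumeration-mode explanations recover linear-model attributions", {
  withr::with_seed(2, {
    M <- 5
    w <- rnorm(M)
    bg <- matrix(rnorm(40 * M), 40, M, dimnames = list(NULL, paste0("f", 1:M)))
    x <- setNames(rnorm(M), paste0("f", 1:M))
  })
  f <- function(X) drop(as.matrix(X) %*% w)
  e <- explain(f, x, bg)
  expect_equal(unname(e$attributions), unname(w * (x - colMeans(bg))),
               tolerance = 1e-6)
  expect_equal(e$base_value + sum(e$attributions), e$model_output,
               tolerance = 1e-9)
  # a feature identical across instance and background gets zero attribution
  bg2 <- bg; bg2[, 3] <- x[[3]]
  e2 <- explain(f, x, bg2)
  expect_equal(unname(e2$attributions[[3]]), 0, tolerance = 1e-9)
})

test_that("exact Shapley satisfies symmetry, efficiency and null-player", {
  bg <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  bg[, 2] <- bg[, 1]   # symmetry needs interchangeable roles in the background
  f_sym <- function(X) X[, 1] + X[, 2]
  x <- c(a = 2, b = 2, c = 5)
  e <- exact_shapley(f_sym, x, bg)
  expect_equal(e$attributions[["a"]], e$attributions[["b"]], tolerance = 1e-9)
  expect_equal(e$base_value + sum(e$attributions), e$model_output,
               tolerance = 1e-12)
  expect_equal(e$attributions[["c"]], 0, tolerance = 1e-12)
  e0 <- exact_shapley(function(X) rep(0.7, nrow(X)), x, bg)
  expect_true(all(abs(e0$attributions) < 1e-12))
  expect_error(exact_shapley(f_sym, rnorm(13), matrix(0, 2, 13)), "2\\^M")
})

test_that("kernel SHAP agrees with exact Shapley on a forest at M = 6", {
  fx <- fx_cohort()
  feats <- c("currentMinGcs", "currentMaxCreatinine", "currentMaxBilirubin",
             "gcs24HoursMods", "renal24HoursMods", "currentMinPlatelet")
  X <- as.matrix(fx$entries[, feats])
  y <- fx$entries$label
  fit <- fit_learner(learner_spec("random_forest", list(n_trees = 20), seed = 2),
                     X, y)
  f <- function(M) predict_proba(fit, as.matrix(M))
  bg <- X[withr::with_seed(6, sample(nrow(X), 25)), ]
  pos <- which(y == 1)
  x <- X[pos[[1]], ]
  e_k <- explain(f, x, bg)        # full enumeration at M = 6
  e_x <- exact_shapley(f, x, bg)
  expect_lt(max(abs(e_k$attributions - e_x$attributions)), 0.01)
  expect_equal(e_k$base_value + sum(e_k$attributions), e_k$model_output,
               tolerance = 1e-6)
})

test_that("sampled explanations converge toward exact Shapley", {
  withr::with_seed(7, {
    M <- 8
    W <- rnorm(M)
    bg <- matrix(rnorm(30 * M), 30, M, dimnames = list(NULL, paste0("f", 1:M)))
    x <- setNames(rnorm(M) + 1, paste0("f", 1:M))
  })
  f <- function(X) plogis(drop(as.matrix(X) %*% W))
  ref <- exact_shapley(f, x, bg)$attributions
  err <- vapply(c(30, 120, 2^M - 2), function(nc) {
    e <- explain(f, x, bg, n_coalitions = nc, seed = 11)
    max(abs(e$attributions - ref))
  }, numeric(1))
  expect_lt(err[2], err[1] + 1e-9)
  expect_lt(err[3], 1e-8)          # full coverage reproduces exact values
  # local accuracy holds even in sampled mode
  e_s <- explain(f, x, bg, n_coalitions = 40, seed = 3)
  expect_equal(e_s$base_value + sum(e_s$attributions), e_s$model_output,
               tolerance = 1e-9)
  expect_error(explain(f, x, bg, n_coalitions = 4), "at least M")
  expect_error(explain(f, x, bg[0, , drop = FALSE]), "non-empty")
})

test_that("background snapshots are frozen and reproducible", {
  fx <- fx_cohort()
  bg1 <- background_snapshot(fx$entries, n = 30, seed = 4)
  bg2 <- background_snapshot(fx$entries, n = 30, seed = 4)
  expect_identical(attr(bg1, "snapshot_id"), attr(bg2, "snapshot_id"))
  f <- function(X) rowMeans(as.matrix(X[, 1:3, drop = FALSE]))
  x <- unlist(fx$entries[5, feature_names()])
  e1 <- explain(f, x, bg1, n_coalitions = 60, seed = 2)
  e2 <- explain(f, x, bg2, n_coalitions = 60, seed = 2)
  expect_identical(e1, e2)
})

test_that("global importance ranks by mean absolute attribution", {
  mk <- function(phi) modsew:::new_shap_explanation(0.1, phi, 0.1 + sum(phi))
  es <- list(mk(c(a = 0.5, b = -0.1, c = 0)),
             mk(c(a = -0.4, b = 0.2, c = 0)))
  gi <- global_importance(es)
  expect_identical(gi$feature, c("a", "b", "c"))
  expect_equal(gi$mean_abs_phi, c(0.45, 0.15, 0))
  expect_identical(global_importance(es[1])$feature[1], "a")
  expect_error(global_importance(list(mk(c(a = 1)), mk(c(z = 1)))),
               "inconsistent")

  # planted dominant weight is ranked first on a synthetic model
  withr::with_seed(2, {
    M <- 6
    W <- c(5, rnorm(M - 1, 0, 0.3))
    bg <- matrix(rnorm(25 * M), 25, M, dimnames = list(NULL, paste0("f", 1:M)))
    xs <- lapply(1:5, function(i) setNames(rnorm(M), paste0("f", 1:M)))
  })
  f <- function(X) drop(as.matrix(X) %*% W)
  es2 <- lapply(xs, function(x) explain(f, x, bg, n_coalitions = 40, seed = 1))
  expect_identical(global_importance(es2)$feature[[1]], "f1")
})
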