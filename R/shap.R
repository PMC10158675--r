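#' Shapley kernel weight
#'
#' Weight of a coalition of size `s` among `M` features in the
#' kernel-weighted least-squares formulation:
#' `(M - 1) / (choose(M, s) * s * (M - s))`. The empty and full coalitions
#' carry infinite weight and are handled as the two equality constraints
#' (base value and local accuracy), not as finite-weight rows.
#'
#' @param M Number of features.
#' @param s Coalition size, `0 < s < M`.
#' @return Numeric weight.
#' @export
kernel_weight <- function(M, s) {
  if (any(s <= 0 | s >= M)) {
    stopf("kernel weight defined for 0 < s < M; boundary coalitions are constraints")
  }
  (M - 1) / (choose(M, s) * s * (M - s))
}

# value function: mean model output with features outside S replaced by
# background rows (marginal expectation over the frozen background sample).
# Z is a logical matrix of coalitions (rows); returns one value per row.
coalition_values <- function(model_fn, x, background, Z) {
  n_bg <- nrow(background)
  M <- length(x)
  big <- background[rep(seq_len(n_bg), times = nrow(Z)), , drop = FALSE]
  for (j in seq_len(M)) {
    on <- rep(Z[, j], each = n_bg)
    big[on, j] <- x[[j]]
  }
  preds <- model_fn(big)
  rowMeans(matrix(preds, nrow = nrow(Z), byrow = TRUE))
}

new_shap_explanation <- function(base_value, phi, model_output) {
  structure(list(base_value = base_value, attributions = phi,
                 model_output = model_output), class = "shap_explanation")
}

#' Kernel-SHAP explanation of one instance
#'
#' Solves the kernel-weighted least-squares problem over coalitions of
#' present/absent features, with the efficiency (local-accuracy) constraint
#' `base + sum(phi) = f(x)` enforced exactly by eliminating one unknown.
#' Absent features are replaced by background rows (marginal masking). When
#' `n_coalitions` covers all `2^M - 2` interior coalitions the problem is
#' solved in full-enumeration mode and the result equals the exact Shapley
#' values.
#'
#' @param model_fn Function(matrix) -> probability vector (the model
#'   explained as a single black box, e.g.
#'   `function(X) predict_proba(ensemble, X)`).
#' @param x Named numeric instance (feature vector).
#' @param background Background feature matrix (frozen snapshot; masking
#'   reference).
#' @param n_coalitions Number of interior coalitions to use; `NULL` (default)
#'   enumerates all when `M <= 13`, otherwise samples `min(2^M - 2, 2048)`.
#' @param seed Sampling seed.
#' @return A `shap_explanation`: `base_value` (`E[f(x)]` over the
#'   background), per-feature `attributions`, `model_output`.
#' @export
explain <- function(model_fn, x, background, n_coalitions = NULL, seed = 1L) {
  x <- unlist(x)
  M <- length(x)
  background <- as.matrix(background)
  if (!nrow(background)) stopf("background set must be non-empty")
  if (ncol(background) != M) stopf("background has %d columns, instance has %d", ncol(background), M)
  full <- 2^M - 2
  if (is.null(n_coalitions)) n_coalitions <- if (M <= 13) full else min(full, 2048)
  if (n_coalitions < M + 2 && n_coalitions < full) {
    stopf("n_coalitions must be at least M + 2 = %d", M + 2)
  }
  enumerate <- n_coalitions >= full && M <= 20
  if (enumerate) {
    Z <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), M)))[, M:1, drop = FALSE]
    sz <- rowSums(Z)
    Z <- Z[sz > 0 & sz < M, , drop = FALSE]
  } else {
    Z <- with_seed(seed, {
      sizes <- 1:(M - 1)
      pr <- (M - 1) / (sizes * (M - sizes))
      draw <- sample(sizes, n_coalitions * 2L, replace = TRUE, prob = pr / sum(pr))
      rows <- lapply(draw, function(s) {
        z <- logical(M); z[sample.int(M, s)] <- TRUE; z
      })
      Zm <- unique(do.call(rbind, rows))
      Zm[seq_len(min(nrow(Zm), n_coalitions)), , drop = FALSE]
    })
  }
  dimnames(Z) <- NULL
  w <- kernel_weight(M, rowSums(Z))
  base <- mean(model_fn(background))
  fx <- mean(model_fn(matrix(x, 1, dimnames = list(NULL, names(x)))))
  v <- coalition_values(model_fn, x, background, Z)
  delta <- fx - base
  # eliminate phi_M through the efficiency constraint
  Zn <- Z * 1
  A <- Zn[, -M, drop = FALSE] - Zn[, M]
  b <- (v - base) - Zn[, M] * delta
  WA <- A * w
  phi_rest <- tryCatch(
    solve(crossprod(A, WA) + diag(1e-10, M - 1), crossprod(WA, b)),
    error = function(e) stopf("kernel SHAP system is singular: %s", conditionMessage(e)))
  phi <- c(phi_rest, delta - sum(phi_rest))
  names(phi) <- names(x) %||% paste0("f", seq_len(M))
  new_shap_explanation(base, drop(phi), fx)
}

#' Exact Shapley values by subset enumeration
#'
#' Brute-force oracle for [explain()]:
#' `phi_i = sum_S |S|! (M-|S|-1)! / M! * (v(S + i) - v(S))` with the same
#' marginal-masking value function. Refuses `M > 12`.
#'
#' @inheritParams explain
#' @return A `shap_explanation` with exact attributions (local accuracy
#'   holds to machine precision).
#' @export
exact_shapley <- function(model_fn, x, background) {
  x <- unlist(x)
  M <- length(x)
  if (M > 12) stopf("exact_shapley enumerates 2^M subsets; use explain() for M > 12")
  background <- as.matrix(background)
  if (!nrow(background)) stopf("background set must be non-empty")
  n_sub <- 2^M
  Z <- matrix(FALSE, n_sub, M)
  for (j in seq_len(M)) Z[, j] <- bitwAnd(seq_len(n_sub) - 1L, bitwShiftL(1L, j - 1L)) > 0
  vals <- coalition_values(model_fn, x, background, Z)
  # replace the full-coalition value with the actual model output so that
  # efficiency is exact even for a 1-row "coalitionized" evaluation
  vals[n_sub] <- mean(model_fn(matrix(x, 1, dimnames = list(NULL, names(x)))))
  sizes <- rowSums(Z)
  wgt <- ifelse(sizes < M,
                factorial(sizes) * factorial(pmax(M - sizes - 1, 0)) / factorial(M),
                0)
  phi <- numeric(M)
  for (i in seq_len(M)) {
    without <- which(!Z[, i])
    with_i <- without + bitwShiftL(1L, i - 1L)
    phi[i] <- sum(wgt[without] * (vals[with_i] - vals[without]))
  }
  names(phi) <- names(x) %||% paste0("f", seq_len(M))
  new_shap_explanation(vals[1], phi, vals[n_sub])
}

#' Rank features by mean absolute attribution
#'
#' @param explanations List of `shap_explanation` objects sharing a feature
#'   order.
#' @return data.frame `feature`, `mean_abs_phi`, descending.
#' @export
global_importance <- function(explanations) {
  if (!length(explanations)) stopf("need at least one explanation")
  nm <- names(explanations[[1]]$attributions)
  for (e in explanations) {
    if (!identical(names(e$attributions), nm)) {
      stopf("explanations have inconsistent feature sets")
    }
  }
  phi <- do.call(rbind, lapply(explanations, function(e) abs(e$attributions)))
  imp <- colMeans(phi)
  out <- data.frame(feature = nm, mean_abs_phi = unname(imp),
                    stringsAsFactors = FALSE)
  out[order(-out$mean_abs_phi), , drop = FALSE]
}

#' Draw a frozen background snapshot from training entries
#'
#' @param entries Entries data.frame.
#' @param n Snapshot size (default 100).
#' @param seed Sampling seed.
#' @return Matrix of feature rows with a `snapshot_id` attribute (an md5 of
#'   the contents); explaining against the same snapshot twice yields
#'   identical output.
#' @export
background_snapshot <- function(entries, n = 100L, seed = 1L) {
  X <- as.matrix(entries[, feature_names(), drop = FALSE])
  idx <- with_seed(seed, sample.int(nrow(X), min(n, nrow(X))))
  bg <- X[sort(idx), , drop = FALSE]
  tf <- tempfile()
  on.exit(unlink(tf))
  writeBin(serialize(bg, NULL), tf)
  attr(bg, "snapshot_id") <- unname(tools::md5sum(tf))
  bg
}
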