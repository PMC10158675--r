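#' Architecture of the deep-wide neural network (DWNN)
#'
#' Dense blocks (affine -> batch normalization -> ReLU) are stacked
#' sequentially; the outputs of *all* blocks (optionally together with the
#' raw input) are concatenated and fed to a single sigmoid output unit, so
#' the loss gradient reaches every block directly regardless of depth. Batch
#' normalization stabilizes training of the deeper blocks.
#'
#' @param block_widths Hidden widths per block (default `c(64, 64, 64)`).
#' @param batch_norm Apply batch normalization in every block (default TRUE).
#' @param concat_inputs Include the raw input in the concatenation
#'   (default TRUE).
#' @param epochs,batch_size,learning_rate Training schedule
#'   (defaults 40 / 64 / 1e-3, Adam).
#' @param patience Early-stopping patience on an internal validation split
#'   (default 5 epochs).
#' @param seed Integer seed for initialization and batching.
#' @return A `dwnn_arch` list.
#' @export
dwnn_arch <- function(block_widths = c(64, 64, 64), batch_norm = TRUE,
                      concat_inputs = TRUE, epochs = 40L, batch_size = 64L,
                      learning_rate = 1e-3, patience = 5L, seed = 1L) {
  if (!length(block_widths)) stopf("DWNN needs at least one block")
  structure(list(block_widths = as.integer(block_widths),
                 batch_norm = isTRUE(batch_norm),
                 concat_inputs = isTRUE(concat_inputs),
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, patience = as.integer(patience),
                 seed = as.integer(seed)),
            class = "dwnn_arch")
}

#' Build an (untrained but forward-ready) DWNN
#'
#' @param input_dim Number of input features (>= 1).
#' @param arch A [dwnn_arch()].
#' @return A `dwnn` handle; [predict_proba()] works immediately (sigmoid
#'   output, so probabilities lie in (0,1) even before training) and
#'   [train_dwnn()] fits it.
#' @export
build_dwnn <- function(input_dim, arch = dwnn_arch()) {
  if (input_dim < 1) stopf("input_dim must be >= 1")
  widths <- arch$block_widths
  with_seed(arch$seed, {
    params <- list(blocks = vector("list", length(widths)))
    d_in <- input_dim
    for (b in seq_along(widths)) {
      d_out <- widths[b]
      params$blocks[[b]] <- list(
        W = matrix(rnorm(d_in * d_out, 0, sqrt(2 / d_in)), d_in, d_out),
        b = rep(0, d_out),
        gamma = rep(1, d_out), beta = rep(0, d_out),
        run_mean = rep(0, d_out), run_var = rep(1, d_out))
      d_in <- d_out
    }
    concat_dim <- sum(widths) + if (arch$concat_inputs) input_dim else 0L
    params$u <- matrix(rnorm(concat_dim, 0, sqrt(1 / concat_dim)), concat_dim, 1)
    params$c <- 0
  })
  structure(list(arch = arch, input_dim = input_dim, params = params,
                 trained = FALSE, x_center = rep(0, input_dim),
                 x_scale = rep(1, input_dim)),
            class = c("dwnn", "modsew_learner"))
}

dwnn_forward <- function(net, X, training = FALSE) {
  arch <- net$arch
  p <- net$params
  eps <- 1e-5
  A <- sweep(sweep(X, 2, net$x_center), 2, net$x_scale, "/")
  x_in <- A
  cache <- list(x = x_in, blocks = vector("list", length(p$blocks)))
  acts <- vector("list", length(p$blocks))
  for (b in seq_along(p$blocks)) {
    bl <- p$blocks[[b]]
    Z <- sweep(A %*% bl$W, 2, bl$b, "+")
    if (arch$batch_norm) {
      if (training) {
        m <- colMeans(Z)
        v <- colMeans(sweep(Z, 2, m)^2)
      } else {
        m <- bl$run_mean
        v <- bl$run_var
      }
      Zc <- sweep(Z, 2, m)
      inv_sd <- 1 / sqrt(v + eps)
      Zh <- sweep(Zc, 2, inv_sd, "*")
      Zn <- sweep(sweep(Zh, 2, bl$gamma, "*"), 2, bl$beta, "+")
    } else {
      m <- v <- NULL; Zh <- Z; Zn <- Z
    }
    Aout <- pmax(Zn, 0)
    cache$blocks[[b]] <- list(A_in = A, Z = Z, Zh = Zh, Zn = Zn,
                              mean = m, var = v)
    acts[[b]] <- Aout
    A <- Aout
  }
  H <- do.call(cbind, if (arch$concat_inputs) c(acts, list(x_in)) else acts)
  s <- drop(H %*% p$u) + p$c
  cache$H <- H
  cache$acts <- acts
  list(prob = plogis(s), cache = cache)
}

# one minibatch gradient step (Adam); returns updated net + adam state
dwnn_backward <- function(net, fw, y, w) {
  arch <- net$arch
  p <- net$params
  eps <- 1e-5
  n <- length(y)
  widths <- arch$block_widths
  sw <- sum(w)
  ds <- w * (fw$prob - y) / sw               # dL/dlogit, weighted BCE
  grads <- list(blocks = vector("list", length(p$blocks)))
  grads$u <- crossprod(fw$cache$H, ds)
  grads$c <- sum(ds)
  dH <- outer(ds, drop(p$u))                 # n x concat_dim
  offs <- c(0, cumsum(widths))
  dA_next <- NULL                            # gradient flowing down the chain
  for (b in rev(seq_along(p$blocks))) {
    bl <- p$blocks[[b]]
    cb <- fw$cache$blocks[[b]]
    dA <- dH[, (offs[b] + 1):offs[b + 1], drop = FALSE]
    if (!is.null(dA_next)) dA <- dA + dA_next
    dZn <- dA * (cb$Zn > 0)
    if (arch$batch_norm) {
      inv_sd <- 1 / sqrt(cb$var + eps)
      dgamma <- colSums(dZn * cb$Zh)
      dbeta <- colSums(dZn)
      dZh <- sweep(dZn, 2, bl$gamma, "*")
      m_dZh <- colMeans(dZh)
      m_dZhZh <- colMeans(dZh * cb$Zh)
      dZ <- sweep(dZh, 2, m_dZh) - sweep(cb$Zh, 2, m_dZhZh, "*")
      dZ <- sweep(dZ, 2, inv_sd, "*")
    } else {
      dgamma <- dbeta <- NULL
      dZ <- dZn
    }
    grads$blocks[[b]] <- list(W = crossprod(cb$A_in, dZ), b = colSums(dZ),
                              gamma = dgamma, beta = dbeta)
    dA_next <- tcrossprod(dZ, bl$W)
  }
  grads
}

adam_init <- function(params) rapply(params, function(x) x * 0, how = "replace")

adam_step <- function(params, grads, m, v, t, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  upd <- function(p, g, m1, v1) {
    m1 <- b1 * m1 + (1 - b1) * g
    v1 <- b2 * v1 + (1 - b2) * g^2
    mh <- m1 / (1 - b1^t)
    vh <- v1 / (1 - b2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m1, v = v1)
  }
  for (b in seq_along(params$blocks)) {
    for (nm in c("W", "b", "gamma", "beta")) {
      g <- grads$blocks[[b]][[nm]]
      if (is.null(g)) next
      r <- upd(params$blocks[[b]][[nm]], g, m$blocks[[b]][[nm]], v$blocks[[b]][[nm]])
      params$blocks[[b]][[nm]] <- r$p
      m$blocks[[b]][[nm]] <- r$m
      v$blocks[[b]][[nm]] <- r$v
    }
  }
  r <- upd(params$u, grads$u, m$u, v$u)
  params$u <- r$p; m$u <- r$m; v$u <- r$v
  r <- upd(params$c, grads$c, m$c, v$c)
  params$c <- r$p; m$c <- r$m; v$c <- r$v
  list(params = params, m = m, v = v)
}

dwnn_loss <- function(prob, y, w) {
  prob <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
  -sum(w * (y * log(prob) + (1 - y) * log(1 - prob))) / sum(w)
}

#' Train a DWNN with class-weighted binary cross-entropy
#'
#' @param net A `dwnn` from [build_dwnn()].
#' @param X Feature matrix.
#' @param y 0/1 labels.
#' @param weights Per-sample weights (e.g. from [class_weights()]).
#' @return The trained `dwnn`.
#' @export
train_dwnn <- function(net, X, y, weights = NULL) {
  arch <- net$arch
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  w <- if (is.null(weights)) rep(1, n) else weights
  net$x_center <- colMeans(X)
  net$x_scale <- pmax(apply(X, 2, sd), 1e-8)
  with_seed(child_seed(arch$seed, 2L), {
    n_val <- max(1L, floor(0.1 * n))
    val_idx <- sample.int(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)
    m <- adam_init(net$params)
    v <- adam_init(net$params)
    best <- list(loss = Inf, params = net$params, blocks_run = NULL)
    stall <- 0L
    t <- 0L
    momentum <- 0.9
    for (epoch in seq_len(arch$epochs)) {
      ord <- sample(tr_idx)
      starts <- seq(1, length(ord), by = arch$batch_size)
      for (s in starts) {
        rows <- ord[s:min(s + arch$batch_size - 1L, length(ord))]
        if (length(rows) < 2L) next
        fw <- dwnn_forward(net, X[rows, , drop = FALSE], training = TRUE)
        grads <- dwnn_backward(net, fw, y[rows], w[rows])
        t <- t + 1L
        st <- adam_step(net$params, grads, m, v, t, arch$learning_rate)
        net$params <- st$params; m <- st$m; v <- st$v
        if (arch$batch_norm) {
          for (b in seq_along(net$params$blocks)) {
            cb <- fw$cache$blocks[[b]]
            net$params$blocks[[b]]$run_mean <-
              momentum * net$params$blocks[[b]]$run_mean + (1 - momentum) * cb$mean
            net$params$blocks[[b]]$run_var <-
              momentum * net$params$blocks[[b]]$run_var + (1 - momentum) * cb$var
          }
        }
      }
      val_prob <- dwnn_forward(net, X[val_idx, , drop = FALSE])$prob
      vl <- dwnn_loss(val_prob, y[val_idx], w[val_idx])
      if (vl < best$loss - 1e-6) {
        best <- list(loss = vl, params = net$params)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= arch$patience) break
      }
    }
    net$params <- best$params
  })
  net$trained <- TRUE
  net
}
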