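# Minimal neural-network machinery for the desk-scale base learners.
#
# Everything is expressed as dense BLAS matrix products: the convolution uses
# an im2col expansion precomputed once per input shape, and 2x2 average
# pooling is a fixed sparse-pattern matrix applied by crossprod.  Training is
# plain minibatch gradient descent (optional classical momentum) on the
# categorical cross-entropy of the softmax output.

#' Softmax over rows
#'
#' Numerically stable softmax: each row of `z` is shifted by its maximum
#' before exponentiation, so rows sum to 1 within 1e-6 for any finite logits.
#'
#' @param z Numeric matrix of logits (rows = samples) or a single vector.
#' @return Matrix (or vector) of probabilities with unit row sums.
#' @export
softmax <- function(z) {
  vec <- is.null(dim(z))
  if (vec) z <- matrix(z, 1)
  z <- z - apply(z, 1, max)
  e <- exp(z)
  p <- e / rowSums(e)
  if (vec) p[1, ] else p
}

relu <- function(x) pmax(x, 0)

# Geometry of the tiny CNN for a given input shape and dense width.
cnn_arch <- function(H, W, C = 3L, filters = 8L, kernel = 3L, dense = 64L, K) {
  Hc <- H - kernel + 1L; Wc <- W - kernel + 1L
  if (Hc < 2L || Wc < 2L) stop_fmt("input %dx%d too small for a %dx%d kernel",
                                   H, W, kernel, kernel)
  Hp <- Hc %/% 2L; Wp <- Wc %/% 2L
  list(H = H, W = W, C = C, F = filters, kernel = kernel, dense = dense, K = K,
       Hc = Hc, Wc = Wc, Hp = Hp, Wp = Wp,
       P = Hc * Wc, Pp = Hp * Wp, patch = kernel * kernel * C)
}

# im2col index matrix (P x patch): linear indices into an H x W x C array for
# every kernel position.  Output positions are ordered column-major over the
# conv grid (row index fastest), matching cnn_pool_matrix.
cnn_im2col_index <- function(arch) {
  with(arch, {
    pos <- expand.grid(i = seq_len(Hc), j = seq_len(Wc))
    off <- expand.grid(di = 0:(kernel - 1), dj = 0:(kernel - 1), c = seq_len(C))
    idx <- matrix(0L, P, patch)
    for (q in seq_len(patch)) {
      idx[, q] <- (pos$i + off$di[q]) +
        (pos$j + off$dj[q] - 1L) * H +
        (off$c[q] - 1L) * H * W
    }
    idx
  })
}

# P x Pp matrix with 0.25 entries implementing 2x2/stride-2 average pooling
# over the conv grid (odd trailing rows/columns are dropped).
cnn_pool_matrix <- function(arch) {
  with(arch, {
    M <- matrix(0, P, Pp)
    for (b in seq_len(Wp)) for (a in seq_len(Hp)) {
      cell <- a + (b - 1L) * Hp
      for (dj in 0:1) for (di in 0:1) {
        p <- (2L * a - 1L + di) + (2L * b - 2L + dj) * Hc
        M[p, cell] <- 0.25
      }
    }
    M
  })
}

# Expand images (rows of Xflat, one flattened H x W x C image per row) into
# the im2col matrix for the tiny CNN: (length(idx) * P) x patch, position
# index fastest within each image.  Intensities are shifted to [-0.5, 0.5]:
# zero-centered inputs keep optimization stable regardless of whether the
# image background is dark or light.
cnn_expand <- function(Xflat, rows, idxm, arch) {
  B <- length(rows)
  A <- Xflat[rows, as.vector(idxm), drop = FALSE]
  dim(A) <- c(B, arch$P, arch$patch)
  A <- aperm(A, c(2L, 1L, 3L))
  dim(A) <- c(arch$P * B, arch$patch)
  A - 0.5
}

he_init <- function(nrow, ncol) {
  matrix(stats::rnorm(nrow * ncol, 0, sqrt(2 / nrow)), nrow, ncol)
}

cnn_init_params <- function(arch, seed) {
  with_seed(seed, list(
    W1 = he_init(arch$patch, arch$F),        b1 = numeric(arch$F),
    W2 = he_init(arch$Pp * arch$F, arch$dense), b2 = numeric(arch$dense),
    W3 = he_init(arch$dense, arch$K),        b3 = numeric(arch$K)))
}

# Forward pass for image rows `rows`; returns probabilities and, when
# `keep = TRUE`, the intermediates needed by the backward pass.
cnn_forward <- function(params, cache, rows, keep = FALSE) {
  arch <- cache$arch
  B <- length(rows)
  Xc <- cnn_expand(cache$Xflat, rows, cache$idxm, arch)
  Z1 <- sweep(Xc %*% params$W1, 2L, params$b1, "+")
  A1 <- relu(Z1)
  Am <- A1; dim(Am) <- c(arch$P, B * arch$F)
  pooled <- crossprod(cache$Mpool, Am)            # Pp x (B*F)
  dim(pooled) <- c(arch$Pp, B, arch$F)
  Fl <- aperm(pooled, c(2L, 1L, 3L))
  dim(Fl) <- c(B, arch$Pp * arch$F)
  Z2 <- sweep(Fl %*% params$W2, 2L, params$b2, "+")
  A2 <- relu(Z2)
  Z3 <- sweep(A2 %*% params$W3, 2L, params$b3, "+")
  probs <- softmax(Z3)
  if (!keep) return(list(probs = probs))
  list(probs = probs, Xc = Xc, Z1 = Z1, Fl = Fl, Z2 = Z2, A2 = A2, B = B)
}

# Gradients of mean cross-entropy for one minibatch.
cnn_backward <- function(params, cache, fwd, Y) {
  arch <- cache$arch
  B <- fwd$B
  dZ3 <- (fwd$probs - Y) / B
  g <- list(W3 = crossprod(fwd$A2, dZ3), b3 = colSums(dZ3))
  dA2 <- tcrossprod(dZ3, params$W3)
  dZ2 <- dA2 * (fwd$Z2 > 0)
  g$W2 <- crossprod(fwd$Fl, dZ2); g$b2 <- colSums(dZ2)
  dFl <- tcrossprod(dZ2, params$W2)               # B x (Pp*F)
  dim(dFl) <- c(B, arch$Pp, arch$F)
  dFl <- aperm(dFl, c(2L, 1L, 3L))
  dim(dFl) <- c(arch$Pp, B * arch$F)
  dA1 <- cache$Mpool %*% dFl                      # P x (B*F)
  dim(dA1) <- c(arch$P * B, arch$F)
  dZ1 <- dA1 * (fwd$Z1 > 0)
  g$W1 <- crossprod(fwd$Xc, dZ1); g$b1 <- colSums(dZ1)
  g
}

mean_cross_entropy <- function(probs, y) {
  p <- probs[cbind(seq_along(y), y)]
  -mean(log(pmax(p, 1e-12)))
}

# Shared SGD loop.  `model` supplies forward(params, rows, keep) and
# backward(params, fwd, Y); epochs = 0 returns the initialization unchanged.
sgd_train <- function(params, model, labels, K, config) {
  n <- length(labels)
  Y <- one_hot_matrix(labels, K)
  vel <- lapply(params, function(p) p * 0)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        accuracy = numeric(0))
  lr <- config$learning_rate; mom <- config$momentum
  for (epoch in seq_len(config$epochs)) {
    perm <- with_seed(derive_seed(config$seed, epoch), sample.int(n))
    loss_sum <- 0; correct <- 0
    for (b0 in seq(1L, n, by = config$batch_size)) {
      rows <- perm[b0:min(n, b0 + config$batch_size - 1L)]
      fwd <- model$forward(params, rows, keep = TRUE)
      yb <- labels[rows]
      loss <- mean_cross_entropy(fwd$probs, yb)
      if (!is.finite(loss))
        stop_fmt("non-finite loss at epoch %d (lr %.4g too large?)", epoch, lr)
      loss_sum <- loss_sum + loss * length(rows)
      correct <- correct + sum(max.col(fwd$probs, "first") == yb)
      g <- model$backward(params, fwd, Y[rows, , drop = FALSE])
      for (nm in names(params)) {
        vel[[nm]] <- mom * vel[[nm]] - lr * g[[nm]]
        params[[nm]] <- params[[nm]] + vel[[nm]]
      }
    }
    history <- rbind(history, data.frame(epoch = epoch, loss = loss_sum / n,
                                         accuracy = correct / n))
  }
  list(params = params, history = history)
}

# ---- fully connected head (finetune family) --------------------------------

mlp_init_params <- function(widths, seed) {
  with_seed(seed, {
    p <- list()
    for (l in seq_len(length(widths) - 1L)) {
      p[[paste0("W", l)]] <- he_init(widths[l], widths[l + 1L])
      p[[paste0("b", l)]] <- numeric(widths[l + 1L])
    }
    p
  })
}

mlp_forward <- function(params, X, keep = FALSE) {
  n_layers <- length(params) / 2L
  acts <- list(X)
  zs <- list()
  a <- X
  for (l in seq_len(n_layers)) {
    z <- sweep(a %*% params[[paste0("W", l)]], 2L, params[[paste0("b", l)]], "+")
    zs[[l]] <- z
    a <- if (l < n_layers) relu(z) else z
    acts[[l + 1L]] <- a
  }
  probs <- softmax(a)
  if (!keep) return(list(probs = probs))
  list(probs = probs, acts = acts, zs = zs, B = nrow(X))
}

mlp_backward <- function(params, fwd, Y) {
  n_layers <- length(params) / 2L
  g <- list()
  delta <- (fwd$probs - Y) / fwd$B
  for (l in rev(seq_len(n_layers))) {
    g[[paste0("W", l)]] <- crossprod(fwd$acts[[l]], delta)
    g[[paste0("b", l)]] <- colSums(delta)
    if (l > 1L) delta <- tcrossprod(delta, params[[paste0("W", l)]]) *
        (fwd$zs[[l - 1L]] > 0)
  }
  g
}

# Built-in stand-in feature extractor: block-average each channel to an
# 8x8 grid, centered to [-0.5, 0.5], and flatten (192 features).  Real
# pretrained backbones plug in as any function(images_array) -> features.
avgpool_features <- function(images, grid = 8L) {
  images <- images - 0.5
  d <- dim(images)
  N <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  hb <- pmin(floor((seq_len(H) - 1L) / H * grid) + 1L, grid)
  wb <- pmin(floor((seq_len(W) - 1L) / W * grid) + 1L, grid)
  out <- matrix(0, N, grid * grid * C)
  for (ch in seq_len(C)) {
    M <- matrix(images[, , , ch], N, H * W)
    cell <- as.vector(outer(hb, wb, function(a, b) a + (b - 1L) * grid))
    # column-group means via multiplication with a 0/1 membership matrix
    G <- matrix(0, H * W, grid * grid)
    G[cbind(seq_len(H * W), cell)] <- 1
    G <- sweep(G, 2L, pmax(colSums(G), 1), "/")
    out[, ((ch - 1L) * grid * grid + 1L):(ch * grid * grid)] <- M %*% G
  }
  out
}
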