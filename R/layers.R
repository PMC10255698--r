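# Neural-network layer primitives.
#
# All batched activations are 3-d arrays dim (N, T, C): sample, timestep,
# channel. Convolutions are realized as im2col + one BLAS matrix multiply;
# every layer has a hand-derived backward pass so the whole network trains
# without any external deep-learning framework.

# ---- convolution -----------------------------------------------------------

# "same" padding 1-d convolution. W: (k*C_in) x C_out, b: length C_out.
conv1d_forward <- function(x, W, b, k) {
  d <- dim(x); N <- d[1]; T_ <- d[2]; C <- d[3]
  pl <- (k - 1L) %/% 2L
  xp <- array(0, dim = c(N, T_ + k - 1L, C))
  xp[, (pl + 1L):(pl + T_), ] <- x
  xcol <- matrix(0, N * T_, k * C)
  for (j in seq_len(k)) {
    xcol[, ((j - 1L) * C + 1L):(j * C)] <-
      matrix(xp[, j:(j + T_ - 1L), , drop = FALSE], N * T_, C)
  }
  out <- xcol %*% W
  out <- out + rep(b, each = N * T_)
  dim(out) <- c(N, T_, ncol(W))
  list(out = out, xcol = xcol, dims = d)
}

conv1d_backward <- function(dout, cache, W, k) {
  d <- cache$dims; N <- d[1]; T_ <- d[2]; C <- d[3]
  dym <- matrix(dout, N * T_, dim(dout)[3])
  dW <- crossprod(cache$xcol, dym)
  db <- colSums(dym)
  dxcol <- tcrossprod(dym, W)
  pl <- (k - 1L) %/% 2L
  dxp <- array(0, dim = c(N, T_ + k - 1L, C))
  for (j in seq_len(k)) {
    dxp[, j:(j + T_ - 1L), ] <- dxp[, j:(j + T_ - 1L), , drop = FALSE] +
      array(dxcol[, ((j - 1L) * C + 1L):(j * C)], c(N, T_, C))
  }
  list(dx = dxp[, (pl + 1L):(pl + T_), , drop = FALSE], dW = dW, db = db)
}

# ---- activations -----------------------------------------------------------

relu_forward <- function(x) {
  y <- x
  y[y < 0] <- 0
  y
}

relu_backward <- function(dy, x) {
  dy[x <= 0] <- 0
  dy
}

# ---- batch normalization ---------------------------------------------------

# Operates on a 2-d matrix (observations x features); conv activations are
# reshaped to (N*T, C) so normalization is per channel. Batch statistics use
# the population variance; running statistics serve inference.
bn_forward <- function(x, gamma, beta, running_mean, running_var,
                       training, eps = 1e-5, momentum = 0.1) {
  n <- nrow(x)
  if (training) {
    mu <- colMeans(x)
    xc <- x - rep(mu, each = n)
    v <- colMeans(xc * xc)
    invstd <- 1 / sqrt(v + eps)
    xhat <- xc * rep(invstd, each = n)
    running_mean <- (1 - momentum) * running_mean + momentum * mu
    running_var <- (1 - momentum) * running_var + momentum * v
  } else {
    invstd <- 1 / sqrt(running_var + eps)
    xhat <- (x - rep(running_mean, each = n)) * rep(invstd, each = n)
  }
  y <- xhat * rep(gamma, each = n) + rep(beta, each = n)
  list(out = y, xhat = xhat, invstd = invstd,
       running_mean = running_mean, running_var = running_var)
}

bn_backward <- function(dy, cache, gamma) {
  n <- nrow(dy)
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- dy * rep(gamma, each = n)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * xhat)
  dx <- (dxhat - rep(s1 / n, each = n) - xhat * rep(s2 / n, each = n)) *
    rep(cache$invstd, each = n)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- max pooling -----------------------------------------------------------

# Non-overlapping windows of size s along time; a trailing remainder shorter
# than s is dropped. Ties go to the earliest position.
maxpool_forward <- function(x, s) {
  d <- dim(x); N <- d[1]; T_ <- d[2]; C <- d[3]
  T_out <- T_ %/% s
  xt <- x[, seq_len(T_out * s), , drop = FALSE]
  dim(xt) <- c(N, s, T_out, C)
  m <- array(xt[, 1L, , ], c(N, T_out, C))
  idx <- array(1L, dim = c(N, T_out, C))
  if (s > 1L) {
    for (p in 2L:s) {
      cand <- array(xt[, p, , ], c(N, T_out, C))
      upd <- cand > m
      m[upd] <- cand[upd]
      idx[upd] <- p
    }
  }
  list(out = m, idx = idx, dims = d, T_out = T_out)
}

maxpool_backward <- function(dout, cache, s) {
  d <- cache$dims; N <- d[1]; T_ <- d[2]; C <- d[3]
  T_out <- cache$T_out
  nmat <- slice.index(cache$idx, 1L)
  tomat <- slice.index(cache$idx, 2L)
  cmat <- slice.index(cache$idx, 3L)
  t_orig <- (tomat - 1L) * s + cache$idx
  lin <- nmat + (t_orig - 1L) * N + (cmat - 1L) * N * T_
  dx <- numeric(N * T_ * C)
  dx[lin] <- dout
  dim(dx) <- c(N, T_, C)
  dx
}

# ---- attention -------------------------------------------------------------

# Batched attention over timesteps: scores q_t = tanh(x_t . W + b), weights
# a = softmax_t(q), attended_t = a_t * x_t (broadcast over channels).
att_forward <- function(x, W, b) {
  d <- dim(x); N <- d[1]; T_ <- d[2]; C <- d[3]
  xm <- matrix(x, N * T_, C)
  q <- tanh(xm %*% W + b)          # (N*T) x 1
  dim(q) <- c(N, T_)
  qs <- q - apply(q, 1L, max)
  e <- exp(qs)
  a <- e / rowSums(e)              # (N, T), rows sum to 1
  attended <- x * as.numeric(a)    # recycles over the channel dimension
  list(out = attended, a = a, q = q, x = x, xm = xm)
}

att_backward <- function(dout, cache, W) {
  d <- dim(cache$x); N <- d[1]; T_ <- d[2]; C <- d[3]
  a <- cache$a; q <- cache$q
  # d(loss)/d(a_nt) = sum_c dout * x
  da <- rowSums(matrix(dout * cache$x, N * T_, C))
  dim(da) <- c(N, T_)
  dx <- dout * as.numeric(a)
  dq <- a * (da - rowSums(a * da))             # softmax backward per row
  dpre <- as.numeric(dq * (1 - q^2))           # tanh backward, (N*T)
  dW <- crossprod(cache$xm, dpre)
  db <- sum(dpre)
  dx <- dx + array(dpre %*% t(W), c(N, T_, C))
  list(dx = dx, dW = dW, db = db)
}

#' Attention layer forward computation
#'
#' The attention score for timestep t is `q_t = tanh(x_t . W + b)`; a
#' softmax over timesteps turns the scores into weights `a` (non-negative,
#' summing to 1), and the attended signal is the elementwise product
#' `attended_t = a_t * x_t`, so the layer rescales informative timesteps
#' without changing the time-by-channel shape.
#'
#' @param x Numeric matrix, timesteps x channels.
#' @param W Numeric weight vector, one entry per channel.
#' @param b Scalar bias.
#' @return List with `a` (attention weights over timesteps) and `attended`
#'   (weighted matrix, same shape as `x`).
#' @examples
#' attention_forward(matrix(c(1, -1), ncol = 1), W = 1, b = 0)
#' @export
attention_forward <- function(x, W, b = 0) {
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L)
  W <- as.numeric(W)
  if (length(W) != ncol(x)) {
    abort_invalid(sprintf(
      "length(W) = %d does not match the channel dimension of x (%d)",
      length(W), ncol(x)))
  }
  check_scalar_number(b, "b")
  xa <- array(x, c(1L, nrow(x), ncol(x)))
  f <- att_forward(xa, matrix(W, ncol = 1L), b)
  list(a = as.numeric(f$a),
       attended = matrix(f$out, nrow(x), ncol(x)))
}

# ---- dense / dropout / softmax --------------------------------------------

dense_forward <- function(x, W, b) {
  y <- x %*% W
  y + rep(b, each = nrow(x))
}

dense_backward <- function(dy, x, W) {
  list(dx = tcrossprod(dy, W), dW = crossprod(x, dy), db = colSums(dy))
}

# Inverted dropout: each unit kept with probability 1-p and scaled by
# 1/(1-p) during training so inference is the identity.
dropout_forward <- function(x, p, training) {
  if (!training || p <= 0) return(list(out = x, mask = NULL))
  mask <- array(runif(length(x)) >= p, dim = dim(x) %||% length(x))
  list(out = x * mask / (1 - p), mask = mask)
}

dropout_backward <- function(dy, cache, p) {
  if (is.null(cache$mask)) return(dy)
  dy * cache$mask / (1 - p)
}

softmax_rows <- function(z) {
  zs <- z - apply(z, 1L, max)
  e <- exp(zs)
  e / rowSums(e)
}
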