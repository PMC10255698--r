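# Attention-augmented 1D CNN: configuration, construction, forward/backward.
#
# Architecture (fixed topology, sizes configurable):
#   conv(64,k5,ReLU) -> BN -> maxpool(2)
#   conv(128,k5,ReLU) -> BN -> maxpool(2)
#   conv(256,k5,ReLU) -> BN -> maxpool(2)
#   attention -> flatten
#   dense(512,ReLU) -> BN -> dropout(p)
#   dense(256,ReLU) -> BN -> dropout(p)
#   dense(K) -> softmax

#' Model and training configuration
#'
#' Defaults are the selected hyperparameters of the reference architecture:
#' three convolutional blocks with 64/128/256 filters of kernel size 5,
#' pool size 2, dense widths 512/256, dropout 0.5, Adam learning rate
#' 0.001, batch size 512, 25 epochs, 5 output classes, input length 186.
#'
#' @param input_length Beat length L fed to the network.
#' @param conv_filters Integer triple of filters per conv block.
#' @param kernel_size Convolution kernel size.
#' @param pool_size Max-pooling window (and stride).
#' @param dense_units Integer pair of hidden dense widths.
#' @param dropout_p Dropout rate in `[0, 1)`.
#' @param n_classes Number of output classes K (>= 2).
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size.
#' @param epochs Training epochs.
#' @param seed Integer seed for initialization, shuffling and dropout.
#' @return An object of class `model_config`.
#' @export
model_config <- function(input_length = 186L,
                         conv_filters = c(64L, 128L, 256L),
                         kernel_size = 5L,
                         pool_size = 2L,
                         dense_units = c(512L, 256L),
                         dropout_p = 0.5,
                         n_classes = 5L,
                         learning_rate = 0.001,
                         batch_size = 512L,
                         epochs = 25L,
                         seed = 0L) {
  check_count(input_length, "input_length", lower = 1L)
  if (length(conv_filters) != 3L || any(conv_filters < 1))
    abort_invalid("`conv_filters` must be a positive integer triple")
  check_count(kernel_size, "kernel_size", lower = 1L)
  check_count(pool_size, "pool_size", lower = 1L)
  if (length(dense_units) != 2L || any(dense_units < 1))
    abort_invalid("`dense_units` must be a positive integer pair")
  check_scalar_number(dropout_p, "dropout_p", 0, 1)
  if (dropout_p >= 1) abort_invalid("`dropout_p` must be < 1")
  check_count(n_classes, "n_classes", lower = 2L)
  check_scalar_number(learning_rate, "learning_rate")
  check_count(batch_size, "batch_size", lower = 1L)
  check_count(epochs, "epochs", lower = 1L)
  check_scalar_number(seed, "seed")
  structure(
    list(input_length = as.integer(input_length),
         conv_filters = as.integer(conv_filters),
         kernel_size = as.integer(kernel_size),
         pool_size = as.integer(pool_size),
         dense_units = as.integer(dense_units),
         dropout_p = dropout_p,
         n_classes = as.integer(n_classes),
         learning_rate = learning_rate,
         batch_size = as.integer(batch_size),
         epochs = as.integer(epochs),
         seed = as.integer(seed)),
    class = "model_config"
  )
}

# pooled time lengths after each of the three blocks
.pooled_lengths <- function(cfg) {
  s <- cfg$pool_size
  t1 <- cfg$input_length %/% s
  t2 <- t1 %/% s
  t3 <- t2 %/% s
  c(t1, t2, t3)
}

#' Build an attention-augmented 1D CNN
#'
#' Instantiates the fixed layer sequence with He-initialized weights;
#' initialization is a pure function of `cfg$seed`.
#'
#' @param cfg A [model_config()].
#' @return An object of class `ecg_cnn` holding parameters, Adam/batch-norm
#'   state and the configuration.
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  tl <- .pooled_lengths(cfg)
  if (tl[3] < 1L) {
    abort_invalid(sprintf(
      "input_length = %d is too short for three poolings of size %d",
      cfg$input_length, cfg$pool_size))
  }
  k <- cfg$kernel_size
  f <- cfg$conv_filters
  du <- cfg$dense_units
  K <- cfg$n_classes
  flat <- tl[3] * f[3]
  he <- function(nr, nc, fan_in) matrix(rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
  params <- with_local_seed(cfg$seed, list(
    cW1 = he(k * 1L, f[1], k * 1L),      cb1 = numeric(f[1]),
    g1 = rep(1, f[1]),  be1 = numeric(f[1]),
    cW2 = he(k * f[1], f[2], k * f[1]),  cb2 = numeric(f[2]),
    g2 = rep(1, f[2]),  be2 = numeric(f[2]),
    cW3 = he(k * f[2], f[3], k * f[2]),  cb3 = numeric(f[3]),
    g3 = rep(1, f[3]),  be3 = numeric(f[3]),
    aW = matrix(rnorm(f[3], 0, sqrt(1 / f[3])), f[3], 1L), ab = 0,
    dW1 = he(flat, du[1], flat),         db1 = numeric(du[1]),
    g4 = rep(1, du[1]), be4 = numeric(du[1]),
    dW2 = he(du[1], du[2], du[1]),       db2 = numeric(du[2]),
    g5 = rep(1, du[2]), be5 = numeric(du[2]),
    dW3 = he(du[2], K, du[2]),           db3 = numeric(K)
  ))
  running <- list(
    rm1 = numeric(f[1]), rv1 = rep(1, f[1]),
    rm2 = numeric(f[2]), rv2 = rep(1, f[2]),
    rm3 = numeric(f[3]), rv3 = rep(1, f[3]),
    rm4 = numeric(du[1]), rv4 = rep(1, du[1]),
    rm5 = numeric(du[2]), rv5 = rep(1, du[2])
  )
  structure(list(cfg = cfg, params = params, running = running,
                 trained = FALSE, n_updates = 0L),
            class = "ecg_cnn")
}

#' Layer-by-layer model summary
#'
#' @param model An `ecg_cnn`.
#' @return A data.frame with one row per layer: `kind`, `detail`,
#'   `output_shape` (time x channels, or units).
#' @export
model_layers <- function(model) {
  stopifnot(inherits(model, "ecg_cnn"))
  cfg <- model$cfg
  tl <- .pooled_lengths(cfg)
  f <- cfg$conv_filters
  du <- cfg$dense_units
  sh <- function(t, c) sprintf("%d x %d", t, c)
  data.frame(
    kind = c("conv", "batchnorm", "maxpool",
             "conv", "batchnorm", "maxpool",
             "conv", "batchnorm", "maxpool",
             "attention", "flatten",
             "dense", "batchnorm", "dropout",
             "dense", "batchnorm", "dropout",
             "dense", "softmax"),
    detail = c(sprintf("%d filters, kernel %d, relu", f[1], cfg$kernel_size), "", sprintf("size %d", cfg$pool_size),
               sprintf("%d filters, kernel %d, relu", f[2], cfg$kernel_size), "", sprintf("size %d", cfg$pool_size),
               sprintf("%d filters, kernel %d, relu", f[3], cfg$kernel_size), "", sprintf("size %d", cfg$pool_size),
               "softmax over timesteps", "",
               sprintf("%d units, relu", du[1]), "", sprintf("p = %g", cfg$dropout_p),
               sprintf("%d units, relu", du[2]), "", sprintf("p = %g", cfg$dropout_p),
               sprintf("%d units", cfg$n_classes), ""),
    output_shape = c(sh(cfg$input_length, f[1]), sh(cfg$input_length, f[1]), sh(tl[1], f[1]),
                     sh(tl[1], f[2]), sh(tl[1], f[2]), sh(tl[2], f[2]),
                     sh(tl[2], f[3]), sh(tl[2], f[3]), sh(tl[3], f[3]),
                     sh(tl[3], f[3]), sprintf("%d", tl[3] * f[3]),
                     sprintf("%d", du[1]), sprintf("%d", du[1]), sprintf("%d", du[1]),
                     sprintf("%d", du[2]), sprintf("%d", du[2]), sprintf("%d", du[2]),
                     sprintf("%d", cfg$n_classes), sprintf("%d", cfg$n_classes)),
    stringsAsFactors = FALSE
  )
}

#' @export
print.ecg_cnn <- function(x, ...) {
  cat(sprintf("<ecg_cnn> input %d x 1, %s\n", x$cfg$input_length,
              if (x$trained) "trained" else "untrained"))
  print(model_layers(x))
  invisible(x)
}

# Full forward pass. x: (N, L) matrix. Returns probs and, when
# keep_cache = TRUE, every intermediate needed for the backward pass plus
# updated running statistics. Dropout draws come from the current RNG
# stream (callers seed it).
cnn_forward <- function(model, x, training = FALSE, keep_cache = training) {
  p <- model$params; r <- model$running; cfg <- model$cfg
  s <- cfg$pool_size; k <- cfg$kernel_size
  N <- nrow(x)
  a0 <- array(x, c(N, cfg$input_length, 1L))
  cache <- list()

  c1 <- conv1d_forward(a0, p$cW1, p$cb1, k)
  z1 <- relu_forward(c1$out)
  b1 <- bn_forward(matrix(z1, N * dim(z1)[2], dim(z1)[3]), p$g1, p$be1,
                   r$rm1, r$rv1, training)
  r$rm1 <- b1$running_mean; r$rv1 <- b1$running_var
  h1 <- array(b1$out, dim(z1))
  m1 <- maxpool_forward(h1, s)

  c2 <- conv1d_forward(m1$out, p$cW2, p$cb2, k)
  z2 <- relu_forward(c2$out)
  b2 <- bn_forward(matrix(z2, N * dim(z2)[2], dim(z2)[3]), p$g2, p$be2,
                   r$rm2, r$rv2, training)
  r$rm2 <- b2$running_mean; r$rv2 <- b2$running_var
  h2 <- array(b2$out, dim(z2))
  m2 <- maxpool_forward(h2, s)

  c3 <- conv1d_forward(m2$out, p$cW3, p$cb3, k)
  z3 <- relu_forward(c3$out)
  b3 <- bn_forward(matrix(z3, N * dim(z3)[2], dim(z3)[3]), p$g3, p$be3,
                   r$rm3, r$rv3, training)
  r$rm3 <- b3$running_mean; r$rv3 <- b3$running_var
  h3 <- array(b3$out, dim(z3))
  m3 <- maxpool_forward(h3, s)

  at <- att_forward(m3$out, p$aW, p$ab)
  flat <- matrix(at$out, N, prod(dim(at$out)[2:3]))

  f1 <- dense_forward(flat, p$dW1, p$db1)
  rf1 <- relu_forward(f1)
  b4 <- bn_forward(rf1, p$g4, p$be4, r$rm4, r$rv4, training)
  r$rm4 <- b4$running_mean; r$rv4 <- b4$running_var
  dr1 <- dropout_forward(b4$out, cfg$dropout_p, training)

  f2 <- dense_forward(dr1$out, p$dW2, p$db2)
  rf2 <- relu_forward(f2)
  b5 <- bn_forward(rf2, p$g5, p$be5, r$rm5, r$rv5, training)
  r$rm5 <- b5$running_mean; r$rv5 <- b5$running_var
  dr2 <- dropout_forward(b5$out, cfg$dropout_p, training)

  logits <- dense_forward(dr2$out, p$dW3, p$db3)
  probs <- softmax_rows(logits)

  if (keep_cache) {
    cache <- list(a0 = a0, c1 = c1, z1 = z1, b1 = b1, m1 = m1,
                  c2 = c2, z2 = z2, b2 = b2, m2 = m2,
                  c3 = c3, z3 = z3, b3 = b3, m3 = m3,
                  at = at, flat = flat,
                  f1 = f1, b4 = b4, dr1 = dr1,
                  f2 = f2, b5 = b5, dr2 = dr2, N = N)
  }
  list(probs = probs, cache = cache, running = r)
}

# Backward pass for softmax + cross-entropy. y_onehot: (N, K).
cnn_backward <- function(model, cache, probs, y_onehot) {
  p <- model$params; cfg <- model$cfg
  s <- cfg$pool_size; k <- cfg$kernel_size
  N <- cache$N
  g <- list()

  dlogits <- (probs - y_onehot) / N
  d3 <- dense_backward(dlogits, cache$dr2$out, p$dW3)
  g$dW3 <- d3$dW; g$db3 <- d3$db

  dd <- dropout_backward(d3$dx, cache$dr2, cfg$dropout_p)
  bb5 <- bn_backward(dd, cache$b5, p$g5)
  g$g5 <- bb5$dgamma; g$be5 <- bb5$dbeta
  dd <- relu_backward(bb5$dx, cache$f2)
  d2 <- dense_backward(dd, cache$dr1$out, p$dW2)
  g$dW2 <- d2$dW; g$db2 <- d2$db

  dd <- dropout_backward(d2$dx, cache$dr1, cfg$dropout_p)
  bb4 <- bn_backward(dd, cache$b4, p$g4)
  g$g4 <- bb4$dgamma; g$be4 <- bb4$dbeta
  dd <- relu_backward(bb4$dx, cache$f1)
  d1 <- dense_backward(dd, cache$flat, p$dW1)
  g$dW1 <- d1$dW; g$db1 <- d1$db

  datt <- array(d1$dx, dim(cache$at$out))
  ab <- att_backward(datt, cache$at, p$aW)
  g$aW <- ab$dW; g$ab <- ab$db

  dm3 <- maxpool_backward(ab$dx, cache$m3, s)
  dh3 <- matrix(dm3, N * dim(dm3)[2], dim(dm3)[3])
  bb3 <- bn_backward(dh3, cache$b3, p$g3)
  g$g3 <- bb3$dgamma; g$be3 <- bb3$dbeta
  dz3 <- relu_backward(array(bb3$dx, dim(cache$z3)), cache$c3$out)
  cb3 <- conv1d_backward(dz3, cache$c3, p$cW3, k)
  g$cW3 <- cb3$dW; g$cb3 <- cb3$db

  dm2 <- maxpool_backward(cb3$dx, cache$m2, s)
  dh2 <- matrix(dm2, N * dim(dm2)[2], dim(dm2)[3])
  bb2 <- bn_backward(dh2, cache$b2, p$g2)
  g$g2 <- bb2$dgamma; g$be2 <- bb2$dbeta
  dz2 <- relu_backward(array(bb2$dx, dim(cache$z2)), cache$c2$out)
  cb2 <- conv1d_backward(dz2, cache$c2, p$cW2, k)
  g$cW2 <- cb2$dW; g$cb2 <- cb2$db

  dm1 <- maxpool_backward(cb2$dx, cache$m1, s)
  dh1 <- matrix(dm1, N * dim(dm1)[2], dim(dm1)[3])
  bb1 <- bn_backward(dh1, cache$b1, p$g1)
  g$g1 <- bb1$dgamma; g$be1 <- bb1$dbeta
  dz1 <- relu_backward(array(bb1$dx, dim(cache$z1)), cache$c1$out)
  cb1 <- conv1d_backward(dz1, cache$c1, p$cW1, k)
  g$cW1 <- cb1$dW; g$cb1 <- cb1$db

  g
}

#' Predict beat classes
#'
#' Runs the network in inference mode (batch-norm running statistics,
#' dropout disabled); inference is fully deterministic.
#'
#' @param object A built (ideally trained) `ecg_cnn`.
#' @param beats Matrix of beats (rows x input_length), a `beat_dataset`, or
#'   a list of `beat_segment`s.
#' @param ... Unused.
#' @return List with `prob` (rows are probability vectors over the K
#'   classes, each summing to 1) and `label` (argmax class per row, ties
#'   broken by the lowest class index).
#' @export
predict.ecg_cnn <- function(object, beats, ...) {
  x <- as_beat_matrix(beats)
  if (ncol(x) != object$cfg$input_length) {
    abort_invalid(sprintf(
      "beats have length %d but the model expects %d",
      ncol(x), object$cfg$input_length))
  }
  probs <- cnn_forward(object, x, training = FALSE, keep_cache = FALSE)$probs
  list(prob = probs,
       label = as.integer(max.col(probs, ties.method = "first") - 1L))
}

# Coerce supported beat containers to a plain matrix.
as_beat_matrix <- function(beats) {
  if (inherits(beats, "beat_dataset")) return(beats$beats)
  if (is.list(beats) && length(beats) > 0 &&
      inherits(beats[[1]], "beat_segment")) {
    return(do.call(rbind, lapply(beats, function(b) b$samples)))
  }
  if (is.numeric(beats) && is.null(dim(beats))) {
    return(matrix(beats, nrow = 1L))
  }
  if (is.matrix(beats)) return(beats)
  abort_invalid("unsupported beats container")
}
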