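test_that("default architecture has 3 conv blocks and 2 hidden dense layers", {
  m <- build_model(model_config())
  layers <- model_layers(m)
  convs <- layers[layers$kind == "conv", ]
  expect_equal(nrow(convs), 3L)
  expect_equal(convs$detail,
               c("64 filters, kernel 5, relu",
                 "128 filters, kernel 5, relu",
                 "256 filters, kernel 5, relu"))
  dense <- layers[layers$kind == "dense", ]
  expect_equal(nrow(dense), 3L)  # two hidden + output head
  expect_equal(dense$output_shape[1:2], c("512", "256"))
  expect_equal(tail(layers$kind, 1), "softmax")
  expect_equal(sum(layers$kind == "attention"), 1L)
})

test_that("initialization is a pure function of the seed", {
  a <- build_model(model_config(seed = 42))
  b <- build_model(model_config(seed = 42))
  expect_identical(a$params, b$params)
  c <- build_model(model_config(seed = 43))
  expect_false(identical(a$params, c$params))
})

test_that("build_model rejects inputs too short for three poolings", {
  expect_error(build_model(model_config(input_length = 7L)), "too short")
})

test_that("forward pass emits probability rows over 5 classes", {
  m <- build_model(tiny_cfg())
  x <- matrix(0, 4, 64)
  out <- predict(m, x)
  expect_equal(dim(out$prob), c(4L, 5L))
  expect_equal(rowSums(out$prob), rep(1, 4), tolerance = 1e-6)
  expect_true(all(out$label %in% 0:4))
})

test_that("attention matches the scalar hand evaluation", {
  res <- attention_forward(matrix(c(1, -1), ncol = 1), W = 1, b = 0)
  q <- tanh(c(1, -1))
  expect_equal(q, c(0.7616, -0.7616), tolerance = 1e-4)
  expect_equal(res$a, c(0.821, 0.179), tolerance = 1e-3)
  expect_equal(res$attended, matrix(c(0.821, -0.179), ncol = 1),
               tolerance = 1e-3)
})

test_that("attention weights form a distribution and zeros give uniform", {
  z <- attention_forward(matrix(0, 7, 3), W = rnorm(3), b = 2.5)
  expect_equal(z$a, rep(1 / 7, 7))
  expect_equal(z$attended, matrix(0, 7, 3))
  set.seed(123)
  for (i in 1:100) {
    T_ <- sample(2:12, 1); C <- sample(1:6, 1)
    r <- attention_forward(matrix(rnorm(T_ * C), T_, C), rnorm(C), rnorm(1))
    expect_equal(sum(r$a), 1, tolerance = 1e-6)
    expect_true(all(r$a >= 0))
    expect_equal(dim(r$attended), c(T_, C))  # shape-preserving rescale
  }
  expect_error(attention_forward(matrix(0, 3, 2), W = c(1, 2, 3)), "channel")
})

test_that("max pooling equals a brute-force windowed maximum", {
  set.seed(11)
  for (i in 1:25) {
    N <- sample(1:4, 1); T_ <- sample(4:15, 1); C <- sample(1:5, 1)
    s <- sample(2:3, 1)
    x <- array(rnorm(N * T_ * C), c(N, T_, C))
    got <- ecgtriage:::maxpool_forward(x, s)$out
    T_out <- T_ %/% s
    want <- array(0, c(N, T_out, C))
    for (n in 1:N) for (to in 1:T_out) for (c in 1:C) {
      want[n, to, c] <- max(x[n, ((to - 1) * s + 1):(to * s), c])
    }
    expect_equal(got, want)
  }
})

test_that("batch norm maps a constant batch to beta", {
  x <- matrix(5, 32, 3)
  gamma <- c(2, 3, 4); beta <- c(-1, 0, 1)
  out <- ecgtriage:::bn_forward(x, gamma, beta, numeric(3), rep(1, 3),
                                training = TRUE)
  for (j in 1:3) expect_equal(out$out[, j], rep(beta[j], 32), tolerance = 1e-6)
})

test_that("dropout keeps about 1-p of units in training, all at inference", {
  set.seed(21)
  p <- 0.3
  x <- matrix(1, 100, 100)  # 10,000 units
  out <- ecgtriage:::dropout_forward(x, p, training = TRUE)
  kept <- mean(out$out != 0)
  tol3sig <- 3 * sqrt(p * (1 - p) / length(x))
  expect_lt(abs(kept - (1 - p)), tol3sig)
  # kept units are rescaled so the layer is unbiased in expectation
  expect_equal(unique(as.numeric(out$out[out$out != 0])), 1 / (1 - p))
  infer <- ecgtriage:::dropout_forward(x, p, training = FALSE)
  expect_identical(infer$out, x)
})

test_that("inference is deterministic and rejects length mismatches", {
  m <- build_model(tiny_cfg())
  x <- matrix(rnorm(64), 1, 64)
  batch <- rbind(x, x, x)
  out <- predict(m, batch)
  expect_equal(out$prob[1, ], out$prob[2, ])
  expect_equal(out$prob[2, ], out$prob[3, ])
  expect_identical(predict(m, batch)$prob, out$prob)
  expect_error(predict(m, matrix(0, 2, 100)), "expects")
})
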