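test_that("training is fully seeded and history has one row per epoch", {
  ds <- tiny_dataset()
  cfg <- tiny_cfg(epochs = 3L)
  m1 <- train_model(build_model(cfg), ds, cfg)
  m2 <- train_model(build_model(cfg), ds, cfg)
  expect_equal(nrow(m1$history), 3L)
  expect_identical(m1$history$loss[1], m2$history$loss[1])
  expect_identical(m1$params, m2$params)
  expect_true(all(c("loss", "accuracy", "val_accuracy") %in%
                    names(m1$history)))
})

test_that("training rejects single-class or untagged data", {
  ds <- tiny_dataset()
  solo <- ds
  keep <- solo$labels == 0L
  solo$beats <- solo$beats[keep, ]; solo$labels <- solo$labels[keep]
  solo$split <- rep("train", sum(keep))
  expect_error(train_model(build_model(tiny_cfg()), solo), "2 classes")
  untagged <- ds
  untagged$split <- rep(NA_character_, length(ds$labels))
  expect_error(train_model(build_model(tiny_cfg()), untagged), "split")
})

test_that("evaluate_model scores a tagged split end to end", {
  ds <- tiny_dataset(n_per_class = 8L)
  cfg <- tiny_cfg(epochs = 4L)
  fitted <- train_model(build_model(cfg), ds, cfg)
  rep_ <- suppressWarnings(evaluate_model(fitted, ds, split = "test"))
  expect_s3_class(rep_, "evaluation_report")
  expect_equal(rep_$total, sum(ds$split == "test"))
  expect_true(rep_$accuracy >= 0 && rep_$accuracy <= 1)
  expect_error(evaluate_model(fitted, ds, split = "nope"), "no rows")
})

test_that("confusion_matrix counts true-by-predicted pairs", {
  cm <- confusion_matrix(0:4, 0:4, 5)
  expect_equal(unname(diag(unclass(cm))), rep(1L, 5))
  expect_equal(sum(cm), 5L)
  cm2 <- confusion_matrix(c(0, 0, 1), c(0, 1, 1), 2)
  expect_equal(unname(unclass(cm2)), matrix(c(1L, 0L, 1L, 1L), 2, 2))
  expect_error(confusion_matrix(c(0, 7), c(0, 1), 5), "0..4")
  expect_error(confusion_matrix(0:1, 0:2, 5), "equal length")
})

test_that("metrics_report reproduces hand-computed values", {
  # harmonic mean of a printed precision/recall pair
  expect_equal(round(f1_score(0.88, 0.50), 2), 0.64)
  # 2-class counts TP=9 FP=1 FN=3 TN=7
  cm <- matrix(c(9L, 1L, 3L, 7L), 2, 2)  # rows = true (pos, neg), cols = pred
  rep2 <- metrics_report(cm)
  expect_equal(rep2$per_class$precision[1], 0.9)
  expect_equal(rep2$per_class$recall[1], 0.75)
  expect_equal(rep2$per_class$f1[1], 0.8182, tolerance = 1e-4)
  # perfect diagonal
  perf <- metrics_report(diag(c(5L, 8L, 2L)))
  expect_equal(perf$accuracy, 1)
  expect_true(all(perf$per_class[, c("precision", "recall", "f1")] == 1))
})

test_that("metrics agree with an independent brute-force recount", {
  set.seed(17)
  for (trial in 1:100) {
    k <- sample(2:6, 1)
    n <- sample(5:60, 1)
    y_true <- sample(0:(k - 1), n, replace = TRUE)
    y_pred <- sample(0:(k - 1), n, replace = TRUE)
    cm <- confusion_matrix(y_true, y_pred, k)
    rep_ <- suppressWarnings(metrics_report(cm))
    # recount every (true, pred) pair from scratch
    for (cl in 0:(k - 1)) {
      tp <- sum(y_true == cl & y_pred == cl)
      fp <- sum(y_true != cl & y_pred == cl)
      fn <- sum(y_true == cl & y_pred != cl)
      p <- if (tp + fp > 0) tp / (tp + fp) else 0
      r <- if (tp + fn > 0) tp / (tp + fn) else 0
      expect_equal(rep_$per_class$precision[cl + 1], p)
      expect_equal(rep_$per_class$recall[cl + 1], r)
      expect_equal(rep_$per_class$support[cl + 1], sum(y_true == cl))
    }
    expect_equal(rep_$accuracy, mean(y_true == y_pred))
    expect_equal(sum(cm), n)
    # weighted averages are the support-weighted combination
    sup <- rep_$per_class$support
    expect_equal(unname(rep_$weighted["f1"]),
                 sum(rep_$per_class$f1 * sup) / sum(sup))
    expect_equal(unname(rep_$macro["precision"]),
                 mean(rep_$per_class$precision))
  }
})

test_that("zero-denominator classes report 0 with a warning", {
  cm <- matrix(c(3L, 0L, 2L, 0L), 2, 2)  # class 1 never true nor predicted? no: col2
  cm <- matrix(0L, 3, 3); cm[1, 1] <- 5L; cm[2, 1] <- 2L
  expect_warning(rep_ <- metrics_report(cm), "zero denominator")
  expect_equal(rep_$per_class$precision[3], 0)
  expect_equal(rep_$per_class$f1[3], 0)
})

test_that("grid search enumerates the full grid and picks the best point", {
  ds <- tiny_dataset()
  g1 <- grid_spec(conv_filters = list(c(4L, 6L, 8L)),
                  dense_units = list(c(16L, 12L)),
                  dropout_p = 0.2, learning_rate = 0.01,
                  batch_size = 16L, epochs = 2L)
  res1 <- grid_search(g1, ds, seed = 1)
  expect_equal(nrow(res1$results), 1L)
  expect_equal(res1$best_config$learning_rate, 0.01)
  expect_equal(res1$best_config$epochs, 2L)

  g2 <- grid_spec(conv_filters = list(c(4L, 6L, 8L)),
                  dense_units = list(c(16L, 12L)),
                  dropout_p = c(0.2, 0.5), learning_rate = c(0.01, 0.001),
                  batch_size = 16L, epochs = 2L)
  res2 <- grid_search(g2, ds, seed = 1, epochs_budget = 1L)
  expect_equal(nrow(res2$results), 4L)  # product of axis lengths
})

test_that("a divergent learning rate loses the grid to a sane one", {
  ds <- tiny_dataset(n_per_class = 8L)
  g <- grid_spec(conv_filters = list(c(4L, 6L, 8L)),
                 dense_units = list(c(16L, 12L)),
                 dropout_p = 0.2, learning_rate = c(10.0, 0.005),
                 batch_size = 16L, epochs = 6L)
  res <- grid_search(g, ds, seed = 2)
  expect_equal(res$best_config$learning_rate, 0.005)
  div <- res$results$val_accuracy[res$results$learning_rate == 10.0]
  expect_lte(div, 0.5)  # divergent run scores at or near chance
})
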