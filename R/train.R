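# Training (Adam + categorical cross-entropy) and hyperparameter grid search.

#' Train the classifier
#'
#' Minimizes categorical cross-entropy with Adam. All randomness (shuffling
#' and dropout; initialization is owned by [build_model()]) flows from
#' `cfg$seed`, so a rebuilt model retrained with the same data and seed
#' reproduces the run exactly.
#'
#' @param model An `ecg_cnn` from [build_model()].
#' @param data A `beat_dataset` with split tags assigned
#'   (see [assign_splits()]); rows tagged "train" are fitted, rows tagged
#'   "val" (if any) are scored each epoch.
#' @param cfg Configuration; defaults to the model's own.
#' @param epochs Optional override of `cfg$epochs` (used by
#'   [grid_search()] for reduced-budget scoring).
#' @param verbose Print a line per epoch.
#' @return The trained model, with `$history` (data.frame of per-epoch
#'   `loss`, `accuracy` and, when a validation split exists,
#'   `val_accuracy`).
#' @export
train_model <- function(model, data, cfg = model$cfg, epochs = NULL,
                        verbose = FALSE) {
  stopifnot(inherits(model, "ecg_cnn"), inherits(data, "beat_dataset"))
  if (length(unique(data$labels)) < 2L) {
    abort_invalid("training data must contain at least 2 classes")
  }
  if (!any(data$split == "train", na.rm = TRUE)) {
    abort_invalid("data has no 'train' split tags; call assign_splits() first")
  }
  epochs <- if (is.null(epochs)) cfg$epochs else check_count(epochs, "epochs")
  tr <- which(data$split == "train")
  xv <- NULL
  if (any(data$split == "val", na.rm = TRUE)) {
    va <- which(data$split == "val")
    xv <- data$beats[va, , drop = FALSE]
    yv <- data$labels[va]
  }
  x <- data$beats[tr, , drop = FALSE]
  y <- data$labels[tr]
  K <- cfg$n_classes
  if (any(y < 0 | y >= K)) abort_invalid("labels outside 0..K-1")
  n <- nrow(x)
  yh <- matrix(0, n, K)
  yh[cbind(seq_len(n), y + 1L)] <- 1

  adam_m <- lapply(model$params, function(p) p * 0)
  adam_v <- adam_m
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  t_step <- model$n_updates
  history <- data.frame(epoch = integer(), loss = numeric(),
                        accuracy = numeric())
  if (!is.null(xv)) history$val_accuracy <- numeric()

  with_local_seed(cfg$seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      losses <- c(); accs <- c(); wts <- c()
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        xb <- x[idx, , drop = FALSE]
        yb <- yh[idx, , drop = FALSE]
        fw <- cnn_forward(model, xb, training = TRUE)
        model$running <- fw$running
        pb <- fw$probs
        loss <- -mean(log(pmax(pb[yb == 1], 1e-12)))
        acc <- mean(max.col(pb, ties.method = "first") ==
                      max.col(yb, ties.method = "first"))
        grads <- cnn_backward(model, fw$cache, pb, yb)
        t_step <- t_step + 1L
        for (nm in names(grads)) {
          g <- grads[[nm]]
          if (!all(is.finite(g))) g <- array(0, dim = dim(g) %||% length(g))
          adam_m[[nm]] <- b1 * adam_m[[nm]] + (1 - b1) * g
          adam_v[[nm]] <- b2 * adam_v[[nm]] + (1 - b2) * g * g
          mh <- adam_m[[nm]] / (1 - b1^t_step)
          vh <- adam_v[[nm]] / (1 - b2^t_step)
          model$params[[nm]] <- model$params[[nm]] -
            cfg$learning_rate * mh / (sqrt(vh) + eps)
        }
        losses <- c(losses, loss); accs <- c(accs, acc)
        wts <- c(wts, length(idx))
      }
      row <- data.frame(epoch = ep,
                        loss = sum(losses * wts) / sum(wts),
                        accuracy = sum(accs * wts) / sum(wts))
      if (!is.null(xv)) {
        pv <- cnn_forward(model, xv, training = FALSE, keep_cache = FALSE)$probs
        pred <- max.col(pv, ties.method = "first") - 1L
        row$val_accuracy <- mean(pred == yv)
      }
      history <- rbind(history, row)
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  acc %.4f%s", ep, row$loss,
                        row$accuracy,
                        if (!is.null(xv)) sprintf("  val_acc %.4f", row$val_accuracy) else ""))
      }
    }
  })
  model$n_updates <- t_step
  model$trained <- TRUE
  model$history <- history
  model
}

#' Hyperparameter grid specification
#'
#' Candidate lists for the tunable hyperparameters; the cartesian product
#' defines the search space.
#'
#' @param conv_filters List of integer triples.
#' @param dense_units List of integer pairs.
#' @param dropout_p,learning_rate,batch_size,epochs Numeric candidate
#'   vectors.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(conv_filters = list(c(32L, 64L, 128L),
                                          c(64L, 128L, 256L),
                                          c(128L, 256L, 512L)),
                      dense_units = list(c(128L, 256L), c(256L, 512L),
                                         c(512L, 256L)),
                      dropout_p = c(0.2, 0.5, 0.8),
                      learning_rate = c(0.1, 0.01, 0.001),
                      batch_size = c(128L, 256L, 512L),
                      epochs = c(25L, 40L, 50L)) {
  if (!length(conv_filters) || !length(dense_units) || !length(dropout_p) ||
      !length(learning_rate) || !length(batch_size) || !length(epochs)) {
    abort_invalid("every grid axis must be non-empty")
  }
  structure(list(conv_filters = conv_filters, dense_units = dense_units,
                 dropout_p = dropout_p, learning_rate = learning_rate,
                 batch_size = batch_size, epochs = epochs),
            class = "grid_spec")
}

#' Exhaustive grid search over hyperparameters
#'
#' Trains one model per grid point and selects the configuration with the
#' highest validation accuracy (ties broken by earliest grid order). A
#' divergent run (non-finite validation score) scores 0. `epochs_budget`
#' caps per-point epochs so the search stays desk-scale; the winning
#' configuration retains its own full epoch count for final retraining.
#'
#' @param grid A [grid_spec()].
#' @param data A `beat_dataset` with train/val split tags.
#' @param seed Integer seed shared by every candidate.
#' @param epochs_budget Optional reduced epochs per grid point.
#' @param verbose Print a line per grid point.
#' @return List with `best_config` (a [model_config()]) and `results`
#'   (data.frame with one row per grid point and its `val_accuracy`).
#' @export
grid_search <- function(grid, data, seed = 0L, epochs_budget = NULL,
                        verbose = FALSE) {
  stopifnot(inherits(grid, "grid_spec"), inherits(data, "beat_dataset"))
  combos <- expand.grid(
    conv_filters = seq_along(grid$conv_filters),
    dense_units = seq_along(grid$dense_units),
    dropout_p = grid$dropout_p,
    learning_rate = grid$learning_rate,
    batch_size = grid$batch_size,
    epochs = grid$epochs,
    KEEP.OUT.ATTRS = FALSE
  )
  results <- combos
  results$conv_filters <- vapply(combos$conv_filters, function(i)
    paste(grid$conv_filters[[i]], collapse = "-"), character(1))
  results$dense_units <- vapply(combos$dense_units, function(i)
    paste(grid$dense_units[[i]], collapse = "-"), character(1))
  results$val_accuracy <- NA_real_
  cfgs <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    cfg <- model_config(
      input_length = ncol(data$beats),
      conv_filters = grid$conv_filters[[combos$conv_filters[i]]],
      dense_units = grid$dense_units[[combos$dense_units[i]]],
      dropout_p = combos$dropout_p[i],
      learning_rate = combos$learning_rate[i],
      batch_size = as.integer(combos$batch_size[i]),
      epochs = as.integer(combos$epochs[i]),
      n_classes = length(unique(data$labels)),
      seed = seed
    )
    cfgs[[i]] <- cfg
    fitted <- train_model(build_model(cfg), data, cfg,
                          epochs = epochs_budget)
    va <- tail(fitted$history$val_accuracy, 1L)
    if (length(va) == 0L || !is.finite(va)) va <- 0
    results$val_accuracy[i] <- va
    if (verbose) {
      message(sprintf("grid point %d/%d: val_accuracy %.4f",
                      i, nrow(combos), va))
    }
  }
  best <- which.max(results$val_accuracy)  # ties: earliest grid order
  list(best_config = cfgs[[best]], results = results)
}
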