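# Training loop behavior: schedules, early stopping, divergence handling,
# learning on separable data, and cross-validation aggregation.

make_toy_data <- function(n_per = 8, size = 8, classes = 3, seed = 1) {
  # linearly separable blobs: class k lights up a distinct image region
  set.seed(seed)
  n <- n_per * classes
  x <- array(rnorm(size * size * n, sd = 0.05), c(1, size, size, n))
  y <- rep(seq_len(classes), each = n_per)
  for (i in seq_len(n)) {
    r <- ((y[i] - 1) %% classes) * 2 + 1
    x[1, r:(r + 1), , i] <- x[1, r:(r + 1), , i] + 1
  }
  list(x = x, y = y)
}

test_that("defaults mirror the study hyperparameters", {
  hp <- hyperparams()
  expect_equal(hp$learning_rate, 5e-4)
  expect_equal(hp$batch_size, 16L)
  expect_equal(hp$max_epochs, 30L)
  expect_equal(hp$patience, 5L)
  expect_equal(hp$lr_reduce_factor, 0.2)
  # one plateau event scales the learning rate to 1e-4
  expect_equal(hp$learning_rate * hp$lr_reduce_factor, 1e-4)
})

test_that("constant validation loss triggers patience stop after the epoch floor", {
  tr <- make_toy_data(n_per = 4)
  # degenerate validation set whose loss cannot improve: uniform labels on
  # identical all-zero images
  va_x <- array(0, c(1, 8, 8, 3))
  va_y <- c(1L, 2L, 3L)
  set.seed(2)
  model <- tiny_dense_model()
  # freeze learning so nothing changes: lr 0 keeps val loss exactly constant
  hp <- hyperparams(learning_rate = 0, max_epochs = 30L, seed = 3)
  fit <- train_model(model, list(x_train = tr$x, y_train = tr$y,
                                 x_val = va_x, y_val = va_y), hp)
  expect_equal(fit$stop_reason, "patience")
  # epoch 1 records the initial loss; two full patience windows later the
  # run stops, once past the 10-epoch floor: 1 + 2*5 = 11 epochs
  expect_equal(fit$epochs_run, 11L)
  # the plateau multiplier was applied on the way
  expect_lt(fit$final_lr, hp$learning_rate + 1e-15)
})

test_that("learning-rate plateau reduction applies the 0.2 factor", {
  tr <- make_toy_data(n_per = 4)
  va_x <- array(0, c(1, 8, 8, 3)); va_y <- c(1L, 2L, 3L)
  set.seed(4)
  model <- tiny_dense_model()
  hp <- hyperparams(learning_rate = 1e-9, max_epochs = 12L, seed = 5)
  fit <- train_model(model, list(x_train = tr$x, y_train = tr$y,
                                 x_val = va_x, y_val = va_y), hp)
  # one plateau event before the floor, one at it
  expect_equal(fit$final_lr, 1e-9 * 0.2^2, tolerance = 1e-20)
})

test_that("training a small model separates an easy synthetic problem", {
  tr <- make_toy_data(n_per = 10, seed = 6)
  va <- make_toy_data(n_per = 4, seed = 7)
  set.seed(8)
  model <- tiny_dense_model()
  hp <- hyperparams(learning_rate = 5e-3, batch_size = 8L, max_epochs = 25L,
                    seed = 9)
  fit <- train_model(model, list(x_train = tr$x, y_train = tr$y,
                                 x_val = va$x, y_val = va$y), hp)
  final_acc <- fit$history$val_acc[nrow(fit$history)]
  expect_gt(max(fit$history$val_acc), 1 / 3 + 0.4) # far above chance
  expect_true(all(fit$history$epoch <= hp$max_epochs))
  expect_s3_class(fit, "mbinet_fit")
  # history is monotone in epochs and finite
  expect_true(all(is.finite(fit$history$train_loss)))
})

test_that("empty training sets and divergence raise typed errors", {
  set.seed(10)
  model <- tiny_dense_model()
  va_x <- array(0, c(1, 8, 8, 2)); va_y <- c(1L, 2L)
  expect_error(train_model(model, list(x_train = array(0, c(1, 8, 8, 0)),
                                       y_train = integer(0),
                                       x_val = va_x, y_val = va_y)),
               "empty training set")
  tr <- make_toy_data(n_per = 3)
  # a corrupted parameter makes the loss non-finite on the first batch
  model$layers[[1]]$W[1] <- NaN
  hp <- hyperparams(max_epochs = 4L, seed = 11)
  expect_error(train_model(model, list(x_train = tr$x, y_train = tr$y,
                                       x_val = va_x, y_val = va_y), hp),
               "divergence")
})

test_that("fold-wise aggregation computes mean and sample SD", {
  # two folds with accuracies 0.9 and 1.0 -> mean 0.95, sd ~0.0707
  acc <- c(0.9, 1.0)
  expect_equal(mean(acc), 0.95)
  expect_equal(sd(acc), 0.0707, tolerance = 1e-3)
})

test_that("cross-validation on tiny synthetic data emits coherent reports", {
  p64 <- phantom_params(image_size = 64L)
  ds <- generate_dataset(10L, p64, seed = 21)
  hp <- hyperparams(max_epochs = 2L, min_epochs = 1L, batch_size = 8L,
                    seed = 22)
  cv <- cross_validate(ds$images, ds$labels, model_name = "Self-ONN4L",
                       hp = hp, input_size = c(64L, 64L, 3L),
                       folds = 1:2, seed = 23)
  expect_length(cv$fold_results, 2L)
  expect_equal(nrow(cv$aggregate), 5L)
  expect_true(all(cv$fold_metrics >= 0 & cv$fold_metrics <= 1))
  expect_true(all(is.finite(cv$aggregate$mean)))
  # identical metrics across folds give zero SD (degenerate check on copies)
  fake <- cv; fake$fold_metrics <- rbind(cv$fold_metrics[1, ],
                                         cv$fold_metrics[1, ])
  expect_equal(unname(apply(fake$fold_metrics, 2, sd)), rep(0, 5))
  # rerunning with the same seeds reproduces the aggregate table
  cv2 <- cross_validate(ds$images, ds$labels, model_name = "Self-ONN4L",
                        hp = hp, input_size = c(64L, 64L, 3L),
                        folds = 1:2, seed = 23)
  expect_equal(cv$aggregate, cv2$aggregate, tolerance = 1e-12)
  # report artifacts land on disk
  out <- file.path(tempdir(), "cv_report")
  unlink(out, recursive = TRUE)
  write_crossval_report(cv, out)
  expect_true(all(file.exists(file.path(out,
    c("fold_metrics.csv", "aggregate_metrics.csv", "metrics.json",
      "confusion_fold1.csv", "roc_fold1.csv", "history_fold1.csv")))))
  unlink(out, recursive = TRUE)
})

test_that("evaluate_model ties scores, confusion and metrics together", {
  set.seed(30)
  model <- build_variant("Self-ONN4L", input_size = c(16L, 16L, 3L))
  x <- array(rnorm(3 * 16 * 16 * 12, sd = 0.3), c(3, 16, 16, 12))
  y <- rep(class_labels(), 2)
  ev <- evaluate_model(model, x, y)
  expect_equal(dim(ev$scores), c(12L, 6L))
  expect_equal(rowSums(ev$scores), rep(1, 12), tolerance = 1e-6)
  expect_equal(sum(ev$confusion), 12L)
  # confusion conservation: per-class TP + FN equals support
  expect_equal(unname(rowSums(unclass(ev$confusion))), rep(2L, 6L))
})
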