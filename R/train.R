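# Training loop (Adam, categorical cross-entropy, reduce-on-plateau,
# patience-based early stopping) and the cross-validation driver.

#' Training hyperparameters
#'
#' Defaults are the study settings: learning rate 5e-4, batch size 16, at
#' most 30 epochs, patience 5 on validation loss, learning-rate reduction
#' factor 0.2 on plateau, Adam optimizer. "No improvement" means the
#' validation loss failed to drop by more than \code{improve_tol} (1e-4).
#' Early stopping is not allowed before \code{min_epochs} (10) epochs.
#'
#' @param learning_rate,batch_size,max_epochs,patience,lr_reduce_factor
#'   Optimization settings (see above).
#' @param min_epochs Hard floor of epochs before early stopping may trigger.
#' @param improve_tol Minimum validation-loss drop that counts as progress.
#' @param seed Optional integer seed for shuffling/initialization.
#' @return List of class \code{hyperparams}.
#' @export
hyperparams <- function(learning_rate = 5e-4, batch_size = 16L,
                        max_epochs = 30L, patience = 5L,
                        lr_reduce_factor = 0.2, min_epochs = 10L,
                        improve_tol = 1e-4, seed = NULL) {
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 lr_reduce_factor = lr_reduce_factor,
                 min_epochs = as.integer(min_epochs),
                 improve_tol = improve_tol,
                 optimizer = "adam", seed = seed),
            class = "hyperparams")
}

adam_init <- function(model) {
  lapply(model$layers, function(l) {
    if (l$kind %in% c("operational", "dense"))
      list(mW = array(0, dim(l$W)), vW = array(0, dim(l$W)),
           mb = numeric(length(l$b)), vb = numeric(length(l$b)))
    else NULL
  })
}

adam_step <- function(model, state, grads, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  for (j in seq_along(model$layers)) {
    g <- grads[[j]]
    if (is.null(g)) next
    s <- state[[j]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$dW
    s$vW <- beta2 * s$vW + (1 - beta2) * g$dW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$db
    s$vb <- beta2 * s$vb + (1 - beta2) * g$db^2
    model$layers[[j]]$W <- model$layers[[j]]$W -
      lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + eps)
    model$layers[[j]]$b <- model$layers[[j]]$b -
      lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    state[[j]] <- s
  }
  list(model = model, state = state)
}

eval_loss_acc <- function(model, x, y_idx, chunk = 64L) {
  n <- dim(x)[4]
  loss <- 0; correct <- 0
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    xb <- x[, , , s:e, drop = FALSE]
    p <- nn_forward(model, xb)$probs
    yi <- y_idx[s:e]
    loss <- loss - sum(log(pmax(p[cbind(yi, seq_along(yi))], 1e-12)))
    correct <- correct + sum(max.col(t(p)) == yi)
  }
  c(loss = loss / n, acc = correct / n)
}

labels_to_idx <- function(y) {
  if (is.factor(y)) return(as.integer(y))
  if (is.numeric(y)) return(as.integer(y))
  match(as.character(y), CLASS_LABELS)
}

#' Train a Self-ONN classifier
#'
#' Minimizes categorical cross-entropy with Adam. The validation loss drives
#' two schedules: when it fails to improve for \code{patience} consecutive
#' epochs the learning rate is multiplied by \code{lr_reduce_factor}, and
#' (after the \code{min_epochs} floor) training stops early. The returned
#' fit carries the parameters of the best-validation-loss epoch.
#'
#' @param model A \code{sonn_model} (its current weights are the starting
#'   point).
#' @param data List with \code{x_train}, \code{y_train}, \code{x_val},
#'   \code{y_val} and optionally \code{x_test}, \code{y_test}; x arrays are
#'   channels-first (C,H,W,N), y are labels or 1-based indices.
#' @param hp A [hyperparams()].
#' @param verbose Print one line per epoch.
#' @return Object of class \code{mbinet_fit}: the trained \code{model}, the
#'   per-epoch \code{history} data frame, \code{stop_reason}
#'   ("patience" or "max_epochs"), \code{epochs_run} and the final learning
#'   rate.
#' @export
train_model <- function(model, data, hp = hyperparams(), verbose = FALSE) {
  x_train <- as_batch(data$x_train)
  n <- dim(x_train)[4]
  if (n < 1) stop("empty training set")
  y_train <- labels_to_idx(data$y_train)
  x_val <- as_batch(data$x_val); y_val <- labels_to_idx(data$y_val)
  has_test <- !is.null(data$x_test)
  if (has_test) { x_test <- as_batch(data$x_test); y_test <- labels_to_idx(data$y_test) }

  if (!is.null(hp$seed)) set.seed(hp$seed)
  state <- adam_init(model)
  lr <- hp$learning_rate
  best_val <- Inf; best_model <- model
  stall <- 0L; tstep <- 0L
  stop_reason <- "max_epochs"
  hist <- list()

  for (epoch in seq_len(hp$max_epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_correct <- 0
    for (s in seq(1L, n, by = hp$batch_size)) {
      ix <- ord[s:min(s + hp$batch_size - 1L, n)]
      xb <- x_train[, , , ix, drop = FALSE]
      fw <- nn_forward(model, xb, keep_cache = TRUE)
      bk <- nn_backward(model, fw, y_train[ix])
      if (!is.finite(bk$loss))
        stop(sprintf("divergence error: non-finite loss at epoch %d", epoch))
      ep_loss <- ep_loss + bk$loss * length(ix)
      ep_correct <- ep_correct + sum(max.col(t(fw$probs)) == y_train[ix])
      tstep <- tstep + 1L
      upd <- adam_step(model, state, bk$grads, lr, tstep)
      model <- upd$model; state <- upd$state
    }
    val <- eval_loss_acc(model, x_val, y_val)
    row <- data.frame(epoch = epoch, lr = lr,
                      train_loss = ep_loss / n, train_acc = ep_correct / n,
                      val_loss = val["loss"], val_acc = val["acc"])
    if (has_test) {
      te <- eval_loss_acc(model, x_test, y_test)
      row$test_loss <- te["loss"]; row$test_acc <- te["acc"]
    }
    hist[[epoch]] <- row
    if (verbose)
      message(sprintf("epoch %2d  lr %.2e  train loss %.4f acc %.3f  val loss %.4f acc %.3f",
                      epoch, lr, row$train_loss, row$train_acc,
                      row$val_loss, row$val_acc))

    if (val["loss"] < best_val - hp$improve_tol) {
      best_val <- val["loss"]; best_model <- model; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= hp$patience) {
        lr <- lr * hp$lr_reduce_factor
        if (epoch >= hp$min_epochs) { stop_reason <- "patience"; break }
        stall <- 0L
      }
    }
  }
  history <- do.call(rbind, hist)
  rownames(history) <- NULL
  structure(list(model = best_model, history = history,
                 stop_reason = stop_reason, epochs_run = nrow(history),
                 best_val_loss = best_val, final_lr = lr, hp = hp),
            class = "mbinet_fit")
}

#' @export
print.mbinet_fit <- function(x, ...) {
  cat(sprintf("%s fit: %d epoch(s), stopped on %s\n",
              x$model$name, x$epochs_run, x$stop_reason))
  last <- x$history[nrow(x$history), ]
  cat(sprintf("  best val loss %.4f; last epoch val acc %.3f\n",
              x$best_val_loss, last$val_acc))
  invisible(x)
}

#' @export
summary.mbinet_fit <- function(object, ...) {
  print(object)
  cat("training history (first/last epochs):\n")
  h <- object$history
  show <- unique(c(1, nrow(h)))
  print(h[show, ], row.names = FALSE)
  invisible(object)
}

#' @export
predict.mbinet_fit <- function(object, newdata, type = c("class", "prob"),
                               ...) {
  predict(object$model, newdata, type = match.arg(type), ...)
}

#' Plot training curves
#'
#' @param x An \code{mbinet_fit}.
#' @param ... Passed to \code{matplot}.
#' @importFrom graphics legend matplot
#' @export
plot.mbinet_fit <- function(x, ...) {
  h <- x$history
  cols <- intersect(c("train_loss", "val_loss", "test_loss"), names(h))
  matplot(h$epoch, as.matrix(h[cols]), type = "l", lty = 1,
          xlab = "epoch", ylab = "cross-entropy loss", ...)
  legend("topright", legend = cols, col = seq_along(cols), lty = 1, bty = "n")
  invisible(x)
}

#' Evaluate a model on labeled data
#'
#' @param model A \code{sonn_model} or \code{mbinet_fit}.
#' @param x Channels-first batch (C,H,W,N).
#' @param y Labels.
#' @return List with \code{scores}, predicted labels, the
#'   [confusion_matrix()], the [class_metrics()] report, and [roc_auc()].
#' @export
evaluate_model <- function(model, x, y) {
  if (inherits(model, "mbinet_fit")) model <- model$model
  x <- as_batch(x)
  n <- dim(x)[4]
  scores <- matrix(0, n, model$n_classes)
  for (s in seq(1L, n, by = 64L)) {
    e <- min(s + 63L, n)
    scores[s:e, ] <- forward(model, x[, , , s:e, drop = FALSE])
  }
  colnames(scores) <- CLASS_LABELS[seq_len(model$n_classes)]
  pred <- CLASS_LABELS[max.col(scores)]
  true <- if (is.factor(y)) as.character(y) else
    if (is.numeric(y)) CLASS_LABELS[y] else as.character(y)
  cm <- confusion_matrix(true, pred)
  list(scores = scores, predicted = pred, true = true,
       confusion = cm, metrics = class_metrics(cm),
       roc = roc_auc(scores, true))
}

dataset_to_arrays <- function(images, labels, stats = rmb_norm_stats()) {
  norm <- lapply(images, zscore_normalize, stats = stats)
  list(x = images_to_batch(norm), y = labels_to_idx(labels))
}

#' Stratified k-fold cross-validation of a model
#'
#' Trains one freshly initialized model per fold on the plan's training
#' split (optionally expanded with the augmentation menu — training split
#' only, never validation or test), evaluates on the fold's test split, and
#' aggregates the weighted metrics as mean and sample standard deviation
#' over folds.
#'
#' @param images List of H x W x 3 arrays in \[0, 1\] (pre-normalization).
#' @param labels Labels parallel to \code{images}.
#' @param model_name A [model_zoo()] name.
#' @param hp A [hyperparams()].
#' @param plan Optional [build_fold_plan()]; built from \code{labels}
#'   otherwise.
#' @param input_size Model input (height, width, channels); images are
#'   assumed already sized.
#' @param q_order Polynomial order passed to the variant builder.
#' @param augment Expand the training split with
#'   [default_augmentation_menu()].
#' @param stats Normalization statistics.
#' @param folds Which folds to run (default all).
#' @param seed Base seed; fold f uses seed + f for initialization/shuffling.
#' @param verbose Print per-epoch progress.
#' @return Object of class \code{crossval_result}: per-fold evaluations and
#'   an aggregate mean/SD table.
#' @export
cross_validate <- function(images, labels, model_name = "MBINet",
                           hp = hyperparams(), plan = NULL,
                           input_size = c(dim(images[[1]])[1:2], 3L),
                           q_order = 3L, augment = FALSE,
                           stats = rmb_norm_stats(), folds = NULL,
                           seed = 1L, verbose = FALSE) {
  if (is.null(plan)) plan <- build_fold_plan(labels, seed = seed)
  if (is.null(folds)) folds <- seq_len(plan$k)
  fold_results <- list()
  for (f in folds) {
    sp <- plan$folds[[f]]
    tr_imgs <- images[sp$train]; tr_labs <- labels[sp$train]
    if (augment) {
      aug <- augment_images(tr_imgs, tr_labs, include_original = FALSE)
      tr_imgs <- aug$images; tr_labs <- aug$labels
    }
    tr <- dataset_to_arrays(tr_imgs, tr_labs, stats)
    va <- dataset_to_arrays(images[sp$validation], labels[sp$validation], stats)
    te <- dataset_to_arrays(images[sp$test], labels[sp$test], stats)
    set.seed(seed + f)
    model <- build_variant(model_name, q_order = q_order,
                           input_size = input_size)
    hpf <- hp; hpf$seed <- seed + f
    fit <- tryCatch(
      train_model(model, list(x_train = tr$x, y_train = tr$y,
                              x_val = va$x, y_val = va$y), hpf,
                  verbose = verbose),
      error = function(e) stop(sprintf("fold %d: %s", f, conditionMessage(e)),
                               call. = FALSE))
    ev <- evaluate_model(fit$model, te$x, CLASS_LABELS[te$y])
    fold_results[[as.character(f)]] <- list(fit = fit, evaluation = ev)
  }
  metr <- t(vapply(fold_results, function(fr)
    c(accuracy = fr$evaluation$metrics$overall_accuracy,
      fr$evaluation$metrics$weighted[c("precision", "recall",
                                       "specificity", "f1")]),
    numeric(5)))
  agg <- data.frame(metric = colnames(metr),
                    mean = colMeans(metr),
                    sd = if (nrow(metr) > 1) apply(metr, 2, sd) else
                      rep(NA_real_, ncol(metr)),
                    row.names = NULL)
  structure(list(plan = plan, model_name = model_name,
                 fold_results = fold_results, fold_metrics = metr,
                 aggregate = agg),
            class = "crossval_result")
}

#' @export
print.crossval_result <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation of %s\n",
              length(x$fold_results), x$model_name))
  agg <- x$aggregate
  agg$mean <- round(agg$mean, 4); agg$sd <- round(agg$sd, 4)
  print(agg, row.names = FALSE)
  invisible(x)
}

#' Write cross-validation report artifacts
#'
#' Emits per-fold and aggregate metrics as CSV and JSON, the per-fold
#' confusion matrices and ROC points as CSV, into \code{out_dir}.
#'
#' @param cv A [cross_validate()] result.
#' @param out_dir Output directory (created if needed).
#' @return \code{out_dir}, invisibly.
#' @importFrom utils write.csv
#' @export
write_crossval_report <- function(cv, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(data.frame(fold = rownames(cv$fold_metrics), cv$fold_metrics,
                       row.names = NULL),
            file.path(out_dir, "fold_metrics.csv"), row.names = FALSE)
  write.csv(cv$aggregate, file.path(out_dir, "aggregate_metrics.csv"),
            row.names = FALSE)
  jsonlite::write_json(list(model = cv$model_name,
                            fold_metrics = as.data.frame(cv$fold_metrics),
                            aggregate = cv$aggregate),
                       file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  for (f in names(cv$fold_results)) {
    ev <- cv$fold_results[[f]]$evaluation
    write.csv(as.data.frame(unclass(ev$confusion)),
              file.path(out_dir, sprintf("confusion_fold%s.csv", f)))
    roc_rows <- do.call(rbind, lapply(names(ev$roc$per_class), function(cl) {
      z <- ev$roc$per_class[[cl]]
      if (is.null(z)) return(NULL)
      data.frame(class = cl, fpr = z$fpr, tpr = z$tpr)
    }))
    write.csv(roc_rows, file.path(out_dir, sprintf("roc_fold%s.csv", f)),
              row.names = FALSE)
    h <- cv$fold_results[[f]]$fit$history
    write.csv(h, file.path(out_dir, sprintf("history_fold%s.csv", f)),
              row.names = FALSE)
  }
  invisible(out_dir)
}
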