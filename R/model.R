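#' Model configuration for Self-ONN classifiers
#'
#' Declarative description of an operational-layer classifier: per-layer
#' output channels, which layers are followed by a 2x2 stride-2 max pool, a
#' final pre-flatten max pool, the polynomial order Q and the dense head.
#'
#' @param name Model name.
#' @param input_size (height, width, channels) of the expected input.
#' @param channel_schedule Integer vector, output channels per operational
#'   layer (all kernels 3x3, same-padded, tanh-activated).
#' @param pool_after Indices of operational layers followed by a
#'   \code{pool_size} stride-\code{pool_stride} max pool.
#' @param pool_size,pool_stride Mid-network pooling geometry (default 2x2,
#'   stride 2).
#' @param final_pool,final_pool_stride Pre-flatten pooling geometry (default
#'   3x3, stride 3, floor division, no ceil mode).
#' @param q_order Polynomial order Q of every operational layer (1 = vanilla
#'   CNN).
#' @param n_classes Number of output classes (6).
#' @param dense_hidden Width of an optional extra dense hidden layer
#'   (tanh-activated) before the class head, or NULL for none.
#' @param expect_flatten If non-NULL, the flatten length the architecture
#'   must reach; a mismatch is a configuration error naming the stage.
#' @return A list of class \code{model_config}.
#' @export
model_config <- function(name = "MBINet",
                         input_size = c(224L, 224L, 3L),
                         channel_schedule = c(8L, 8L, 8L, 8L, 8L, 16L, 32L),
                         pool_after = c(1L, 3L, 5L, 7L),
                         pool_size = c(2L, 2L), pool_stride = 2L,
                         final_pool = c(3L, 3L), final_pool_stride = 3L,
                         q_order = 3L, n_classes = 6L,
                         dense_hidden = NULL, expect_flatten = NULL) {
  if (any(channel_schedule < 1)) stop("channel_schedule entries must be positive")
  if (q_order < 1) stop("q_order must be >= 1")
  structure(list(name = name, input_size = as.integer(input_size),
                 channel_schedule = as.integer(channel_schedule),
                 pool_after = as.integer(pool_after),
                 pool_size = as.integer(pool_size),
                 pool_stride = as.integer(pool_stride),
                 final_pool = as.integer(final_pool),
                 final_pool_stride = as.integer(final_pool_stride),
                 q_order = as.integer(q_order),
                 n_classes = as.integer(n_classes),
                 dense_hidden = dense_hidden,
                 expect_flatten = expect_flatten),
            class = "model_config")
}

#' Default MBINet configuration
#'
#' Eight-layer network: seven 3x3 same-padded operational layers with channel
#' schedule (8, 8, 8, 8, 8, 16, 32), tanh after each, 2x2 stride-2 max pools
#' after layers 1, 3, 5 and 7, a 3x3 stride-3 max pool before flattening, and
#' a dense 512 -> 6 softmax head (the "MLP layer"). On 224x224x3 input the
#' spatial trace is 224 -> 112 -> 56 -> 28 -> 14 -> 4, so the flatten holds
#' 32 x 4 x 4 = 512 features. An alternative consistent reading of the layer
#' enumeration is available as \code{preset = "enum8"} with schedule
#' (8, 8, 8, 8, 8, 16, 16, 32) (also flatten-512).
#'
#' @param input_size (height, width, channels); the flatten length scales
#'   with the input (64x64 input gives 32 features).
#' @param q_order Polynomial order, default 3.
#' @param preset "default" (7 operational layers) or "enum8" (8 operational
#'   layers).
#' @return A \code{model_config}.
#' @export
mbinet_config <- function(input_size = c(224L, 224L, 3L), q_order = 3L,
                          preset = c("default", "enum8")) {
  preset <- match.arg(preset)
  sched <- switch(preset,
                  default = c(8L, 8L, 8L, 8L, 8L, 16L, 32L),
                  enum8 = c(8L, 8L, 8L, 8L, 8L, 16L, 16L, 32L))
  expect <- if (identical(as.integer(input_size[1:2]), c(224L, 224L)))
    512L else NULL
  model_config(name = "MBINet", input_size = input_size,
               channel_schedule = sched, pool_after = c(1L, 3L, 5L, 7L),
               q_order = q_order, expect_flatten = expect)
}

trace_shapes <- function(config) {
  # spatial/channel trace; errors name the offending stage
  h <- config$input_size[1]; w <- config$input_size[2]
  trace <- list()
  for (i in seq_along(config$channel_schedule)) {
    trace[[length(trace) + 1L]] <-
      list(stage = sprintf("operational layer %d", i),
           shape = c(config$channel_schedule[i], h, w))
    if (i %in% config$pool_after) {
      h2 <- (h - config$pool_size[1]) %/% config$pool_stride + 1L
      w2 <- (w - config$pool_size[2]) %/% config$pool_stride + 1L
      if (h2 < 1 || w2 < 1)
        stop(sprintf("configuration error at max pool after layer %d: %dx%d input too small for %dx%d pool",
                     i, h, w, config$pool_size[1], config$pool_size[2]))
      h <- h2; w <- w2
      trace[[length(trace) + 1L]] <-
        list(stage = sprintf("max pool after layer %d", i),
             shape = c(config$channel_schedule[i], h, w))
    }
  }
  ch <- config$channel_schedule[length(config$channel_schedule)]
  h2 <- (h - config$final_pool[1]) %/% config$final_pool_stride + 1L
  w2 <- (w - config$final_pool[2]) %/% config$final_pool_stride + 1L
  if (h2 < 1 || w2 < 1)
    stop(sprintf("configuration error at final max pool: %dx%d input too small for %dx%d pool",
                 h, w, config$final_pool[1], config$final_pool[2]))
  flat <- ch * h2 * w2
  if (!is.null(config$expect_flatten) && flat != config$expect_flatten)
    stop(sprintf("configuration error at flatten: pooling/channel arithmetic yields %d features, declared %d",
                 flat, config$expect_flatten))
  list(trace = trace, flatten = flat, final_spatial = c(h2, w2))
}

#' Build a Self-ONN classifier from a configuration
#'
#' Instantiates the operational layers (with tanh activations and the pooling
#' schedule), the flatten stage, the optional dense hidden layer and the
#' softmax class head. Weights are drawn from the current RNG state; call
#' \code{set.seed()} first for reproducible initialization.
#'
#' @param config A [model_config()].
#' @return An object of class \code{sonn_model}.
#' @export
build_model <- function(config) {
  shapes <- trace_shapes(config)
  layers <- list()
  cin <- config$input_size[3]
  for (i in seq_along(config$channel_schedule)) {
    cout <- config$channel_schedule[i]
    layers[[length(layers) + 1L]] <-
      op_layer(cin, cout, kernel = c(3L, 3L), q_order = config$q_order)
    layers[[length(layers) + 1L]] <-
      structure(list(kind = "tanh"), class = "nn_layer")
    if (i %in% config$pool_after)
      layers[[length(layers) + 1L]] <-
        structure(list(kind = "maxpool", size = config$pool_size,
                       stride = rep(config$pool_stride, 2L)),
                  class = "nn_layer")
    cin <- cout
  }
  layers[[length(layers) + 1L]] <-
    structure(list(kind = "maxpool", size = config$final_pool,
                   stride = rep(config$final_pool_stride, 2L)),
              class = "nn_layer")
  layers[[length(layers) + 1L]] <-
    structure(list(kind = "flatten"), class = "nn_layer")
  nin <- shapes$flatten
  if (!is.null(config$dense_hidden)) {
    layers[[length(layers) + 1L]] <- dense_layer(nin, config$dense_hidden,
                                                 activation = "tanh")
    nin <- as.integer(config$dense_hidden)
  }
  layers[[length(layers) + 1L]] <- dense_layer(nin, config$n_classes)
  layers[[length(layers) + 1L]] <-
    structure(list(kind = "softmax"), class = "nn_layer")
  structure(list(name = config$name, config = config,
                 input_size = config$input_size,
                 n_classes = config$n_classes,
                 flatten_length = shapes$flatten,
                 layers = layers),
            class = "sonn_model")
}

dense_layer <- function(n_in, n_out, activation = "none") {
  lim <- sqrt(1 / n_in)
  structure(list(kind = "dense",
                 W = matrix(runif(n_out * n_in, -lim, lim), n_out, n_in),
                 b = runif(n_out, -lim, lim), activation = activation),
            class = "nn_layer")
}

#' Build MBINet
#'
#' @param config Optional [model_config()]; defaults to [mbinet_config()].
#' @return A \code{sonn_model}.
#' @export
build_mbinet <- function(config = mbinet_config()) build_model(config)

#' Build a named model variant
#'
#' The model zoo covers MBINet, the shallower Self-ONN variants with 4 or 6
#' operational layers ("1DN" adds one extra dense hidden layer before the
#' class head), and the vanilla CNN counterparts, which are the same graphs
#' with the polynomial order forced to 1 (a plain convolution). Channel
#' schedules for the shallower variants reuse MBINet's schedule truncated to
#' the stated depth with a widened final stage.
#'
#' @param name One of "MBINet", "Self-ONN4L", "Self-ONN4L1DN", "Self-ONN6L",
#'   "Self-ONN6L1DN", "VanillaCNN6L", "VanillaCNN8L".
#' @param q_order Polynomial order; defaults to 3 for Self-ONN models and is
#'   forced to 1 for the vanilla variants.
#' @param input_size (height, width, channels).
#' @param dense_hidden Width of the "1DN" hidden layer (default 64).
#' @return A \code{sonn_model}.
#' @export
build_variant <- function(name, q_order = 3L,
                          input_size = c(224L, 224L, 3L),
                          dense_hidden = 64L) {
  zoo <- list(
    "MBINet"        = list(sched = c(8L,8L,8L,8L,8L,16L,32L), pools = c(1L,3L,5L,7L), q = q_order, dn = NULL),
    "Self-ONN4L"    = list(sched = c(8L,8L,8L,16L),           pools = c(1L,3L),     q = q_order, dn = NULL),
    "Self-ONN4L1DN" = list(sched = c(8L,8L,8L,16L),           pools = c(1L,3L),     q = q_order, dn = dense_hidden),
    "Self-ONN6L"    = list(sched = c(8L,8L,8L,8L,8L,16L),     pools = c(1L,3L,5L),  q = q_order, dn = NULL),
    "Self-ONN6L1DN" = list(sched = c(8L,8L,8L,8L,8L,16L),     pools = c(1L,3L,5L),  q = q_order, dn = dense_hidden),
    "VanillaCNN6L"  = list(sched = c(8L,8L,8L,8L,8L,16L),     pools = c(1L,3L,5L),  q = 1L,      dn = NULL),
    "VanillaCNN8L"  = list(sched = c(8L,8L,8L,8L,8L,16L,32L), pools = c(1L,3L,5L,7L), q = 1L,    dn = NULL))
  if (!name %in% names(zoo))
    stop(sprintf("unknown model '%s'; available: %s", name,
                 paste(names(zoo), collapse = ", ")))
  z <- zoo[[name]]
  cfg <- model_config(name = name, input_size = input_size,
                      channel_schedule = z$sched, pool_after = z$pools,
                      q_order = z$q, dense_hidden = z$dn)
  build_model(cfg)
}

#' Names of the available model variants
#' @return Character vector.
#' @export
model_zoo <- function() c("MBINet", "Self-ONN4L", "Self-ONN4L1DN",
                          "Self-ONN6L", "Self-ONN6L1DN",
                          "VanillaCNN6L", "VanillaCNN8L")

#' Count trainable parameters
#'
#' An operational layer contributes C_out * C_in * Q * kh * kw + C_out
#' scalars; a dense layer n_out * n_in + n_out. Parameter count is strictly
#' increasing in Q for a fixed topology.
#'
#' @param model A \code{sonn_model} (or a bare layer list).
#' @return Integer total.
#' @export
count_parameters <- function(model) {
  layers <- if (inherits(model, "sonn_model")) model$layers else model
  sum(vapply(layers, function(l) {
    if (l$kind %in% c("operational", "dense")) length(l$W) + length(l$b) else 0L
  }, numeric(1)))
}

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max), "-")
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

nn_forward <- function(model, xb, keep_cache = FALSE) {
  xb <- as_batch(xb)
  d <- dim(xb)
  exp_in <- model$input_size
  if (d[1] != exp_in[3] || d[2] != exp_in[1] || d[3] != exp_in[2])
    stop(sprintf("input shape (%d,%d,%d) does not match model input (%d,%d,%d)",
                 d[1], d[2], d[3], exp_in[3], exp_in[1], exp_in[2]))
  caches <- if (keep_cache) vector("list", length(model$layers)) else NULL
  x <- xb
  flatten_length <- NA_integer_
  for (j in seq_along(model$layers)) {
    l <- model$layers[[j]]
    if (l$kind == "operational") {
      pad <- (dim(l$W)[4:5] - 1L) %/% 2L
      if (keep_cache) caches[[j]] <- list(x = x, dim = dim(x))
      x <- cpp_opconv_forward(x, dim(x), l$W, l$b, l$q_order, l$shift,
                              pad[1], pad[2])
    } else if (l$kind == "tanh") {
      x <- tanh(x)
      if (keep_cache) caches[[j]] <- list(y = x)
    } else if (l$kind == "maxpool") {
      res <- cpp_maxpool_forward(x, dim(x), l$size[1], l$size[2],
                                 l$stride[1], l$stride[2])
      if (keep_cache) caches[[j]] <- list(idx = res$idx, xdim = dim(x))
      x <- res$y
    } else if (l$kind == "flatten") {
      dm <- dim(x)
      if (keep_cache) caches[[j]] <- list(xdim = dm)
      dim(x) <- c(prod(dm[1:3]), dm[4])
      flatten_length <- nrow(x)
    } else if (l$kind == "dense") {
      if (keep_cache) caches[[j]] <- list(x = x)
      x <- l$W %*% x + l$b
      if (identical(l$activation, "tanh")) {
        x <- tanh(x)
        if (keep_cache) caches[[j]]$y <- x
      }
    } else if (l$kind == "softmax") {
      x <- softmax_cols(x)
      if (keep_cache) caches[[j]] <- list(probs = x)
    }
  }
  list(probs = x, caches = caches, flatten_length = flatten_length)
}

# Backward pass from softmax + categorical cross-entropy.
# y_idx: integer class indices (1-based) per sample.
# Returns list(grads = per-layer list(dW, db) or NULL, loss = scalar).
nn_backward <- function(model, fw, y_idx) {
  probs <- fw$probs
  n <- ncol(probs)
  loss <- -mean(log(pmax(probs[cbind(y_idx, seq_len(n))], 1e-12)))
  g <- probs
  g[cbind(y_idx, seq_len(n))] <- g[cbind(y_idx, seq_len(n))] - 1
  g <- g / n
  grads <- vector("list", length(model$layers))
  for (j in rev(seq_along(model$layers))) {
    l <- model$layers[[j]]
    cc <- fw$caches[[j]]
    if (l$kind == "softmax") {
      # combined with cross-entropy above
    } else if (l$kind == "dense") {
      if (identical(l$activation, "tanh")) g <- g * (1 - cc$y^2)
      grads[[j]] <- list(dW = g %*% t(cc$x), db = rowSums(g))
      g <- t(l$W) %*% g
    } else if (l$kind == "flatten") {
      dim(g) <- cc$xdim
    } else if (l$kind == "maxpool") {
      g <- cpp_maxpool_backward(g, cc$idx, cc$xdim)
    } else if (l$kind == "tanh") {
      g <- g * (1 - cc$y^2)
    } else if (l$kind == "operational") {
      pad <- (dim(l$W)[4:5] - 1L) %/% 2L
      bk <- cpp_opconv_backward(cc$x, cc$dim, l$W, g, l$q_order, l$shift,
                                pad[1], pad[2])
      grads[[j]] <- list(dW = bk$dW, db = bk$db)
      g <- bk$dx
    }
  }
  list(grads = grads, loss = loss)
}

#' Forward pass: class probabilities for a batch
#'
#' @param model A \code{sonn_model}.
#' @param batch A (C,H,W) feature map or (C,H,W,N) batch matching the model's
#'   input size (channels first).
#' @return N x n_classes matrix of probabilities; each row sums to 1.
#' @export
forward <- function(model, batch) {
  p <- nn_forward(model, batch)$probs
  m <- t(p)
  colnames(m) <- if (model$n_classes == 6L) CLASS_LABELS else NULL
  m
}

#' Convert H x W x 3 images to a channels-first batch
#'
#' @param imgs A list of H x W x 3 arrays (or a single one).
#' @return Array (3, H, W, N).
#' @export
images_to_batch <- function(imgs) {
  if (!is.list(imgs)) imgs <- list(imgs)
  d <- dim(imgs[[1]])
  out <- array(0, c(d[3], d[1], d[2], length(imgs)))
  for (i in seq_along(imgs)) out[, , , i] <- aperm(imgs[[i]], c(3, 1, 2))
  out
}

#' @export
print.sonn_model <- function(x, ...) {
  cat(sprintf("%s: Self-ONN classifier (Q = %d)\n", x$name, x$config$q_order))
  cat(sprintf("  input %dx%dx%d, %d classes, flatten length %d\n",
              x$input_size[1], x$input_size[2], x$input_size[3],
              x$n_classes, x$flatten_length))
  nop <- sum(vapply(x$layers, function(l) l$kind == "operational", logical(1)))
  nde <- sum(vapply(x$layers, function(l) l$kind == "dense", logical(1)))
  cat(sprintf("  %d operational layers, %d dense layers, %d trainable parameters\n",
              nop, nde, count_parameters(x)))
  invisible(x)
}

#' @export
summary.sonn_model <- function(object, ...) {
  rows <- lapply(object$layers, function(l) {
    if (l$kind == "operational")
      data.frame(kind = "operational",
                 detail = sprintf("%d->%d ch, %dx%d, Q=%d", dim(l$W)[2],
                                  dim(l$W)[1], dim(l$W)[4], dim(l$W)[5],
                                  l$q_order),
                 params = length(l$W) + length(l$b))
    else if (l$kind == "dense")
      data.frame(kind = "dense",
                 detail = sprintf("%d->%d%s", ncol(l$W), nrow(l$W),
                                  if (identical(l$activation, "tanh")) " (tanh)" else ""),
                 params = length(l$W) + length(l$b))
    else if (l$kind == "maxpool")
      data.frame(kind = "maxpool",
                 detail = sprintf("%dx%d stride %d", l$size[1], l$size[2],
                                  l$stride[1]),
                 params = 0L)
    else data.frame(kind = l$kind, detail = "", params = 0L)
  })
  tab <- do.call(rbind, rows)
  structure(list(name = object$name, table = tab,
                 total = count_parameters(object)),
            class = "summary.sonn_model")
}

#' @export
print.summary.sonn_model <- function(x, ...) {
  cat(sprintf("%s layer stack:\n", x$name))
  print(x$table, row.names = FALSE)
  cat(sprintf("total trainable parameters: %d\n", x$total))
  invisible(x)
}

#' Predict classes or probabilities for images
#'
#' @param object A \code{sonn_model}.
#' @param newdata A list of H x W x 3 arrays, a single such array, or a
#'   channels-first (C,H,W,N) batch.
#' @param type "class" for predicted labels, "prob" for the probability
#'   matrix.
#' @param ... Unused.
#' @return Factor of predicted labels, or an N x 6 probability matrix.
#' @export
predict.sonn_model <- function(object, newdata, type = c("class", "prob"),
                               ...) {
  type <- match.arg(type)
  xb <- if (is.list(newdata) ||
            (length(dim(newdata)) == 3L && dim(newdata)[3] == 3L &&
             dim(newdata)[1] != object$input_size[3]))
    images_to_batch(newdata) else as_batch(newdata)
  p <- forward(object, xb)
  if (type == "prob") return(p)
  factor(CLASS_LABELS[max.col(p)], levels = CLASS_LABELS)
}
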