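#' @useDynLib mbinet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm sd predict
NULL

CLASS_LABELS <- c("NT", "BT", "MT", "BBT", "MMT", "BMT")

#' Class labels of the six-way tumor classification problem
#'
#' Fixed ordinal order: non-tumor (NT), single benign (BT), single malignant
#' (MT), double benign (BBT), double malignant (MMT), one benign plus one
#' malignant (BMT). This order indexes every confusion-matrix axis and score
#' column in the package.
#'
#' @return Character vector of length 6.
#' @export
class_labels <- function() CLASS_LABELS

as_batch <- function(x) {
  # promote a single (C,H,W) feature map to a (C,H,W,1) batch
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(3L, 4L)))
    stop("expected a (C,H,W) feature map or (C,H,W,N) batch")
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  x
}

#' Element-wise power expansion of a feature map
#'
#' Stacks the powers \eqn{(x - a)^q}, \eqn{q = 1..Q}, of a feature map into a
#' rank-4 array. This is the expansion that turns a Q-order operational
#' convolution into a plain convolution over Q times as many input channels:
#' the polynomial nodal operator applied to an activation y is
#' \eqn{\sum_q w_q (y - a)^q}.
#'
#' @param x Numeric array (C,H,W), all values finite.
#' @param q_order Integer Q >= 1, polynomial order.
#' @param shift Scalar expansion point a (0 under tanh activations).
#' @return Array of dim (Q, C, H, W); slice q is \code{(x - shift)^q}.
#' @export
raise_to_powers <- function(x, q_order, shift = 0) {
  if (!is.numeric(q_order) || length(q_order) != 1L || q_order < 1)
    stop("q_order must be an integer >= 1")
  if (!all(is.finite(x))) stop("input contains non-finite values")
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  out <- matrix(0, q_order, prod(d))
  xs <- as.numeric(x - shift)
  p <- rep(1, prod(d))
  for (q in seq_len(q_order)) {
    p <- p * xs
    out[q, ] <- p
  }
  array(out, c(q_order, d))
}

#' Polynomial nodal operator of a generative neuron
#'
#' Evaluates \eqn{\Psi(w, y) = \sum_{q=1}^{Q} w_q (y - a)^q}. The constant
#' term of the Taylor expansion is not part of the per-connection operator;
#' it is absorbed into the layer bias (a per-connection constant is
#' unidentifiable next to the bias).
#'
#' @param y Numeric scalar (or array, applied element-wise).
#' @param coeffs Numeric vector (w_1, ..., w_Q).
#' @param shift Scalar expansion point a.
#' @return \code{sum_q coeffs[q] * (y - shift)^q}, same shape as \code{y}.
#' @export
nodal_transform <- function(y, coeffs, shift = 0) {
  if (length(coeffs) < 1L) stop("empty coefficient vector")
  ys <- y - shift
  # Horner on the factored form: sum_q w_q t^q = t*(w_1 + t*(w_2 + ...))
  acc <- 0
  for (q in rev(seq_along(coeffs))) acc <- coeffs[q] + acc * ys
  acc * ys
}

#' Hyperbolic-tangent activation
#'
#' Element-wise tanh; the range bound \eqn{[-1, 1]} is what pins the Taylor
#' expansion point of the following operational layer to a = 0.
#'
#' @param x Numeric array, finite.
#' @return tanh(x), same shape.
#' @export
tanh_activate <- function(x) {
  if (!all(is.finite(x))) stop("input contains non-finite values")
  tanh(x)
}

#' Create an operational (Self-ONN) convolution layer
#'
#' Holds the rank-5 weight bank (C_out, C_in, Q, kh, kw), the per-channel
#' bias, the polynomial order Q and the expansion shift a. With Q = 1 the
#' layer is numerically a standard convolution layer. Initialization is
#' symmetric uniform with fan-in scaling (fan_in = C_in * kh * kw) applied
#' independently to each q-slice, so the Q = 1 initialization matches a
#' standard convolution's.
#'
#' @param in_channels,out_channels Integer channel counts.
#' @param kernel Integer (kh, kw) pair; default 3x3.
#' @param q_order Polynomial order Q >= 1.
#' @param shift Expansion point a; 0 under tanh.
#' @return A list of class \code{op_layer}.
#' @export
op_layer <- function(in_channels, out_channels, kernel = c(3L, 3L),
                     q_order = 3L, shift = 0) {
  if (q_order < 1) stop("q_order must be >= 1")
  kernel <- rep(as.integer(kernel), length.out = 2L)
  fan_in <- in_channels * prod(kernel)
  lim <- sqrt(1 / fan_in)
  W <- array(runif(out_channels * in_channels * q_order * prod(kernel),
                   -lim, lim),
             dim = c(out_channels, in_channels, q_order, kernel))
  b <- runif(out_channels, -lim, lim)
  structure(list(kind = "operational", W = W, b = b,
                 q_order = as.integer(q_order), shift = shift,
                 kernel = kernel),
            class = c("op_layer", "nn_layer"))
}

#' Q-order operational convolution
#'
#' Output channel k is \code{bias_k} plus the sum over input channels and
#' polynomial orders q of the cross-correlation of \eqn{(x - a)^q} with the
#' weight slice (k, ., q, ., .). Orientation is cross-correlation (no kernel
#' flip). Padding is zero same-padding by default so operational layers
#' preserve spatial size (required for the 224 -> 112 -> 56 -> 28 -> 14 -> 4
#' pooling trace that yields the 512-feature flatten).
#'
#' @param x Feature map (C_in, H, W) or batch (C_in, H, W, N).
#' @param layer An \code{op_layer}.
#' @param padding "same" (default) or an integer pad width.
#' @return Feature map/batch with C_out channels, same spatial size under
#'   same-padding.
#' @export
operational_conv2d <- function(x, layer, padding = "same") {
  xb <- as_batch(x)
  d <- dim(xb)
  wd <- dim(layer$W)
  if (d[1] != wd[2])
    stop(sprintf("input has %d channels but layer expects %d", d[1], wd[2]))
  if (wd[3] != layer$q_order)
    stop("weight Q dimension does not match layer q_order")
  pad <- if (identical(padding, "same")) (wd[4:5] - 1L) %/% 2L
         else rep(as.integer(padding), length.out = 2L)
  y <- cpp_opconv_forward(xb, dim(xb), layer$W, layer$b,
                          layer$q_order, layer$shift, pad[1], pad[2])
  if (length(dim(x)) == 3L) dim(y) <- dim(y)[1:3]
  y
}

#' Save model parameters to a JSON checkpoint
#'
#' The checkpoint stores, per layer and in layer order, the flattened weight
#' array with its dimensions, the bias, Q and the shift a, plus the model
#' configuration, so that save -> load reproduces the forward pass exactly.
#'
#' @param model A \code{sonn_model}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  layers <- lapply(model$layers, function(l) {
    out <- list(kind = l$kind)
    if (l$kind == "operational") {
      out$W <- as.numeric(l$W); out$Wdim <- dim(l$W)
      out$b <- as.numeric(l$b)
      out$q_order <- l$q_order; out$shift <- l$shift
    } else if (l$kind == "dense") {
      out$W <- as.numeric(l$W); out$Wdim <- dim(l$W)
      out$b <- as.numeric(l$b); out$activation <- l$activation
    } else if (l$kind == "maxpool") {
      out$size <- l$size; out$stride <- l$stride
    }
    out
  })
  obj <- list(format = "mbinet-checkpoint-1", name = model$name,
              input_size = model$input_size, n_classes = model$n_classes,
              layers = layers)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model from a JSON checkpoint
#'
#' @param path Checkpoint file written by [save_checkpoint()].
#' @return A \code{sonn_model} whose forward pass is identical to the saved
#'   model's.
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "mbinet-checkpoint-1"))
    stop("not an mbinet checkpoint")
  num <- function(v) vapply(v, as.numeric, numeric(1))
  layers <- lapply(obj$layers, function(l) {
    for (f in c("W", "Wdim", "b", "size", "stride"))
      if (!is.null(l[[f]])) l[[f]] <- num(l[[f]])
    if (l$kind == "operational") {
      structure(list(kind = "operational",
                     W = array(l$W, dim = l$Wdim), b = l$b,
                     q_order = as.integer(l$q_order), shift = l$shift,
                     kernel = as.integer(l$Wdim[4:5])),
                class = c("op_layer", "nn_layer"))
    } else if (l$kind == "dense") {
      structure(list(kind = "dense", W = matrix(l$W, l$Wdim[1], l$Wdim[2]),
                     b = l$b, activation = l$activation),
                class = "nn_layer")
    } else if (l$kind == "maxpool") {
      structure(list(kind = "maxpool", size = as.integer(l$size),
                     stride = as.integer(l$stride)), class = "nn_layer")
    } else {
      structure(list(kind = l$kind), class = "nn_layer")
    }
  })
  structure(list(name = obj$name, input_size = as.integer(obj$input_size),
                 n_classes = as.integer(obj$n_classes), layers = layers),
            class = "sonn_model")
}
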