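# Generative-neuron math: power expansion, polynomial nodal operator,
# operational convolution, gradients, and checkpoint round-trips.

test_that("raise_to_powers stacks (x - a)^q with slice 1 equal to x - a", {
  x <- array(c(0.5, -0.3, 0.2, 0.9), c(1, 2, 2))
  p <- raise_to_powers(x, 3)
  expect_equal(dim(p), c(3, 1, 2, 2))
  expect_equal(p[1, , , ], x[1, , ])
  expect_equal(p[2, , , ], x[1, , ]^2)
  expect_equal(p[3, , , ], x[1, , ]^3)
  # identity and zero cases
  expect_equal(raise_to_powers(x, 1)[1, , , ], x[1, , ])
  expect_true(all(raise_to_powers(array(0, c(1, 2, 2)), 3) == 0))
  # shifted expansion point
  ps <- raise_to_powers(x, 2, shift = 0.1)
  expect_equal(ps[2, , , ], (x[1, , ] - 0.1)^2)
  expect_error(raise_to_powers(x, 0), "q_order")
  expect_error(raise_to_powers(array(NA_real_, c(1, 1, 1)), 2), "finite")
})

test_that("nodal_transform matches direct polynomial evaluation", {
  expect_equal(nodal_transform(0.73, 1), 0.73) # Q=1 identity
  expect_equal(nodal_transform(5, c(0, 0, 0)), 0)
  w <- c(1, -1, 2)
  expect_equal(nodal_transform(0.5, w), oracle_poly(0.5, w),
               tolerance = 1e-12)
  set.seed(4)
  for (i in 1:25) {
    q <- sample(1:6, 1)
    w <- rnorm(q); y <- rnorm(1); a <- rnorm(1, sd = 0.3)
    expect_equal(nodal_transform(y, w, a), oracle_poly(y, w, a),
                 tolerance = 1e-10)
  }
  expect_error(nodal_transform(1, numeric(0)), "empty")
})

test_that("tanh activation is bounded and matches the reference evaluation", {
  x <- array(c(-50, -0.5, 0, 0.5, 50, 3), c(2, 3, 1))
  y <- tanh_activate(x)
  expect_true(all(y >= -1 & y <= 1))
  expect_equal(y[2, 1, 1], tanh(-0.5))
  expect_equal(tanh_activate(array(0, c(1, 2, 2))),
               array(0, c(1, 2, 2)))
  expect_error(tanh_activate(array(Inf, c(1, 1, 1))), "finite")
})

test_that("operational convolution reduces to the scalar nodal operator on 1x1 configs", {
  set.seed(11)
  for (i in 1:10) {
    q <- sample(1:4, 1)
    l <- random_op_layer(1, 1, q, kernel = c(1L, 1L))
    y0 <- rnorm(1)
    out <- operational_conv2d(array(y0, c(1, 1, 1)), l)
    expect_equal(out[1, 1, 1],
                 l$b + oracle_poly(y0, as.numeric(l$W[1, 1, , 1, 1])),
                 tolerance = 1e-10)
  }
})

test_that("identity kernel and zero input behave as expected", {
  # centered delta kernel with Q=1 reproduces the input under same-padding
  l <- op_layer(1, 1, q_order = 1)
  l$W[] <- 0; l$W[1, 1, 1, 2, 2] <- 1; l$b <- 0
  x <- array(rnorm(25), c(1, 5, 5))
  expect_equal(operational_conv2d(x, l), x)
  # zero input: every output pixel equals its channel bias
  l2 <- random_op_layer(2, 3, 3)
  out <- operational_conv2d(array(0, c(2, 4, 4)), l2)
  for (k in 1:3) expect_true(all(out[k, , ] == l2$b[k]))
})

test_that("Q=1 operational convolution equals a plain convolution (100 random cases)", {
  set.seed(21)
  worst <- 0
  for (i in 1:100) {
    cin <- sample(1:3, 1); cout <- sample(1:3, 1)
    h <- sample(3:6, 1); w <- sample(3:6, 1)
    l <- random_op_layer(cin, cout, 1)
    x <- array(rnorm(cin * h * w), c(cin, h, w))
    worst <- max(worst, max(abs(operational_conv2d(x, l) -
                                  oracle_conv2d(x, l$W, l$b))))
  }
  expect_lt(worst, 1e-6)
})

test_that("layer errors on channel and Q mismatches", {
  l <- op_layer(2, 3, q_order = 3)
  expect_error(operational_conv2d(array(0, c(3, 4, 4)), l), "channels")
  l$q_order <- 2L
  expect_error(operational_conv2d(array(0, c(2, 4, 4)), l), "q_order")
})

test_that("linear-only layer is homogeneous: doubling input doubles output", {
  set.seed(31)
  l <- random_op_layer(2, 2, 3)
  l$W[, , 2:3, , ] <- 0 # kill the q >= 2 terms
  l$b[] <- 0
  x <- array(rnorm(2 * 5 * 5), c(2, 5, 5))
  expect_equal(operational_conv2d(2 * x, l), 2 * operational_conv2d(x, l),
               tolerance = 1e-10)
})

test_that("backward pass matches central finite differences on a 4x4 Q=3 layer", {
  set.seed(41)
  l <- random_op_layer(2, 2, 3)
  x <- array(rnorm(2 * 4 * 4, sd = 0.5), c(2, 4, 4, 1))
  R <- array(rnorm(2 * 4 * 4), c(2, 4, 4, 1)) # random projection = scalar loss
  loss <- function(W, b) sum(mbinet:::cpp_opconv_forward(
    x, dim(x), W, b, 3L, 0, 1L, 1L) * R)
  bk <- mbinet:::cpp_opconv_backward(x, dim(x), l$W, R, 3L, 0, 1L, 1L)
  eps <- 1e-5
  # every weight and bias entry receives a gradient, checked exhaustively
  max_rel <- 0
  for (i in seq_along(l$W)) {
    Wp <- l$W; Wm <- l$W; Wp[i] <- Wp[i] + eps; Wm[i] <- Wm[i] - eps
    fd <- (loss(Wp, l$b) - loss(Wm, l$b)) / (2 * eps)
    max_rel <- max(max_rel, abs(fd - bk$dW[i]) / max(abs(fd), 1e-6))
  }
  for (i in seq_along(l$b)) {
    bp <- l$b; bm <- l$b; bp[i] <- bp[i] + eps; bm[i] <- bm[i] - eps
    fd <- (loss(l$W, bp) - loss(l$W, bm)) / (2 * eps)
    max_rel <- max(max_rel, abs(fd - bk$db[i]) / max(abs(fd), 1e-6))
  }
  expect_lt(max_rel, 1e-3)
  # input gradients too (needed to train stacked layers)
  max_rel_x <- 0
  for (i in sample(seq_along(x), 12)) {
    xp <- x; xm <- x; xp[i] <- xp[i] + eps; xm[i] <- xm[i] - eps
    fd <- (sum(mbinet:::cpp_opconv_forward(xp, dim(x), l$W, l$b, 3L, 0, 1L, 1L) * R) -
           sum(mbinet:::cpp_opconv_forward(xm, dim(x), l$W, l$b, 3L, 0, 1L, 1L) * R)) /
      (2 * eps)
    max_rel_x <- max(max_rel_x, abs(fd - bk$dx[i]) / max(abs(fd), 1e-6))
  }
  expect_lt(max_rel_x, 1e-3)
})

test_that("whole-model gradients agree with finite differences through pooling and the head", {
  set.seed(51)
  model <- tiny_dense_model()
  x <- array(rnorm(64, sd = 0.5), c(1, 8, 8, 2))
  y <- c(1L, 3L)
  fw <- mbinet:::nn_forward(model, x, keep_cache = TRUE)
  bk <- mbinet:::nn_backward(model, fw, y)
  lossfun <- function(m) {
    p <- mbinet:::nn_forward(m, x)$probs
    -mean(log(p[cbind(y, 1:2)]))
  }
  eps <- 1e-5; max_rel <- 0
  for (j in seq_along(model$layers)) {
    if (is.null(bk$grads[[j]])) next
    for (i in sample(seq_along(model$layers[[j]]$W),
                     min(8, length(model$layers[[j]]$W)))) {
      mp <- model; mm <- model
      mp$layers[[j]]$W[i] <- mp$layers[[j]]$W[i] + eps
      mm$layers[[j]]$W[i] <- mm$layers[[j]]$W[i] - eps
      fd <- (lossfun(mp) - lossfun(mm)) / (2 * eps)
      max_rel <- max(max_rel, abs(fd - bk$grads[[j]]$dW[i]) / max(abs(fd), 1e-4))
    }
  }
  expect_lt(max_rel, 1e-3)
})

test_that("checkpoints round-trip to an identical forward pass", {
  set.seed(61)
  model <- build_variant("Self-ONN4L1DN", input_size = c(16L, 16L, 3L))
  x <- array(rnorm(3 * 16 * 16, sd = 0.3), c(3, 16, 16, 2))
  p1 <- forward(model, x)
  path <- tempfile(fileext = ".json")
  save_checkpoint(model, path)
  m2 <- load_checkpoint(path)
  expect_equal(forward(m2, x), p1, tolerance = 1e-12)
  expect_equal(count_parameters(m2), count_parameters(model))
  unlink(path)
})
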