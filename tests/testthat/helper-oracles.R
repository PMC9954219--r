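# Independent oracles used across the suite. These deliberately take the
# slow, direct route (explicit loops, per-sample tallies) so they share no
# code with the implementation they check.

# direct polynomial evaluation: sum_q w_q * (y - a)^q via explicit powers
oracle_poly <- function(y, w, a = 0) {
  s <- 0
  for (q in seq_along(w)) s <- s + w[q] * (y - a)^q
  s
}

# plain same-padded cross-correlation of a (C,H,W) map, explicit loops
oracle_conv2d <- function(x, W, b) {
  d <- dim(x); Cout <- dim(W)[1]; k <- dim(W)[4:5]; p <- (k - 1) %/% 2
  xp <- array(0, c(d[1], d[2] + 2 * p[1], d[3] + 2 * p[2]))
  xp[, p[1] + seq_len(d[2]), p[2] + seq_len(d[3])] <- x
  out <- array(0, c(Cout, d[2], d[3]))
  for (kk in seq_len(Cout)) for (h in seq_len(d[2])) for (w2 in seq_len(d[3])) {
    s <- b[kk]
    for (i in seq_len(d[1])) for (r in seq_len(k[1])) for (cc in seq_len(k[2]))
      s <- s + W[kk, i, 1, r, cc] * xp[i, h + r - 1, w2 + cc - 1]
    out[kk, h, w2] <- s
  }
  out
}

# per-sample tally of one-vs-rest metrics from expanded label pairs
oracle_metrics <- function(cm) {
  labels <- rownames(cm)
  # expand cm[i,j] = count(true=i, pred=j) into per-sample label pairs
  true <- unlist(lapply(labels, function(tl)
    rep(tl, sum(cm[tl, ]))), use.names = FALSE)
  pred <- unlist(lapply(labels, function(tl)
    rep(labels, cm[tl, ])), use.names = FALSE)
  res <- list()
  for (cl in labels) {
    tp <- sum(true == cl & pred == cl)
    fn <- sum(true == cl & pred != cl)
    fp <- sum(true != cl & pred == cl)
    tn <- sum(true != cl & pred != cl)
    res[[cl]] <- c(accuracy = (tp + tn) / length(true),
                   recall = tp / (tp + fn),
                   specificity = tn / (fp + tn),
                   precision = if (tp + fp > 0) tp / (tp + fp) else 0,
                   f1 = 2 * tp / (2 * tp + fn + fp))
  }
  res
}

# trapezoidal-rule AUC from an explicit threshold sweep
oracle_auc <- function(scores, truth) {
  ths <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0); fpr <- c(0)
  for (t in ths) {
    pred <- scores >= t
    tpr <- c(tpr, sum(pred & truth) / sum(truth))
    fpr <- c(fpr, sum(pred & !truth) / sum(!truth))
  }
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

# center-aligned bilinear interpolation with edge clamping, explicit loops
oracle_bilinear <- function(src, n) {
  m <- nrow(src)
  out <- matrix(0, n, n)
  gv <- function(r, c) src[min(max(r, 0), m - 1) + 1, min(max(c, 0), m - 1) + 1]
  for (i in 0:(n - 1)) for (j in 0:(n - 1)) {
    y <- (i + 0.5) * m / n - 0.5; x <- (j + 0.5) * m / n - 0.5
    y0 <- floor(y); x0 <- floor(x); fy <- y - y0; fx <- x - x0
    out[i + 1, j + 1] <- (1 - fy) * (1 - fx) * gv(y0, x0) +
      (1 - fy) * fx * gv(y0, x0 + 1) + fy * (1 - fx) * gv(y0 + 1, x0) +
      fy * fx * gv(y0 + 1, x0 + 1)
  }
  out
}

random_op_layer <- function(cin, cout, q, kernel = c(3L, 3L)) {
  l <- op_layer(cin, cout, kernel = kernel, q_order = q)
  l$W[] <- rnorm(length(l$W))
  l$b <- rnorm(length(l$b))
  l
}

tiny_dense_model <- function(input_size = 8L, n_classes = 3L) {
  # minimal trainable model for fast training-loop tests
  cfg <- model_config(name = "tiny", input_size = c(input_size, input_size, 1L),
                      channel_schedule = c(4L), pool_after = c(1L),
                      final_pool = c(2L, 2L), final_pool_stride = 2L,
                      q_order = 2L, n_classes = n_classes)
  build_model(cfg)
}
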