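# Image loading, preprocessing, the deterministic augmentation menu, and the
# stratified fold planner. Images are H x W x 3 arrays with intensities in
# [0, 1]; geometric transforms are delegated to EBImage (width-first arrays,
# hence the transposes in to_ebi/from_ebi).

to_ebi <- function(img) EBImage::Image(aperm(img, c(2, 1, 3)),
                                       colormode = "Color")
from_ebi <- function(ebi) aperm(as.array(ebi), c(2, 1, 3))

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Resize an image to a target size
#'
#' Bilinear interpolation; output values are clipped to the unit interval.
#'
#' @param img H x W x 3 array in \[0, 1\].
#' @param size Target (height, width); default c(224, 224).
#' @return Array of dim (size, 3).
#' @export
resize_image <- function(img, size = c(224L, 224L)) {
  d <- dim(img)
  if (is.null(d) || any(d[1:2] < 1)) stop("invalid input image")
  if (length(d) == 2L) img <- array(rep(img, 3), c(d, 3L))
  if (identical(as.integer(dim(img)[1:2]), as.integer(size))) return(img)
  out <- from_ebi(EBImage::resize(to_ebi(img), w = size[2], h = size[1]))
  pmin(pmax(out, 0), 1)
}

#' Per-channel z-score normalization
#'
#' Channel c of the output is \code{(pixel - mean[c]) / std[c]}.
#'
#' @param img H x W x 3 array.
#' @param stats List with numeric 3-vectors \code{mean} and \code{std}
#'   (std strictly positive); default [rmb_norm_stats()].
#' @return Normalized array, same shape (no longer bounded to \[0, 1\]).
#' @export
zscore_normalize <- function(img, stats = rmb_norm_stats()) {
  if (any(stats$std <= 0)) stop("std must be strictly positive")
  out <- img
  for (c in 1:3) out[, , c] <- (img[, , c] - stats$mean[c]) / stats$std[c]
  out
}

#' Channel mean/std used for z-score normalization of RMB images
#'
#' Per-channel statistics applied in storage order (R, G, B).
#'
#' @return List with \code{mean} and \code{std} 3-vectors.
#' @export
rmb_norm_stats <- function() list(mean = c(0.2552, 0.4666, 0.8804),
                                  std = c(0.4116, 0.3645, 0.2597))

#' The default deterministic 10-transform augmentation menu
#'
#' Rotations of 30 and 10 degrees in both directions (positive = clockwise),
#' magnifications of 10% and 12%, translations of (10%, 10%), (8%, 12%) and
#' (-10%, -10%) of the image size, and a vertical flip: exactly 10
#' transforms, so a training set expands tenfold (1,320 originals become
#' 13,200).
#'
#' @return List of 10 transform descriptors (class
#'   \code{augmentation_policy}).
#' @export
default_augmentation_menu <- function() {
  structure(list(
    list(kind = "rotate", angle = 30),
    list(kind = "rotate", angle = -30),
    list(kind = "rotate", angle = 10),
    list(kind = "rotate", angle = -10),
    list(kind = "scale", factor = 1.10),
    list(kind = "scale", factor = 1.12),
    list(kind = "translate", dx = 10, dy = 10),
    list(kind = "translate", dx = 8, dy = 12),
    list(kind = "translate", dx = -10, dy = -10),
    list(kind = "vflip")
  ), class = "augmentation_policy")
}

validate_policy <- function(policy) {
  for (tr in policy) {
    ok <- switch(tr$kind,
      rotate = abs(tr$angle) >= 10 && abs(tr$angle) <= 40,
      scale = tr$factor >= 1.10 && tr$factor <= 1.12,
      translate = all(abs(c(tr$dx, tr$dy)) >= 8) &&
                  all(abs(c(tr$dx, tr$dy)) <= 15),
      vflip = TRUE,
      FALSE)
    if (!ok) stop(sprintf("transform '%s' outside the allowed parameter range",
                          tr$kind))
  }
  invisible(TRUE)
}

apply_transform <- function(img, tr) {
  d <- dim(img)
  out <- switch(tr$kind,
    rotate = from_ebi(EBImage::rotate(to_ebi(img), tr$angle,
                                      output.dim = c(d[2], d[1]),
                                      bg.col = 0)),
    scale = {
      h2 <- round(tr$factor * d[1]); w2 <- round(tr$factor * d[2])
      big <- from_ebi(EBImage::resize(to_ebi(img), w = w2, h = h2))
      r0 <- (h2 - d[1]) %/% 2L; c0 <- (w2 - d[2]) %/% 2L
      big[r0 + seq_len(d[1]), c0 + seq_len(d[2]), , drop = FALSE]
    },
    translate = {
      v <- c(round(tr$dx / 100 * d[2]), round(tr$dy / 100 * d[1]))
      from_ebi(EBImage::translate(to_ebi(img), v = v, bg.col = 0))
    },
    vflip = from_ebi(EBImage::flip(to_ebi(img))),
    stop(sprintf("unknown transform kind '%s'", tr$kind)))
  pmin(pmax(out, 0), 1)
}

#' Apply an augmentation policy to one image
#'
#' Produces one output image per transform in the policy; exposed borders
#' (rotation, translation) are filled with the background value 0, and every
#' output has the input's size. The label of a labeled image is preserved by
#' the dataset-level wrappers.
#'
#' @param img H x W x 3 array in \[0, 1\].
#' @param policy List of transforms, e.g. [default_augmentation_menu()].
#' @return List of transformed images, \code{length(policy)} long.
#' @export
apply_augmentation <- function(img, policy = default_augmentation_menu()) {
  validate_policy(policy)
  lapply(policy, function(tr) apply_transform(img, tr))
}

#' Stratified k-fold train/validation/test plan
#'
#' Per class: a seeded shuffle, then contiguous fifths as the test split of
#' each fold (remainders distributed round-robin); of the remaining samples,
#' \code{ceiling(val_frac * n)} go to validation and the rest to training.
#' On the class counts (300, 215, 215, 200, 200, 190) this reproduces a
#' per-fold test total of 264 and validation counts (48, 35, 35, 32, 32, 31)
#' exactly. Augmentation is meant for the training split only.
#'
#' @param labels Vector (factor/character) of class labels per sample.
#' @param k Number of folds (default 5).
#' @param val_frac Validation fraction of the non-test remainder (0.2).
#' @param seed Integer seed; identical seeds give identical plans.
#' @return Object of class \code{fold_plan}: \code{k}, and per fold the
#'   disjoint index vectors \code{train}, \code{validation}, \code{test}.
#' @export
build_fold_plan <- function(labels, k = 5L, val_frac = 0.2, seed = 1L) {
  if (k < 2) stop("k must be >= 2")
  labels <- as.character(labels)
  classes <- unique(labels)
  tab <- table(labels)
  if (any(tab < k))
    stop(sprintf("stratification error: class '%s' has fewer samples than k",
                 names(tab)[which.min(tab)]))
  folds <- replicate(k, list(train = integer(0), validation = integer(0),
                             test = integer(0)), simplify = FALSE)
  with_seed(seed, {
    for (cl in classes) {
      idx <- sample(which(labels == cl))
      n <- length(idx)
      sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
      starts <- cumsum(c(0L, sizes[-k]))
      parts <- lapply(seq_len(k), function(f) idx[starts[f] + seq_len(sizes[f])])
      for (f in seq_len(k)) {
        test <- parts[[f]]
        rest <- unlist(parts[-f], use.names = FALSE)
        n_val <- ceiling(val_frac * length(rest))
        folds[[f]]$test <- c(folds[[f]]$test, test)
        folds[[f]]$validation <- c(folds[[f]]$validation, rest[seq_len(n_val)])
        folds[[f]]$train <- c(folds[[f]]$train, rest[-seq_len(n_val)])
      }
    }
  })
  structure(list(k = k, val_frac = val_frac, seed = seed, labels = labels,
                 folds = folds),
            class = "fold_plan")
}

#' Per-class split counts of a fold plan
#'
#' @param plan A [build_fold_plan()] result.
#' @param fold Fold index.
#' @return Data frame with per-class train/validation/test counts.
#' @export
fold_counts <- function(plan, fold = 1L) {
  f <- plan$folds[[fold]]
  classes <- if (all(plan$labels %in% CLASS_LABELS))
    CLASS_LABELS[CLASS_LABELS %in% plan$labels] else unique(plan$labels)
  data.frame(
    class = classes,
    train = vapply(classes, function(cl) sum(plan$labels[f$train] == cl), 0),
    validation = vapply(classes, function(cl)
      sum(plan$labels[f$validation] == cl), 0),
    test = vapply(classes, function(cl) sum(plan$labels[f$test] == cl), 0),
    row.names = NULL)
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("stratified %d-fold plan over %d samples (seed %s)\n",
              x$k, length(x$labels), format(x$seed)))
  cnt <- fold_counts(x, 1L)
  cat(sprintf("fold 1: train %d, validation %d, test %d\n",
              sum(cnt$train), sum(cnt$validation), sum(cnt$test)))
  invisible(x)
}

#' Write a fold plan as JSON
#'
#' @param plan A \code{fold_plan}.
#' @param path Output path.
#' @param ids Optional character ids; defaults to indices.
#' @export
write_fold_plan <- function(plan, path, ids = NULL) {
  if (is.null(ids)) ids <- as.character(seq_along(plan$labels))
  obj <- list(k = plan$k, seed = plan$seed,
              folds = lapply(plan$folds, function(f)
                lapply(f, function(ix) ids[ix])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' Load a class-per-folder image dataset
#'
#' Expects one subfolder per class (NT/BT/MT/BBT/MMT/BMT) containing
#' PNG/JPEG files; images are resized to \code{size}.
#'
#' @param root Dataset root directory.
#' @param size Target (height, width).
#' @param classes Class subfolders to read.
#' @return List with \code{images} (list of H x W x 3 arrays),
#'   \code{labels} (factor) and \code{ids} (relative paths).
#' @export
load_image_folder <- function(root, size = c(224L, 224L),
                              classes = class_labels()) {
  if (!dir.exists(root)) stop(sprintf("dataset root '%s' does not exist", root))
  images <- list(); labs <- character(0); ids <- character(0)
  for (cl in classes) {
    d <- file.path(root, cl)
    if (!dir.exists(d)) next
    files <- sort(list.files(d, pattern = "\\.(png|jpg|jpeg)$",
                             ignore.case = TRUE))
    for (f in files) {
      img <- as.array(EBImage::readImage(file.path(d, f)))
      if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3L))
      img <- aperm(img[, , 1:3, drop = FALSE], c(2, 1, 3))
      images[[length(images) + 1L]] <- resize_image(img, size)
      labs <- c(labs, cl); ids <- c(ids, file.path(cl, f))
    }
  }
  if (!length(images)) stop(sprintf("no images found under '%s'", root))
  list(images = images, labels = factor(labs, levels = classes), ids = ids)
}

#' Expand a set of images with the augmentation menu
#'
#' Each input contributes itself plus one image per transform (11 with the
#' default menu when \code{include_original}, or the 10 augmented copies
#' alone otherwise); labels follow the source image.
#'
#' @param images List of H x W x 3 arrays.
#' @param labels Labels parallel to \code{images}.
#' @param policy Augmentation policy.
#' @param include_original Keep the untransformed image too (default FALSE:
#'   the menu's 10 outputs per input).
#' @return List with expanded \code{images} and \code{labels}.
#' @export
augment_images <- function(images, labels,
                           policy = default_augmentation_menu(),
                           include_original = FALSE) {
  out_imgs <- list(); out_labs <- character(0)
  for (i in seq_along(images)) {
    if (include_original) {
      out_imgs[[length(out_imgs) + 1L]] <- images[[i]]
      out_labs <- c(out_labs, as.character(labels[i]))
    }
    for (a in apply_augmentation(images[[i]], policy)) {
      out_imgs[[length(out_imgs) + 1L]] <- a
      out_labs <- c(out_labs, as.character(labels[i]))
    }
  }
  lv <- if (is.factor(labels)) levels(labels) else unique(as.character(labels))
  list(images = out_imgs, labels = factor(out_labs, levels = lv))
}
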