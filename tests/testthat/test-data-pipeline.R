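# Preprocessing, the augmentation menu, and the stratified fold planner.

test_that("resize is an identity on matching sizes and preserves constants", {
  img <- array(runif(24 * 24 * 3), c(24, 24, 3))
  expect_identical(resize_image(img, c(24L, 24L)), img)
  const <- array(0.6, c(44, 44, 3))
  out <- resize_image(const, c(22L, 22L))
  expect_equal(dim(out), c(22L, 22L, 3L))
  expect_equal(out, array(0.6, c(22, 22, 3)), tolerance = 1e-6)
  expect_error(resize_image(array(0, c(0, 4, 3))), "invalid")
})

test_that("upscaling a checkerboard matches the hand-worked bilinear oracle", {
  chk <- matrix(c(0, 1, 1, 0), 2, 2)
  img <- array(rep(chk, 3), c(2, 2, 3))
  out <- resize_image(img, c(4L, 4L))
  expect_equal(out[, , 1], oracle_bilinear(chk, 4), tolerance = 1e-6)
  expect_equal(out[, , 3], oracle_bilinear(chk, 4), tolerance = 1e-6)
})

test_that("z-score normalization applies the per-channel affine map", {
  img <- array(0.5, c(4, 4, 3))
  expect_equal(zscore_normalize(img, list(mean = c(0, 0, 0),
                                          std = c(1, 1, 1))), img)
  st <- rmb_norm_stats()
  z <- zscore_normalize(array(rep(st$mean, each = 16), c(4, 4, 3)), st)
  expect_equal(z, array(0, c(4, 4, 3)), tolerance = 1e-12)
  # independent scalar computation per channel for a constant 0.5 image
  z2 <- zscore_normalize(img, st)
  for (c in 1:3)
    expect_equal(z2[1, 1, c], (0.5 - st$mean[c]) / st$std[c],
                 tolerance = 1e-12)
  expect_error(zscore_normalize(img, list(mean = c(0, 0, 0),
                                          std = c(1, 0, 1))), "positive")
})

test_that("the default menu has exactly 10 transforms within the stated ranges", {
  menu <- default_augmentation_menu()
  expect_length(menu, 10L)
  kinds <- vapply(menu, function(t) t$kind, "")
  expect_equal(sum(kinds == "rotate"), 4L)
  expect_equal(sum(kinds == "scale"), 2L)
  expect_equal(sum(kinds == "translate"), 3L)
  expect_equal(sum(kinds == "vflip"), 1L)
  for (t in menu) {
    if (t$kind == "rotate") expect_true(abs(t$angle) >= 10 && abs(t$angle) <= 40)
    if (t$kind == "scale") expect_true(t$factor >= 1.10 && t$factor <= 1.12)
  }
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  expect_length(apply_augmentation(img), 10L)
  bad <- list(list(kind = "rotate", angle = 50))
  expect_error(apply_augmentation(img, bad), "range")
})

test_that("augmentation expands a training set tenfold with labels preserved", {
  imgs <- lapply(1:3, function(i) array(runif(12 * 12 * 3), c(12, 12, 3)))
  labs <- factor(c("NT", "BT", "NT"), levels = class_labels())
  aug <- augment_images(imgs, labs)
  expect_length(aug$images, 30L)
  expect_equal(as.character(aug$labels), rep(c("NT", "BT", "NT"), each = 10))
  expect_true(all(vapply(aug$images, function(a)
    identical(dim(a), c(12L, 12L, 3L)), logical(1))))
})

test_that("vertical flip is an involution and rotation preserves a centered disk", {
  img <- array(runif(21 * 21 * 3), c(21, 21, 3))
  vf <- list(list(kind = "vflip"))
  twice <- apply_augmentation(apply_augmentation(img, vf)[[1]], vf)[[1]]
  expect_equal(twice, img, tolerance = 1e-12)
  # rotation-invariant object: centered disk survives +30 then -30
  n <- 41
  d <- sqrt(outer((1:n) - 21, rep(0, n), "+")^2 +
            outer(rep(0, n), (1:n) - 21, "+")^2)
  disk <- array(rep((d <= 12) * 0.8, 3), c(n, n, 3))
  rot <- apply_augmentation(disk, list(list(kind = "rotate", angle = 30)))[[1]]
  back <- apply_augmentation(rot, list(list(kind = "rotate", angle = -30)))[[1]]
  core <- d <= 9 # away from the interpolated rim
  expect_lt(max(abs(back[, , 1][core] - disk[, , 1][core])), 0.15)
  expect_lt(mean(abs(back[, , 1] - disk[, , 1])), 0.05)
})

test_that("translation moves a bright pixel by the rounded percentage offsets", {
  n <- 40
  img <- array(0, c(n, n, 3))
  img[10, 12, ] <- 1
  out <- apply_augmentation(img, list(list(kind = "translate",
                                           dx = 10, dy = 10)))[[1]]
  # dx shifts columns (width), dy shifts rows (height)
  expect_equal(which(out[, , 1] == 1, arr.ind = TRUE)[1, ],
               c(row = 10 + round(0.10 * n), col = 12 + round(0.10 * n)))
  out2 <- apply_augmentation(img, list(list(kind = "translate",
                                            dx = 8, dy = 12)))[[1]]
  expect_equal(which(out2[, , 1] == 1, arr.ind = TRUE)[1, ],
               c(row = 10 + round(0.12 * n), col = 12 + round(0.08 * n)))
})

test_that("fold planner reproduces the reference per-class split table", {
  labs <- rep(class_labels(), c(300, 215, 215, 200, 200, 190))
  plan <- build_fold_plan(labs, seed = 9)
  for (f in 1:5) {
    cnt <- fold_counts(plan, f)
    expect_equal(cnt$test, c(60, 43, 43, 40, 40, 38))
    expect_equal(cnt$validation, c(48, 35, 35, 32, 32, 31))
    expect_equal(sum(cnt$test), 264)
    expect_equal(sum(cnt$validation), 213)
    # disjointness and coverage within the fold
    sp <- plan$folds[[f]]
    all_idx <- c(sp$train, sp$validation, sp$test)
    expect_equal(sort(all_idx), seq_along(labs))
    expect_equal(anyDuplicated(all_idx), 0L)
  }
  # every sample is tested exactly once across folds
  test_all <- unlist(lapply(plan$folds, function(f) f$test))
  expect_equal(sort(test_all), seq_along(labs))
})

test_that("fold planner is deterministic in the seed and handles tiny classes", {
  labs <- rep(class_labels(), c(300, 215, 215, 200, 200, 190))
  p1 <- build_fold_plan(labs, seed = 5)
  p2 <- build_fold_plan(labs, seed = 5)
  expect_identical(p1$folds, p2$folds)
  p3 <- build_fold_plan(labs, seed = 6)
  expect_false(identical(p1$folds, p3$folds))
  # 5 per class, k = 5: exactly one test sample per class per fold
  tiny <- rep(class_labels(), each = 5)
  pt <- build_fold_plan(tiny, k = 5, seed = 1)
  for (f in 1:5) expect_equal(fold_counts(pt, f)$test, rep(1, 6))
  expect_error(build_fold_plan(tiny, k = 1), "k must be")
  expect_error(build_fold_plan(rep(c("NT", "BT"), c(10, 3)), k = 5),
               "stratification")
})

test_that("fold plans serialize to JSON with relative ids", {
  labs <- rep(c("NT", "BT"), each = 10)
  plan <- build_fold_plan(labs, k = 2, seed = 2)
  path <- tempfile(fileext = ".json")
  write_fold_plan(plan, path, ids = sprintf("img_%02d.png", 1:20))
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  expect_equal(obj$k, 2L)
  expect_setequal(unlist(obj$folds[[1]]), sprintf("img_%02d.png", 1:20))
  unlink(path)
})

test_that("folder datasets round-trip through PNG loading", {
  root <- file.path(tempdir(), "mini_ds")
  unlink(root, recursive = TRUE)
  for (cl in c("NT", "BT")) dir.create(file.path(root, cl), recursive = TRUE)
  set.seed(3)
  for (cl in c("NT", "BT")) for (i in 1:2)
    png::writePNG(array(runif(20 * 20 * 3), c(20, 20, 3)),
                  file.path(root, cl, sprintf("%s_%d.png", cl, i)))
  ds <- load_image_folder(root, size = c(16L, 16L))
  expect_length(ds$images, 4L)
  expect_equal(as.character(ds$labels), c("NT", "NT", "BT", "BT"))
  expect_equal(dim(ds$images[[1]]), c(16L, 16L, 3L))
  expect_error(load_image_folder(file.path(tempdir(), "nope")), "exist")
  unlink(root, recursive = TRUE)
})
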