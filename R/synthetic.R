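# Synthetic head-phantom image generator. Renders a scalar intensity field
# (background, head disk with mild texture, 0-2 high-intensity tumor blobs)
# through a heat-map-like palette into an RGB image. Benign blobs are
# near-circular ellipses; malignant blobs are radially perturbed stars whose
# measured circularity 4*pi*A/P^2 is forced below a separability cutoff, so
# the six classes are recoverable by a rule-based oracle.

#' Parameters of the synthetic phantom generator
#'
#' Sizes are fractions of the image width. The tumor radius range is floored
#' so the smallest blob stays resolvable (>= ~5 px) at small image sizes.
#' The circularity gap (benign >= 0.85, malignant <= 0.70, as measured by
#' the package's Crofton-corrected boundary estimator) makes shape classes
#' separable by construction; shrinking the gap makes the problem harder.
#'
#' @param image_size Square image side in pixels (default 224).
#' @param head_radius_frac Head disk radius range (fraction of width).
#' @param background_noise_sd Gaussian noise SD added to the intensity field.
#' @param tumor_radius_frac Tumor equivalent-radius range (fraction of
#'   width), floored at 5/image_size.
#' @param benign_circularity_min,malignant_circularity_max Circularity
#'   cutoffs enforced by rejection sampling at render time.
#' @param head_intensity,tumor_intensity Intensity ranges for head tissue
#'   and tumor blobs (background is ~0.02).
#' @return List of class \code{phantom_params}.
#' @export
phantom_params <- function(image_size = 224L,
                           head_radius_frac = c(0.38, 0.45),
                           background_noise_sd = 0.02,
                           tumor_radius_frac = c(0.04, 0.10),
                           benign_circularity_min = 0.85,
                           malignant_circularity_max = 0.70,
                           head_intensity = c(0.28, 0.34),
                           tumor_intensity = c(0.85, 1.0)) {
  if (benign_circularity_min <= malignant_circularity_max)
    stop("benign_circularity_min must exceed malignant_circularity_max")
  if (image_size < 64)
    stop("image_size below 64 px cannot reliably host two resolvable tumor blobs inside the head; use >= 64")
  floor_frac <- 5 / image_size
  tumor_radius_frac <- pmax(tumor_radius_frac, c(floor_frac, 1.8 * floor_frac))
  structure(list(image_size = as.integer(image_size),
                 head_radius_frac = head_radius_frac,
                 background_noise_sd = background_noise_sd,
                 tumor_radius_frac = tumor_radius_frac,
                 benign_circularity_min = benign_circularity_min,
                 malignant_circularity_max = malignant_circularity_max,
                 head_intensity = head_intensity,
                 tumor_intensity = tumor_intensity),
            class = "phantom_params")
}

# Chain-code perimeter with Vossepoel-Smeulders step weights (0.948 for
# axis steps, 1.340 for diagonal steps); a small digital disk then measures
# circularity ~1 while spiky stars fall well below 0.5.
mask_perimeter <- function(mask) {
  oc <- EBImage::ocontour(EBImage::Image(t(mask * 1)))
  sum(vapply(oc, function(pts) {
    n <- nrow(pts)
    if (n < 2) return(4 * 0.948) # isolated pixel
    d <- pts - pts[c(2:n, 1), , drop = FALSE]
    diag <- rowSums(abs(d)) == 2
    0.948 * sum(!diag) + 1.340 * sum(diag)
  }, 0))
}

#' Circularity of a binary mask
#'
#' \eqn{4\pi A / P^2} with a bias-corrected chain-code perimeter estimate;
#' ~1 for a digital disk, small for spiky shapes. Values slightly above 1
#' can occur for very small digitized disks.
#'
#' @param mask Logical or 0/1 matrix.
#' @return Scalar circularity.
#' @export
mask_circularity <- function(mask) {
  p <- mask_perimeter(mask)
  if (p <= 0) return(NA_real_)
  4 * pi * sum(mask) / p^2
}

# rasterize a star-shaped region given its radial boundary function r(theta)
blob_mask <- function(n, center, rfun, rmax) {
  mask <- matrix(FALSE, n, n)
  r0 <- max(1L, floor(center[1] - rmax)); r1 <- min(n, ceiling(center[1] + rmax))
  c0 <- max(1L, floor(center[2] - rmax)); c1 <- min(n, ceiling(center[2] + rmax))
  rows <- r0:r1; cols <- c0:c1
  dy <- outer(rows - center[1], rep(1, length(cols)))
  dx <- outer(rep(1, length(rows)), cols - center[2])
  rad <- sqrt(dy^2 + dx^2)
  th <- atan2(dy, dx)
  mask[rows, cols] <- rad <= rfun(th)
  mask
}

make_blob <- function(kind, n, center, r0, params) {
  # returns list(mask, circ, rmax) or NULL if the shape fails its cutoff
  if (kind == "benign") {
    ratio <- runif(1, 0.9, 1.0)
    phi <- runif(1, 0, pi)
    a <- r0 / sqrt(ratio); b <- r0 * sqrt(ratio)
    # mild boundary wobble scaled to the benign cutoff: the lower the
    # required circularity, the rougher the admissible benign boundary
    ampw <- runif(1, 0.2, 0.6) * (1 - params$benign_circularity_min)
    mw <- sample(6:9, 1); phw <- runif(1, 0, 2 * pi)
    rfun <- function(th) {
      ct <- cos(th - phi); st <- sin(th - phi)
      (1 + ampw * cos(mw * th + phw)) / sqrt((ct / a)^2 + (st / b)^2)
    }
    rmax <- a * (1 + ampw)
  } else {
    m <- sample(5:8, 1)
    amp <- runif(1, 0.22, 0.32)
    amp2 <- runif(1, 0.05, 0.12)
    ph1 <- runif(1, 0, 2 * pi); ph2 <- runif(1, 0, 2 * pi)
    rfun <- function(th) r0 * (1 + amp * cos(m * th + ph1) +
                                 amp2 * cos((m + 3) * th + ph2))
    rmax <- r0 * (1 + amp + amp2)
  }
  mask <- blob_mask(n, center, rfun, rmax)
  if (sum(mask) < 5) return(NULL)
  circ <- mask_circularity(mask)
  ok <- if (kind == "benign") circ >= params$benign_circularity_min
        else circ <= params$malignant_circularity_max
  if (!isTRUE(ok)) return(NULL)
  list(mask = mask, circ = circ, rmax = rmax,
       radius_eq = sqrt(sum(mask) / pi))
}

phantom_palette <- function(t) {
  # dark-blue background -> red/yellow tumor foci; R channel monotone in t
  r <- pmin(pmax(1.6 * t - 0.15, 0), 1)
  g <- pmin(pmax(1.8 * t - 0.65, 0), 1)
  b <- pmin(pmax(0.9 - 1.0 * t, 0.02), 1)
  list(r = r, g = g, b = b)
}

blob_kinds_for_label <- function(label) {
  switch(label,
         NT = character(0),
         BT = "benign",
         MT = "malignant",
         BBT = c("benign", "benign"),
         MMT = c("malignant", "malignant"),
         BMT = c("benign", "malignant"),
         stop(sprintf("unknown class label '%s'", label)))
}

#' Generate one labeled phantom image
#'
#' Renders a head disk with low-level texture plus the label's tumor blobs
#' (0 for NT; 1 benign for BT; 1 malignant for MT; 2 of the stated kinds for
#' BBT/MMT/BMT), placed fully inside the head with disjoint supports.
#' Deterministic given (label, params, seed).
#'
#' @param label One of the six class labels.
#' @param params A [phantom_params()].
#' @param seed Optional integer seed.
#' @return List with \code{image} (H x W x 3 RGB in \[0, 1\]),
#'   \code{intensity} (the scalar field before the palette), and
#'   \code{truth} (label plus per-blob center/equivalent radius/kind/
#'   circularity).
#' @export
generate_image <- function(label, params = phantom_params(), seed = NULL) {
  label <- match.arg(label, CLASS_LABELS)
  with_seed(seed, {
    n <- params$image_size
    ctr <- n / 2 + runif(2, -0.02 * n, 0.02 * n)
    rhead <- runif(1, params$head_radius_frac[1], params$head_radius_frac[2]) * n
    elong <- runif(1, 0.95, 1.05)
    yy <- matrix(seq_len(n), n, n) - ctr[1]
    xx <- t(matrix(seq_len(n), n, n)) - ctr[2]
    head_mask <- (yy / (rhead * elong))^2 + (xx / (rhead / elong))^2 <= 1

    t_field <- matrix(0.02, n, n)
    base <- runif(1, params$head_intensity[1], params$head_intensity[2])
    fx <- runif(2, 1, 3); phx <- runif(2, 0, 2 * pi)
    texture <- 0.02 * sin(2 * pi * fx[1] * xx / n + phx[1]) *
      cos(2 * pi * fx[2] * yy / n + phx[2])
    t_field[head_mask] <- base + texture[head_mask]

    kinds <- blob_kinds_for_label(label)
    blobs <- list()
    for (attempt in 1:20) {
      blobs <- list()
      layout_ok <- TRUE
      for (kind in kinds) {
        placed <- FALSE
        for (try in 1:200) {
        rlo <- params$tumor_radius_frac[1]; rhi <- params$tumor_radius_frac[2]
        # with two blobs, keep each towards the small end so both fit
        if (length(kinds) == 2) rhi <- rlo + 0.6 * (rhi - rlo)
        if (kind == "malignant") rlo <- rlo + 0.4 * (rhi - rlo)
        # late retries draw from the small end so crowded heads still work
        if (try > 100) rhi <- rlo + 0.2 * (rhi - rlo)
        r0 <- runif(1, rlo, rhi) * n
        rmax_guess <- r0 * (if (kind == "malignant") 1.5 else 1.1)
        ang <- runif(1, 0, 2 * pi)
        avail <- max(0, rhead * 0.92 - rmax_guess)
        # two-blob classes: bias placement outward so both supports fit
        rad <- if (length(kinds) == 2) runif(1, 0.55, 1) * avail
               else runif(1, 0, avail)
        cen <- ctr + rad * c(sin(ang), cos(ang))
        if (length(blobs)) {
          dmin <- min(vapply(blobs, function(bb)
            sqrt(sum((bb$center - cen)^2)), 0))
          if (dmin < rmax_guess + max(vapply(blobs, function(bb) bb$rmax, 0)) + 2)
            next
        }
        bl <- make_blob(kind, n, cen, r0, params)
        if (is.null(bl)) next
        bl$center <- cen; bl$kind <- kind
        blobs[[length(blobs) + 1L]] <- bl
          placed <- TRUE
          break
        }
        if (!placed) { layout_ok <- FALSE; break }
      }
      if (layout_ok) break
      if (attempt == 20)
        stop("placement error: could not fit the tumor blobs inside the head")
    }
    for (bl in blobs) {
      ti <- runif(1, params$tumor_intensity[1], params$tumor_intensity[2])
      t_field[bl$mask] <- ti
    }

    t_field <- t_field + matrix(rnorm(n * n, 0, params$background_noise_sd), n, n)
    t_field <- pmin(pmax(t_field, 0), 1)
    pal <- phantom_palette(t_field)
    img <- array(0, c(n, n, 3))
    img[, , 1] <- pal$r; img[, , 2] <- pal$g; img[, , 3] <- pal$b

    truth <- list(label = label,
                  head_center = ctr, head_radius = rhead,
                  tumors = lapply(blobs, function(bl)
                    list(center = bl$center, radius_eq = bl$radius_eq,
                         kind = bl$kind, circularity = bl$circ)))
    list(image = img, intensity = t_field, truth = truth)
  })
}

#' Generate a class-per-folder synthetic dataset
#'
#' Writes PNG files into one subfolder per class plus a
#' \code{manifest.json} of ground-truth descriptors, mirroring the folder
#' layout the loader expects. With \code{out_dir = NULL} the images are
#' returned in memory instead.
#'
#' @param n_per_class Named integer vector (names = class labels) or a
#'   single count applied to all six classes.
#' @param params A [phantom_params()].
#' @param out_dir Output directory, or NULL for an in-memory dataset.
#' @param seed Integer seed; the full dataset is reproducible from it.
#' @return For written datasets, the manifest (invisibly); otherwise a list
#'   with \code{images}, \code{labels}, \code{ids} and \code{truth}.
#' @export
generate_dataset <- function(n_per_class, params = phantom_params(),
                             out_dir = NULL, seed = 1L) {
  if (is.null(names(n_per_class))) {
    if (length(n_per_class) == 1L)
      n_per_class <- stats::setNames(rep(n_per_class, 6L), CLASS_LABELS)
    else names(n_per_class) <- CLASS_LABELS[seq_along(n_per_class)]
  }
  if (any(n_per_class < 0)) stop("counts must be >= 0")
  write_out <- !is.null(out_dir)
  if (write_out) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (cl in names(n_per_class))
      dir.create(file.path(out_dir, cl), showWarnings = FALSE)
  }
  images <- list(); labs <- character(0); ids <- character(0)
  manifest <- list()
  for (cl in names(n_per_class)) {
    for (i in seq_len(n_per_class[[cl]])) {
      # per-image seed derived so each (class, index) is independent of the
      # counts of other classes; kept well below 2^31
      sd_i <- (as.integer(seed) * 997L +
               match(cl, CLASS_LABELS) * 131071L + i * 7L) %% 2000000011L
      g <- generate_image(cl, params, seed = sd_i)
      id <- sprintf("%s/%s_%04d.png", cl, cl, i)
      if (write_out) {
        png::writePNG(g$image, file.path(out_dir, id))
      } else {
        images[[length(images) + 1L]] <- g$image
      }
      labs <- c(labs, cl); ids <- c(ids, id)
      manifest[[length(manifest) + 1L]] <-
        list(id = id, label = cl, seed = sd_i,
             tumors = lapply(g$truth$tumors, function(tu)
               list(center = round(tu$center, 3),
                    radius_eq = round(tu$radius_eq, 3),
                    kind = tu$kind, circularity = round(tu$circularity, 4))))
    }
  }
  if (write_out) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(manifest))
  }
  list(images = images, labels = factor(labs, levels = CLASS_LABELS),
       ids = ids, truth = manifest)
}

#' Rule-based oracle classifier for phantom images
#'
#' Thresholds the red channel (monotone in rendered intensity), labels
#' connected components, discards specks, and maps component count plus
#' per-component circularity to a class: 0 blobs = NT; 1 blob = BT/MT by
#' circularity; 2 blobs = BBT/MMT/BMT by the pair of shape calls. Used to
#' demonstrate that generated datasets are learnable by construction.
#'
#' @param img H x W x 3 phantom image.
#' @param params The [phantom_params()] the image was generated with.
#' @return Predicted class label (character).
#' @export
classify_phantom <- function(img, params = phantom_params()) {
  mask <- img[, , 1] > 0.7 & img[, , 3] < 0.4
  lab <- EBImage::bwlabel(EBImage::Image(t(mask * 1)))
  lab <- t(as.array(lab))
  min_area <- pi * (0.6 * params$tumor_radius_frac[1] * params$image_size)^2
  comps <- setdiff(unique(as.vector(lab)), 0)
  areas <- vapply(comps, function(k) sum(lab == k), 0)
  keep <- comps[areas >= min_area]
  if (length(keep) > 2) keep <- keep[order(areas[match(keep, comps)],
                                           decreasing = TRUE)][1:2]
  n_blobs <- length(keep)
  if (n_blobs == 0) return("NT")
  cutoff <- (params$benign_circularity_min +
             params$malignant_circularity_max) / 2
  round_call <- vapply(keep, function(k)
    mask_circularity(lab == k) >= cutoff, logical(1))
  if (n_blobs == 1) return(if (round_call) "BT" else "MT")
  if (all(round_call)) "BBT" else if (!any(round_call)) "MMT" else "BMT"
}
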