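# Seeded fundus-phantom generator.
#
# Produces retina-like images -- a bright reddish disc on a dark
# background with an optic-disc highlight -- carrying class-specific,
# spatially localized features with per-image ground-truth lesion masks:
#   normal       plain disc, empty mask
#   cataract     diffuse whitish haze inside a lesion region
#   retinopathy  scattered small bright dots inside a lesion region
#   glaucoma     enlarged pale central cup
# The features are deliberately strong: the generator's purpose is to
# exercise classification, saliency and faithfulness end-to-end on CPU in
# minutes, not photorealism.

#' Phantom generator specification
#'
#' @param image_size side length in pixels.
#' @param classes subset of `c("normal", "cataract", "retinopathy",
#'   "glaucoma")`, in label order.
#' @param n_per_class images per class.
#' @param noise_sigma additive Gaussian pixel noise (in `[0, 1]` units).
#' @param seed RNG seed; the same spec yields bit-identical output.
#' @export
phantom_spec <- function(image_size = 64L,
                         classes = c("normal", "cataract", "retinopathy",
                                     "glaucoma"),
                         n_per_class = 50L, noise_sigma = 0.02, seed = 1L) {
  known <- c("normal", "cataract", "retinopathy", "glaucoma")
  if (!all(classes %in% known))
    stop("classes must be drawn from: ", paste(known, collapse = ", "))
  if (n_per_class < 1L) stop("n_per_class must be >= 1")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(image_size = as.integer(image_size), classes = classes,
                 n_per_class = as.integer(n_per_class),
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

disc_mask <- function(s, cy, cx, r) {
  rr <- matrix(seq_len(s), s, s)
  cc <- matrix(seq_len(s), s, s, byrow = TRUE)
  (rr - cy)^2 + (cc - cx)^2 <= r^2
}

# one phantom; returns list(image (H,W,3) in [0,1], mask (H,W) in {0,1})
draw_phantom <- function(cls, s, noise_sigma) {
  img <- array(0.04, c(s, s, 3))
  cy <- s / 2 + stats::runif(1, -0.015, 0.015) * s
  cx <- s / 2 + stats::runif(1, -0.015, 0.015) * s
  retina_r <- 0.44 * s
  retina <- disc_mask(s, cy, cx, retina_r)
  base_col <- c(0.72, 0.34, 0.14) * stats::runif(1, 0.97, 1.03)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[retina] <- min(base_col[ch], 1)
    img[, , ch] <- plane
  }
  # optic-disc highlight (present in every class, near-nasal position)
  od_ang <- stats::runif(1, -0.3, 0.3)
  od <- disc_mask(s, cy + 0.2 * s * sin(od_ang), cx + 0.2 * s * cos(od_ang),
                  0.07 * s)
  od_col <- c(0.95, 0.82, 0.55)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[od & retina] <- od_col[ch]
    img[, , ch] <- plane
  }

  mask <- matrix(0, s, s)
  if (cls != "normal") {
    # lesion region: a sub-disc fully inside the retina
    reg_r <- 0.22 * s
    ang <- stats::runif(1, 0, 2 * pi)
    dist <- stats::runif(1, 0, 0.05) * s
    ry <- cy + dist * sin(ang); rx <- cx + dist * cos(ang)
    region <- disc_mask(s, ry, rx, reg_r)
    paint <- function(where, col, alpha = 1) {
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[where] <- (1 - alpha) * plane[where] + alpha * col[ch]
        img[, , ch] <<- plane
      }
    }
    # class features are deliberately *thin* structures: a large Gaussian
    # blur removes them, so the blur-baseline faithfulness protocol has
    # real evidence to delete/insert
    if (cls == "cataract") {
      # wisps: thin bluish-white streaks criss-crossing the region
      n_streaks <- sample(10:14, 1)
      for (st in seq_len(n_streaks)) {
        a0 <- stats::runif(1, 0, 2 * pi)
        d0 <- stats::runif(1, 0, 0.75 * reg_r)
        y0 <- ry + d0 * sin(a0); x0 <- rx + d0 * cos(a0)
        dir <- stats::runif(1, 0, pi)
        len <- stats::runif(1, 0.6, 1.2) * reg_r
        for (tpos in seq(-len / 2, len / 2, by = 1)) {
          yy <- y0 + tpos * sin(dir); xx <- x0 + tpos * cos(dir)
          paint(disc_mask(s, yy, xx, 0.9) & region, c(0.85, 0.92, 1.0), 0.9)
        }
      }
    } else if (cls == "retinopathy") {
      # scattered small bright exudate dots
      n_dots <- sample(18:24, 1)
      for (d in seq_len(n_dots)) {
        da <- stats::runif(1, 0, 2 * pi)
        dd <- stats::runif(1, 0, reg_r - 3.2)
        paint(disc_mask(s, ry + dd * sin(da), rx + dd * cos(da),
                        stats::runif(1, 1.7, 2.6)), c(1.0, 1.0, 0.1))
      }
    } else if (cls == "glaucoma") {
      # enlarged cup: thin pale rim ring plus short radial vessel kinks
      ring_r <- 0.75 * reg_r
      ring <- disc_mask(s, ry, rx, ring_r + 1.4) & !disc_mask(s, ry, rx, ring_r - 1.4)
      paint(ring & region, c(1.0, 0.85, 0.45))
      for (sp in seq_len(6)) {
        aa <- stats::runif(1, 0, 2 * pi)
        for (tpos in seq(0.35 * ring_r, ring_r - 1, by = 1))
          paint(disc_mask(s, ry + tpos * sin(aa), rx + tpos * cos(aa), 0.8) & region,
                c(1.0, 0.85, 0.45), 0.9)
      }
    }
    mask[region] <- 1
  }
  if (noise_sigma > 0)
    img <- img + array(stats::rnorm(length(img), 0, noise_sigma), dim(img))
  list(image = pmin(pmax(img, 0), 1), mask = mask)
}

#' Generate a phantom dataset
#'
#' @param spec a [phantom_spec()].
#' @return list with `images` `(N, s, s, 3)` in `[0, 1]`, integer
#'   `labels` in `1..K` (balanced, in `spec$classes` order), binary
#'   `masks` `(N, s, s)`, `classes`, and per-image `ids`.
#' @export
generate_phantoms <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  s <- spec$image_size
  K <- length(spec$classes)
  n <- K * spec$n_per_class
  images <- array(0, c(n, s, s, 3))
  masks <- array(0, c(n, s, s))
  labels <- integer(n)
  ids <- character(n)
  withr::with_seed(spec$seed, {
    i <- 0L
    for (k in seq_len(K)) for (j in seq_len(spec$n_per_class)) {
      i <- i + 1L
      ph <- draw_phantom(spec$classes[k], s, spec$noise_sigma)
      images[i, , , ] <- ph$image
      masks[i, , ] <- ph$mask
      labels[i] <- k
      ids[i] <- sprintf("%s_%03d", spec$classes[k], j)
    }
  })
  list(images = images, labels = labels, masks = masks,
       classes = spec$classes, ids = ids, spec = spec)
}

#' Ground-truth saliency from a lesion mask
#'
#' The oracle explanation: 1 inside the lesion mask, 0 outside.
#'
#' @param mask binary `(H, W)` matrix.
#' @return a `saliency_map`.
#' @export
oracle_saliency <- function(mask) {
  if (!all(mask %in% c(0, 1))) stop("mask must be binary")
  structure(list(values = matrix(as.numeric(mask), nrow(mask), ncol(mask)),
                 target_class = NA_integer_, layer_id = "oracle"),
            class = "saliency_map")
}

#' Write a phantom dataset as a class-per-subdirectory image tree
#'
#' @param spec a [phantom_spec()].
#' @param dir output directory (one PNG per image under `dir/<class>/`).
#' @param mask_dir optional separate directory for the ground-truth masks
#'   (kept outside `dir` so the image tree stays a pure class layout).
#' @return invisible [dataset_index()] of the written tree.
#' @export
write_phantom_dataset <- function(spec, dir, mask_dir = NULL) {
  ph <- generate_phantoms(spec)
  for (i in seq_along(ph$labels)) {
    cl <- ph$classes[ph$labels[i]]
    d <- file.path(dir, cl)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    EBImage::writeImage(
      EBImage::Image(aperm(ph$images[i, , , ], c(2, 1, 3)), colormode = "Color"),
      file.path(d, paste0(ph$ids[i], ".png")))
    if (!is.null(mask_dir)) {
      dir.create(mask_dir, recursive = TRUE, showWarnings = FALSE)
      EBImage::writeImage(t(ph$masks[i, , ]),
                          file.path(mask_dir, paste0(ph$ids[i], ".png")))
    }
  }
  invisible(dataset_index(dir))
}
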