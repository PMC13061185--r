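# Insertion/deletion faithfulness: confidence-vs-fraction curves and
# their AUCs under a Gaussian-blur baseline, with the correct-only
# protocol.
#
# Deletion: starting from the original image, pixels are replaced by the
# blurred baseline in order of decreasing saliency; a sharp confidence
# drop means the explanation marked the evidence.  Insertion: starting
# from the baseline, original pixels are restored in the same order; a
# quick confidence rise means the marked regions carry the class
# evidence.  Both AUCs integrate the softmax confidence of the target
# class over the fraction t in [0, 1].

#' Gaussian-blur baseline configuration
#'
#' @param kernel odd kernel side length in pixels.
#' @param sigma Gaussian standard deviation in pixels.
#' @param steps number of insertion/deletion steps (curves have
#'   `steps + 1` points).
#' @export
blur_config <- function(kernel = 51L, sigma = 8.0, steps = 50L) {
  kernel <- as.integer(kernel)
  if (kernel %% 2L == 0L) stop("blur kernel must be odd")
  if (sigma <= 0) stop("sigma must be positive")
  if (steps < 1L) stop("steps must be positive")
  structure(list(kernel = kernel, sigma = sigma, steps = as.integer(steps)),
            class = "blur_config")
}

#' Blur an image with the baseline Gaussian kernel
#'
#' Per-channel 2-D Gaussian blur with the stated kernel size and sigma
#' (replicated edges); values are clipped to the valid range.
#' `kernel = 1` is the identity and a constant image is unchanged.
#'
#' @param image `(H, W, C)` array (or a matrix for one channel).
#' @param cfg a [blur_config()].
#' @param clip `c(lo, hi)` clipping range, or `NULL` to disable.
#' @return blurred array, same shape.
#' @export
blur_baseline <- function(image, cfg = blur_config(), clip = c(0, 1)) {
  if (cfg$kernel == 1L) return(image)
  # the kernel is a truncation window for the Gaussian; it cannot exceed
  # the image, so clamp it to the largest odd size that fits
  keff <- min(cfg$kernel, dim(image)[1], dim(image)[2])
  if (keff %% 2L == 0L) keff <- keff - 1L
  if (keff < 3L) return(image)
  brush <- EBImage::makeBrush(keff, shape = "gaussian", sigma = cfg$sigma)
  was_mat <- is.matrix(image)
  if (was_mat) dim(image) <- c(dim(image), 1L)
  out <- image
  for (ch in seq_len(dim(image)[3]))
    out[, , ch] <- EBImage::filter2(image[, , ch], brush, boundary = "replicate")
  if (!is.null(clip)) out <- pmin(pmax(out, clip[1]), clip[2])
  if (was_mat) dim(out) <- dim(out)[1:2]
  out
}

#' Wrap a model as a softmax scorer on raw images
#'
#' Returns `function(batch)` mapping raw `[0, 1]` images `(N, H, W, 3)`
#' to softmax probabilities, applying the standard normalization first.
#' Because normalization is per-pixel affine, running faithfulness in raw
#' image space and normalizing inside the scorer is exact.
#'
#' @param model a [maxgrnet()] model.
#' @export
model_scorer <- function(model) {
  force(model)
  function(batch) {
    batch <- as_nhwc(batch)
    for (i in seq_len(dim(batch)[1]))
      batch[i, , , ] <- normalize_image(batch[i, , , ])
    predict(model, batch, type = "prob")
  }
}

# descending-saliency pixel order, ties broken by row-major pixel index
saliency_order <- function(values) {
  H <- nrow(values); W <- ncol(values)
  rm_vals <- as.vector(t(values))                  # row-major flatten
  ord_rm <- order(rm_vals, decreasing = TRUE)      # stable: ties by index
  r <- (ord_rm - 1L) %/% W + 1L
  cc <- (ord_rm - 1L) %% W + 1L
  r + (cc - 1L) * H                                # column-major indices
}

# pixel counts per step: npix/steps rounded, remainder spread over the
# earliest steps
step_counts <- function(npix, steps) {
  base <- npix %/% steps
  rem <- npix - base * steps
  counts <- rep(base, steps)
  if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1L
  counts
}

perturbation_curve <- function(scorer, image, saliency, target_class,
                               cfg, baseline, mode) {
  if (inherits(scorer, "maxgrnet")) scorer <- model_scorer(scorer)
  vals <- if (inherits(saliency, "saliency_map")) saliency$values else saliency
  if (!all(is.finite(vals))) stop("non-finite saliency values")
  d <- dim(image)
  if (!all(dim(vals) == d[1:2]))
    stop(sprintf("saliency shape %dx%d does not match image %dx%d",
                 nrow(vals), ncol(vals), d[1], d[2]))
  base_img <- if (is.null(baseline)) blur_baseline(image, cfg)
  else if (identical(baseline, "black")) array(0, d)
  else baseline
  ord <- saliency_order(vals)
  counts <- step_counts(d[1] * d[2], cfg$steps)
  from <- if (mode == "deletion") image else base_img
  to <- if (mode == "deletion") base_img else image
  n_pt <- cfg$steps + 1L
  batch <- array(0, c(n_pt, d))
  cur <- from
  batch[1, , , ] <- cur
  done <- 0L
  for (k in seq_len(cfg$steps)) {
    px <- ord[(done + 1L):(done + counts[k])]
    done <- done + counts[k]
    for (ch in seq_len(d[3])) {
      plane <- cur[, , ch]
      plane[px] <- to[, , ch][px]
      cur[, , ch] <- plane
    }
    batch[k + 1L, , , ] <- cur
  }
  probs <- scorer(batch)
  f <- probs[, target_class]
  fr <- c(0, cumsum(counts)) / (d[1] * d[2])
  structure(list(fractions = fr, confidences = f, mode = mode,
                 target_class = target_class),
            class = "faithfulness_curve")
}

#' Deletion faithfulness curve
#'
#' Replaces pixels of `image` by the blurred baseline in order of
#' decreasing saliency (ties by row-major index), evaluating the softmax
#' confidence of `target_class` after each step.  The first point is the
#' confidence on the unmodified image, the last on the fully blurred
#' baseline.
#'
#' @param scorer a `maxgrnet` model or a `function(batch)` returning a
#'   probability matrix for an `(N, H, W, C)` batch.
#' @param image raw `(H, W, C)` image in `[0, 1]`.
#' @param saliency a [gradcam()] / [random_saliency()] map or a matrix of
#'   the image's spatial shape.
#' @param target_class 1-based class index whose confidence is tracked.
#' @param cfg a [blur_config()].
#' @param baseline `NULL` (Gaussian blur of `image`), `"black"`, or a
#'   custom baseline image.
#' @return a `faithfulness_curve` with `fractions` (0 to 1) and
#'   `confidences`.
#' @export
deletion_curve <- function(scorer, image, saliency, target_class,
                           cfg = blur_config(), baseline = NULL) {
  perturbation_curve(scorer, image, saliency, target_class, cfg, baseline,
                     "deletion")
}

#' Insertion faithfulness curve
#'
#' Mirror of [deletion_curve()]: starts from the baseline image and
#' restores original pixels in decreasing-saliency order.  At `t = 1` the
#' image equals the original, so the last insertion point equals the
#' first deletion point.
#'
#' @inheritParams deletion_curve
#' @export
insertion_curve <- function(scorer, image, saliency, target_class,
                            cfg = blur_config(), baseline = NULL) {
  perturbation_curve(scorer, image, saliency, target_class, cfg, baseline,
                     "insertion")
}

#' Trapezoid area under a faithfulness curve
#'
#' Approximates the integral of the confidence over t in [0, 1] by the
#' trapezoid rule over the stored fractions.
#'
#' @param curve a `faithfulness_curve` (or list with `fractions`,
#'   `confidences`).
#' @return scalar in `[0, 1]`.
#' @export
auc_trapezoid <- function(curve) {
  t <- curve$fractions; f <- curve$confidences
  if (length(t) < 2L) stop("curve needs at least 2 points")
  if (is.unsorted(t)) stop("fractions must be non-decreasing")
  sum(diff(t) * (utils::head(f, -1) + utils::tail(f, -1)) / 2)
}

#' Evaluate explanation faithfulness over a dataset
#'
#' Runs the insertion/deletion protocol per image and aggregates.  Under
#' the correct-only protocol, images the model misclassifies are
#' excluded and the target class is the predicted class.  Summary means
#' come with percentile-bootstrap confidence intervals.
#'
#' @param model a [maxgrnet()] model.
#' @param images raw `(N, H, W, 3)` images in `[0, 1]` at the model's
#'   input size.
#' @param labels integer labels `1..K`.
#' @param explainer `"gradcam"`, `"random"`, or a
#'   `function(image, image_id, target_class)` returning a saliency map.
#' @param cfg a [blur_config()].
#' @param correct_only exclude misclassified images (default TRUE).
#' @param layer Grad-CAM layer (see [gradcam()]).
#' @param image_ids stable per-image ids (default `img_1..img_N`).
#' @param seed seed for the random explainer and the bootstrap.
#' @param n_boot bootstrap replicates for the summary CIs.
#' @param alpha bootstrap miscoverage (0.05 for 95% CIs).
#' @return list with `results` (per-image data frame: `image_id`,
#'   `target_class`, `insertion_auc`, `deletion_auc`,
#'   `one_minus_deletion`, `included`), `summary` (means, CIs, n), and
#'   `curves` (confidence matrices for mean curve plots).
#' @export
evaluate_faithfulness <- function(model, images, labels,
                                  explainer = "gradcam",
                                  cfg = blur_config(),
                                  correct_only = TRUE,
                                  layer = NULL,
                                  image_ids = NULL,
                                  seed = 1L, n_boot = 2000L, alpha = 0.05) {
  images <- as_nhwc(images)
  n <- dim(images)[1]
  stopifnot(length(labels) == n)
  if (is.null(image_ids)) image_ids <- sprintf("img_%d", seq_len(n))
  if (anyDuplicated(image_ids)) stop("image_ids must be unique")
  scorer <- model_scorer(model)
  pred <- max.col(scorer(images), ties.method = "first")
  included <- if (correct_only) pred == labels else rep(TRUE, n)
  if (!any(included))
    stop("no images included: the model classified every image incorrectly")
  sz <- dim(images)[2:3]
  inc_idx <- which(included)
  res <- vector("list", length(inc_idx))
  ins_f <- del_f <- matrix(NA_real_, length(inc_idx), cfg$steps + 1L)
  for (j in seq_along(inc_idx)) {
    i <- inc_idx[j]
    img <- images[i, , , ]
    target <- pred[i]
    sal <- if (is.function(explainer)) explainer(img, image_ids[i], target)
    else if (identical(explainer, "gradcam"))
      gradcam(model, normalize_image(img), target_class = target, layer = layer)
    else if (identical(explainer, "random"))
      random_saliency(sz, seed = seed + i, target_class = target)
    else stop("explainer must be 'gradcam', 'random' or a function")
    dc <- deletion_curve(scorer, img, sal, target, cfg)
    ic <- insertion_curve(scorer, img, sal, target, cfg)
    ins_f[j, ] <- ic$confidences
    del_f[j, ] <- dc$confidences
    ins_auc <- auc_trapezoid(ic)
    del_auc <- auc_trapezoid(dc)
    res[[j]] <- data.frame(image_id = image_ids[i], target_class = target,
                           insertion_auc = ins_auc, deletion_auc = del_auc,
                           one_minus_deletion = 1 - del_auc, included = TRUE)
  }
  results <- do.call(rbind, res)
  ci_ins <- bootstrap_mean_ci(results$insertion_auc, n_boot, alpha, seed)
  ci_del <- bootstrap_mean_ci(results$deletion_auc, n_boot, alpha, seed + 1L)
  list(results = results,
       summary = list(n = nrow(results),
                      insertion = ci_ins, deletion = ci_del,
                      one_minus_deletion = list(mean = 1 - ci_del$mean,
                                                low = 1 - ci_del$high,
                                                high = 1 - ci_del$low)),
       curves = list(fractions = dc$fractions, insertion = ins_f,
                     deletion = del_f))
}
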