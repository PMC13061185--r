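# Grad-CAM saliency for MaxGRNet-style networks, plus the random-saliency
# baseline.

#' Grad-CAM saliency map
#'
#' Computes the gradient of the target class score (the pre-softmax
#' logit) with respect to a convolutional feature layer, averages it
#' spatially per channel to obtain channel weights, forms the rectified
#' weighted channel sum, and upsamples it bilinearly to input resolution.
#' Deterministic given fixed weights; non-negative everywhere; invariant
#' to adding a constant to all logits (the logit gradient of one class is
#' unaffected).
#'
#' @param model a [maxgrnet()] model.
#' @param image single preprocessed image `(H, W, 3)` at the model's
#'   input size.
#' @param target_class integer class (1-based); default: the predicted
#'   class.
#' @param layer layer id from [model_layers()]; default: the depthwise
#'   convolution output of the final stage's last MBConv.
#' @return a `SaliencyMap`: list with `values` (non-negative
#'   `input_size x input_size` matrix), `target_class`, `layer_id`.
#' @export
gradcam <- function(model, image, target_class = NULL, layer = NULL) {
  if (length(dim(image)) != 3L)
    stop("gradcam expects a single (H, W, 3) image")
  if (is.null(layer)) layer <- default_gradcam_layer(model)
  valid <- model_layers(model)
  if (!layer %in% valid)
    stop(sprintf("unknown layer '%s'; valid layers: %s", layer,
                 paste(valid, collapse = ", ")))
  logits <- model_forward(model, image, keep_cache = TRUE)
  caches <- attr(logits, "caches")
  if (is.null(target_class))
    target_class <- max.col(matrix(logits, 1), ties.method = "first")
  if (target_class < 1L || target_class > model$config$num_classes)
    stop("target_class out of range")
  dlogits <- matrix(0, 1, model$config$num_classes)
  dlogits[1, target_class] <- 1
  bk <- model_backward(model, caches, dlogits, capture = layer,
                       stop_at_capture = TRUE)
  grad <- bk$captured                       # (1, h, w, c)
  acts <- layer_activation(model, caches, attr(logits, "outputs"), layer)
  hw <- dim(grad)[2] * dim(grad)[3]
  gm <- grad; dim(gm) <- c(hw, dim(grad)[4])
  am <- acts; dim(am) <- c(hw, dim(acts)[4])
  wts <- colMeans(gm)                       # spatial mean of gradients
  cam <- pmax(am %*% wts, 0)                # rectified weighted sum
  cam <- matrix(cam, dim(grad)[2], dim(grad)[3])
  sz <- model$config$input_size
  structure(list(values = bilinear_upsample(cam, sz, sz),
                 target_class = target_class, layer_id = layer),
            class = "saliency_map")
}

# fetch the activation a Grad-CAM layer id refers to: the op's output,
# or for ".dw" ids the MBConv's internal depthwise-conv output
layer_activation <- function(model, caches, outputs, layer) {
  is_dw <- grepl("\\.dw$", layer)
  opid <- sub("\\.dw$", "", layer)
  i <- which(vapply(model$ops, `[[`, "", "id") == opid)
  if (is_dw) caches[[i]]$dw_out else outputs[[i]]
}

#' Min-max normalize a saliency map for visualization
#'
#' Faithfulness ranking uses raw values (only the ordering matters); this
#' helper rescales to `[0, 1]` for display.
#' @param sal a `saliency_map` or numeric matrix.
#' @export
normalize_saliency <- function(sal) {
  v <- if (inherits(sal, "saliency_map")) sal$values else sal
  rng <- range(v)
  if (diff(rng) == 0) return(v * 0)
  (v - rng[1]) / diff(rng)
}

#' Random saliency baseline
#'
#' Uniform random values in `[0, 1)`, reproducible per seed; the
#' chance-level reference for faithfulness comparisons.
#'
#' @param shape `c(H, W)` (a single integer gives a square map).
#' @param seed RNG seed.
#' @param target_class,layer_id optional metadata carried through.
#' @return a `saliency_map`.
#' @export
random_saliency <- function(shape, seed = 1L, target_class = NA_integer_,
                            layer_id = "random") {
  if (length(shape) == 1L) shape <- c(shape, shape)
  vals <- withr::with_seed(as.integer(seed),
                           matrix(stats::runif(prod(shape)), shape[1], shape[2]))
  structure(list(values = vals, target_class = target_class,
                 layer_id = layer_id),
            class = "saliency_map")
}

#' Select a Grad-CAM layer by ground-truth mask concentration
#'
#' For models whose deepest feature maps are too coarse to localize
#' (e.g. a 64-pixel tiny model reaching its final stage at 2x2), picks
#' the candidate layer whose saliency concentrates best inside known
#' lesion masks on correctly classified lesion images.  This rule needs
#' ground-truth masks and is therefore a phantom-study tool; on real
#' data the layer must be chosen by hand (see [model_layers()]).
#'
#' @param model a [maxgrnet()] model.
#' @param images preprocessed images `(N, H, W, 3)`.
#' @param labels integer labels `1..K`.
#' @param masks binary lesion masks `(N, H, W)`; images whose mask is
#'   empty are ignored.
#' @param candidates layer ids to compare (default: the S1/S2 conv and
#'   depthwise layers).
#' @return list with `layer` (the selected id) and `concentration`
#'   (mean mass-in-mask over area fraction, per candidate).
#' @export
select_gradcam_layer <- function(model, images, labels, masks,
                                 candidates = c("s1.b1.mbconv",
                                                "s1.b1.mbconv.dw",
                                                "s2.b1.mbconv",
                                                "s2.b1.mbconv.dw")) {
  images <- as_nhwc(images)
  has_mask <- apply(masks, 1, sum) > 0
  idx <- which(has_mask)
  pred <- predict(model, images[idx, , , , drop = FALSE], type = "class")
  ok <- idx[pred == labels[idx]]
  if (length(ok) == 0) stop("no correctly classified images with non-empty masks")
  valid <- model_layers(model)
  if (!all(candidates %in% valid))
    stop("unknown candidate layer(s): ",
         paste(setdiff(candidates, valid), collapse = ", "))
  conc <- vapply(candidates, function(layer) {
    mean(vapply(ok, function(i) {
      sal <- gradcam(model, images[i, , , ], target_class = labels[i],
                     layer = layer)
      mask <- masks[i, , ]
      (sum(sal$values[mask == 1]) / max(sum(sal$values), 1e-12)) / mean(mask)
    }, 0))
  }, 0)
  list(layer = candidates[which.max(conc)], concentration = conc)
}
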