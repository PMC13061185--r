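# Shared fixtures, memoized so expensive objects (phantom sets, the
# trained tiny model, the faithfulness smoke) are built once per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (!exists(key, envir = .fixture_env)) assign(key, build(), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# tiny MaxGRNet used throughout the suite (~0.11M parameters, 64 px input)
tiny_config <- function(grn_enabled = TRUE, num_classes = 4L) {
  model_config(num_classes = num_classes, input_size = 64, stem_channels = 8,
               stage_depths = c(1, 1, 1, 1), stage_channels = c(8, 16, 32, 64),
               partition_size = 2, mlp_expansion = 2, se_ratio = 0.25,
               head_dim = 8, grn_enabled = grn_enabled)
}

# even smaller model for gradient-oracle tests (fast tail reruns)
micro_config <- function() {
  model_config(num_classes = 3, input_size = 64, stem_channels = 4,
               stage_depths = c(1, 1, 1, 1), stage_channels = c(4, 8, 8, 16),
               partition_size = 2, mlp_expansion = 2, se_ratio = 0.5,
               head_dim = 4)
}

# 4-class variant matching the phantom label space
micro_config_4 <- function() {
  model_config(num_classes = 4, input_size = 64, stem_channels = 4,
               stage_depths = c(1, 1, 1, 1), stage_channels = c(4, 8, 8, 16),
               partition_size = 2, mlp_expansion = 2, se_ratio = 0.5,
               head_dim = 4)
}

normalize_all <- function(x) {
  for (i in seq_len(dim(x)[1])) x[i, , , ] <- normalize_image(x[i, , , ])
  x
}

# the canonical desk-scale phantom study set: 60 per class at 64 px
phantom_set <- function() {
  memo("phantoms", function() {
    ph <- generate_phantoms(phantom_spec(n_per_class = 60, seed = 5))
    ph$norm <- normalize_all(ph$images)
    set.seed(2)
    perm <- sample(length(ph$labels))
    ph$train_idx <- perm[1:192]
    ph$val_idx <- perm[193:240]
    ph
  })
}

# the tiny model trained on the phantom training split.  Four epochs:
# enough for >= 95% validation accuracy while keeping the softmax
# calibrated (longer runs saturate the probabilities, which washes out
# the insertion/deletion dynamics)
trained_tiny <- function() {
  memo("trained_tiny", function() {
    ph <- phantom_set()
    train_model(maxgrnet(tiny_config(), seed = 1),
                ph$norm[ph$train_idx, , , ], ph$labels[ph$train_idx],
                ph$norm[ph$val_idx, , , ], ph$labels[ph$val_idx],
                cfg = train_config(epochs = 4, batch_size = 8,
                                   learning_rate = 2e-3, weight_decay = 1e-4,
                                   seed = 7))
  })
}

# desk-scale Grad-CAM layer selection on the validation images (see
# select_gradcam_layer(): mask-concentration rule)
select_cam_layer <- function(model, ph) {
  va <- ph$val_idx
  select_gradcam_layer(model, ph$norm[va, , , ], ph$labels[va],
                       ph$masks[va, , ])
}

# faithfulness smoke: Grad-CAM vs random saliency on 120 phantom images,
# standard blur baseline at 20 steps, Grad-CAM at the selected layer
smoke_faithfulness <- function() {
  memo("smoke_faith", function() {
    ph <- phantom_set()
    fit <- trained_tiny()
    layer <- select_cam_layer(fit$model, ph)$layer
    sub <- sort(c(ph$train_idx[1:72], ph$val_idx))    # 120 images
    cfgb <- blur_config(kernel = 51, sigma = 8, steps = 20)
    gc_expl <- function(img, id, tc)
      gradcam(fit$model, normalize_image(img), target_class = tc,
              layer = layer)
    list(
      n_images = length(sub),
      idx = sub,
      gradcam = evaluate_faithfulness(fit$model, ph$images[sub, , , ],
                                      ph$labels[sub], explainer = gc_expl,
                                      cfg = cfgb, image_ids = ph$ids[sub],
                                      seed = 3),
      random = evaluate_faithfulness(fit$model, ph$images[sub, , , ],
                                     ph$labels[sub], explainer = "random",
                                     cfg = cfgb, image_ids = ph$ids[sub],
                                     seed = 3))
  })
}

# central finite differences of f at x
num_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, if (is.null(dim(x))) length(x) else dim(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}
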