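# MaxGRNet model assembly.
#
# The network is an ordered list of ops:
#   stem.conv1 (3x3, stride 2, GELU), stem.conv2 (3x3)
#   stages s1..s4, each repeating (mbconv, block attention, grid attention)
#     stage_depths[s] times, with spatial downsampling at stage entry
#   head: global average pooling -> layer norm -> linear classifier
# Every op carries its parameters and a forward cache, so the backward
# pass (training, Grad-CAM) is a single reverse iteration.

#' Model configuration
#'
#' All architectural hyperparameters of a MaxGRNet / MaxViT-style model.
#' Defaults follow the MaxViT-T design: stage depths (2,2,5,2), widths
#' (64,128,256,512), stem width 64, partition size 7, MLP expansion 4,
#' squeeze-excitation ratio 0.25, head width 32.  `grn_enabled = TRUE`
#' gives MaxGRNet (GRN-MLP feed-forward); `FALSE` gives the plain
#' MaxViT-style block.
#'
#' @param num_classes number of output classes (e.g. 4 or 10).
#' @param input_size input side length in pixels.
#' @param stem_channels stem width.
#' @param stage_depths,stage_channels integer vectors of length 4.
#' @param partition_size window / grid side length `P`; the spatial size
#'   after every stage's downsampling must be divisible by `P`.
#' @param mlp_expansion hidden/input width ratio of the feed-forward MLP
#'   (also the MBConv expansion).
#' @param se_ratio squeeze-excitation reduction fraction.
#' @param head_dim per-attention-head width; must divide every stage width.
#' @param grn_enabled use the GRN-MLP (MaxGRNet) instead of the plain MLP.
#' @param grn_eps GRN stabilizer.
#' @param grn_frozen keep GRN gamma/beta pinned at zero (the
#'   parameter-free reading of the operator) instead of learning them.
#' @return a `maxgr_config` list.
#' @export
model_config <- function(num_classes,
                         input_size = 224L,
                         stem_channels = 64L,
                         stage_depths = c(2L, 2L, 5L, 2L),
                         stage_channels = c(64L, 128L, 256L, 512L),
                         partition_size = 7L,
                         mlp_expansion = 4,
                         se_ratio = 0.25,
                         head_dim = 32L,
                         grn_enabled = TRUE,
                         grn_eps = 1e-6,
                         grn_frozen = FALSE) {
  cfg <- list(num_classes = as.integer(num_classes),
              input_size = as.integer(input_size),
              stem_channels = as.integer(stem_channels),
              stage_depths = as.integer(stage_depths),
              stage_channels = as.integer(stage_channels),
              partition_size = as.integer(partition_size),
              mlp_expansion = mlp_expansion,
              se_ratio = se_ratio,
              head_dim = as.integer(head_dim),
              grn_enabled = isTRUE(grn_enabled),
              grn_eps = grn_eps,
              grn_frozen = isTRUE(grn_frozen))
  validate_config(cfg)
  structure(cfg, class = "maxgr_config")
}

validate_config <- function(cfg) {
  if (cfg$num_classes < 1L) stop("num_classes must be positive")
  if (length(cfg$stage_depths) != 4L || length(cfg$stage_channels) != 4L)
    stop("stage_depths and stage_channels must have length 4 (stages S1 to S4)")
  if (any(c(cfg$stage_depths, cfg$stage_channels, cfg$stem_channels,
            cfg$partition_size, cfg$head_dim, cfg$input_size) < 1L))
    stop("all counts must be positive")
  if (cfg$grn_eps <= 0) stop("grn_eps must be a small positive scalar")
  P <- cfg$partition_size
  size <- cfg$input_size %/% 2L           # after stem
  for (s in 1:4) {
    size <- size %/% 2L                   # stage-entry downsampling
    if ((cfg$input_size %% 2L^(s + 1L)) != 0L || size %% P != 0L)
      stop(sprintf(
        "input_size %d: stage S%d spatial size %d is not divisible by partition_size %d",
        cfg$input_size, s, size, P))
    if (cfg$stage_channels[s] %% cfg$head_dim != 0L)
      stop(sprintf("stage_channels[%d] = %d not divisible by head_dim %d",
                   s, cfg$stage_channels[s], cfg$head_dim))
  }
  invisible(cfg)
}

build_ops <- function(cfg) {
  ops <- list()
  add <- function(id, type, params, opcfg) {
    ops[[length(ops) + 1L]] <<- list(id = id, type = type, params = params,
                                     cfg = opcfg)
  }
  sc <- cfg$stem_channels
  add("stem.conv1", "conv",
      list(W = matrix(trunc_normal_fan(9L * 3L * sc, 27L), 9L * 3L, sc),
           b = numeric(sc)),
      list(k = 3L, stride = 2L, pad = 1L, gelu = TRUE))
  add("stem.conv2", "conv",
      list(W = matrix(trunc_normal_fan(9L * sc * sc, 9L * sc), 9L * sc, sc),
           b = numeric(sc)),
      list(k = 3L, stride = 1L, pad = 1L, gelu = FALSE))
  Cin <- sc
  for (s in 1:4) {
    Cs <- cfg$stage_channels[s]
    heads <- Cs %/% cfg$head_dim
    for (b in seq_len(cfg$stage_depths[s])) {
      down <- b == 1L
      add(sprintf("s%d.b%d.mbconv", s, b), "mbconv",
          init_mbconv_params(Cin, Cs, cfg$mlp_expansion, cfg$se_ratio, down),
          list(stride = if (down) 2L else 1L))
      add(sprintf("s%d.b%d.block_attn", s, b), "attn",
          init_attention_params(Cs, cfg$partition_size, heads,
                                cfg$mlp_expansion, cfg$grn_enabled),
          attn_cfg(cfg$partition_size, heads, cfg$grn_enabled, cfg$grn_eps,
                   "block"))
      add(sprintf("s%d.b%d.grid_attn", s, b), "attn",
          init_attention_params(Cs, cfg$partition_size, heads,
                                cfg$mlp_expansion, cfg$grn_enabled),
          attn_cfg(cfg$partition_size, heads, cfg$grn_enabled, cfg$grn_eps,
                   "grid"))
      Cin <- Cs
    }
  }
  C4 <- cfg$stage_channels[4]
  add("head", "head",
      list(ln_g = rep(1, C4), ln_b = numeric(C4),
           W = matrix(trunc_normal_fan(C4 * cfg$num_classes, C4), C4, cfg$num_classes),
           b = numeric(cfg$num_classes)),
      list())
  ops
}

#' Create a MaxGRNet model
#'
#' Initializes all weight matrices with a fan-in-scaled truncated normal
#' (sd `sqrt(2/fan_in)`, truncated at two sd) and zeros for GRN
#' gamma/beta, relative-position bias tables, norm offsets and all
#' biases, under the given seed.  Fan-in scaling keeps activation
#' magnitude stable through the non-residual paths (stem, downsampling
#' shortcuts), which a flat sd cannot.
#'
#' @param config a [model_config()].
#' @param seed integer RNG seed for weight initialization.
#' @return an object of class `maxgrnet`.
#' @export
maxgrnet <- function(config, seed = 1L) {
  stopifnot(inherits(config, "maxgr_config"))
  ops <- withr::with_seed(as.integer(seed), build_ops(config))
  structure(list(config = config, ops = ops), class = "maxgrnet")
}

#' @export
print.maxgrnet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "MaxGRNet model: %d classes, input %dx%d, depths (%s), channels (%s), P=%d, GRN %s\n",
    cfg$num_classes, cfg$input_size, cfg$input_size,
    paste(cfg$stage_depths, collapse = ","),
    paste(cfg$stage_channels, collapse = ","), cfg$partition_size,
    if (cfg$grn_enabled) "on" else "off"))
  cat(sprintf("  %d ops, %s parameters\n", length(x$ops),
              format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Number of trainable parameters
#' @param model a `maxgrnet` model.
#' @export
n_parameters <- function(model) {
  count <- function(p) if (is.list(p)) sum(vapply(p, count, 0)) else length(p)
  sum(vapply(model$ops, function(op) count(op$params), 0))
}

## ---- per-op forward / backward -----------------------------------------

op_forward <- function(op, x) {
  switch(op$type,
    conv = {
      cv <- conv2d_forward(x, op$params$W, op$params$b, op$cfg$k,
                           op$cfg$stride, op$cfg$pad)
      if (op$cfg$gelu) {
        out <- gelu(cv$out)
        list(out = out, cache = list(conv = cv$cache, z = cv$out))
      } else list(out = cv$out, cache = list(conv = cv$cache))
    },
    mbconv = mbconv_forward_impl(x, op$params, op$cfg$stride),
    attn = attn_unit_forward(x, op$params, op$cfg),
    head = head_forward(x, op$params),
    stop("unknown op type: ", op$type))
}

op_backward <- function(op, dout, cache, want_dw = FALSE) {
  switch(op$type,
    conv = {
      if (op$cfg$gelu) dout <- dout * gelu_grad(cache$z)
      cb <- conv2d_backward(dout, cache$conv)
      list(dx = cb$dx, grads = list(W = cb$dW, b = cb$db))
    },
    mbconv = mbconv_backward_impl(dout, cache, want_dw = want_dw),
    attn = attn_unit_backward(dout, cache),
    head = head_backward(dout, cache),
    stop("unknown op type: ", op$type))
}

head_forward <- function(x, p) {
  d <- dim(x); sp <- d[2] * d[3]
  xm <- nhwc_mat(x)
  grp <- rep(seq_len(d[1]), sp)
  s <- rowsum(xm, grp) / sp
  dimnames(s) <- NULL                      # rowsum's group rownames
  ln <- ln_forward(s, p$ln_g, p$ln_b)
  lg <- linear_forward(ln$out, p$W, p$b)
  list(out = lg$out,
       cache = list(ln = ln$cache, lg = lg$cache, grp = grp, sp = sp, dims = d))
}

head_backward <- function(dout, cache) {
  bg <- linear_backward(dout, cache$lg)
  bl <- ln_backward(bg$dx, cache$ln)
  dxm <- bl$dx[cache$grp, , drop = FALSE] / cache$sp
  dx <- dxm; dim(dx) <- cache$dims
  list(dx = dx,
       grads = list(ln_g = bl$dg, ln_b = bl$db, W = bg$dW, b = bg$db))
}

## ---- whole-model passes -------------------------------------------------

#' Model forward pass
#'
#' Runs a batch of preprocessed images through the network and returns the
#' class logits.
#'
#' @param model a [maxgrnet()] model.
#' @param images array `(N, H, W, 3)` or `(H, W, 3)`, spatially equal to
#'   `config$input_size` and already normalized (see [preprocess_image()]).
#' @param keep_cache keep per-op caches (needed for a backward pass);
#'   returned as attribute `"caches"` together with `"outputs"`.
#' @return logits matrix `(N, num_classes)`.
#' @export
model_forward <- function(model, images, keep_cache = FALSE) {
  x <- as_nhwc(images)
  check_finite(x, "images")
  sz <- model$config$input_size
  if (dim(x)[2] != sz || dim(x)[3] != sz || dim(x)[4] != 3L)
    stop(sprintf("expected input of spatial size %dx%dx3, got %dx%dx%d",
                 sz, sz, dim(x)[2], dim(x)[3], dim(x)[4]))
  caches <- outputs <- if (keep_cache) vector("list", length(model$ops))
  for (i in seq_along(model$ops)) {
    fw <- op_forward(model$ops[[i]], x)
    x <- fw$out
    if (keep_cache) {
      caches[[i]] <- fw$cache
      outputs[[i]] <- fw$out
    }
  }
  if (keep_cache) {
    attr(x, "caches") <- caches
    attr(x, "outputs") <- outputs
  }
  x
}

# reverse pass; dlogits (N, K).  Returns grads (named by op id) and, when
# `capture` names an op (optionally with ".dw" suffix for the depthwise
# output of an MBConv), the gradient at that activation.
model_backward <- function(model, caches, dlogits,
                           capture = NULL, stop_at_capture = FALSE) {
  capture_op <- capture_dw <- NULL
  if (!is.null(capture)) {
    capture_dw <- grepl("\\.dw$", capture)
    capture_op <- sub("\\.dw$", "", capture)
  }
  grads <- list()
  d <- dlogits
  captured <- NULL
  for (i in rev(seq_along(model$ops))) {
    op <- model$ops[[i]]
    want_dw <- !is.null(capture_op) && identical(op$id, capture_op) && capture_dw
    bk <- op_backward(op, d, caches[[i]], want_dw = want_dw)
    if (!is.null(capture_op) && identical(op$id, capture_op)) {
      captured <- if (want_dw) bk$d_dw else d
      if (stop_at_capture) {
        grads[[op$id]] <- bk$grads
        return(list(grads = grads, captured = captured))
      }
    }
    grads[[op$id]] <- bk$grads
    d <- bk$dx
  }
  list(grads = grads, dx = d, captured = captured)
}

#' Predict from a MaxGRNet model
#'
#' @param object a `maxgrnet` model.
#' @param images preprocessed image array (see [model_forward()]).
#' @param type `"logits"`, `"prob"` (softmax) or `"class"` (1-based label).
#' @param ... unused.
#' @export
predict.maxgrnet <- function(object, images, type = c("prob", "logits", "class"),
                             ...) {
  type <- match.arg(type)
  logits <- model_forward(object, images)
  switch(type,
         logits = logits,
         prob = row_softmax(logits),
         class = max.col(logits, ties.method = "first"))
}

#' List layers usable as Grad-CAM targets
#'
#' Returns the identifiers of 4-axis feature layers: every convolutional
#' and MBConv op, with an additional `".dw"`-suffixed id per MBConv
#' selecting the output of its 3x3 depthwise convolution (the default
#' "last convolutional layer" target).
#'
#' @param model a `maxgrnet` model.
#' @export
model_layers <- function(model) {
  ids <- character()
  for (op in model$ops) {
    if (op$type == "conv") ids <- c(ids, op$id)
    if (op$type == "mbconv") ids <- c(ids, op$id, paste0(op$id, ".dw"))
  }
  ids
}

# default Grad-CAM layer: depthwise conv of the final stage's last MBConv
default_gradcam_layer <- function(model) {
  mb <- grep("^s4\\..*\\.mbconv$", vapply(model$ops, `[[`, "", "id"), value = TRUE)
  paste0(mb[length(mb)], ".dw")
}

## ---- serialization ------------------------------------------------------

#' Save / load a model
#'
#' Weights go to an RDS container; the configuration is additionally
#' written as YAML next to it for inspection.
#'
#' @param model a `maxgrnet` model.
#' @param path file path for the checkpoint (e.g. `model.rds`).
#' @export
save_model <- function(model, path) {
  saveRDS(list(config = unclass(model$config), ops = model$ops), path)
  yaml::write_yaml(list(model = unclass(model$config)),
                   paste0(sub("\\.rds$", "", path), ".yaml"))
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  raw <- readRDS(path)
  cfg <- structure(raw$config, class = "maxgr_config")
  validate_config(cfg)
  structure(list(config = cfg, ops = raw$ops), class = "maxgrnet")
}

#' Export penultimate-layer embeddings
#'
#' Returns the pooled, layer-normalized feature vectors feeding the
#' classifier head — the representation used for embedding-space
#' analyses (e.g. external projection/clustering tools).
#'
#' @param model a [maxgrnet()] model.
#' @param images preprocessed images (see [model_forward()]).
#' @return numeric matrix `(N, stage_channels[4])`.
#' @export
model_embeddings <- function(model, images) {
  x <- as_nhwc(images)
  check_finite(x, "images")
  for (i in seq_len(length(model$ops) - 1L))
    x <- op_forward(model$ops[[i]], x)$out
  p <- model$ops[[length(model$ops)]]$params
  d <- dim(x); sp <- d[2] * d[3]
  xm <- nhwc_mat(x)
  s <- rowsum(xm, rep(seq_len(d[1]), sp)) / sp
  dimnames(s) <- NULL
  ln_forward(s, p$ln_g, p$ln_b)$out
}
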