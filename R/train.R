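# Training: softmax cross-entropy, Adam with decoupled weight decay, and
# the cross-validation harness.

#' Training configuration
#'
#' Defaults are the reference configuration (50 epochs, batch 64, Adam,
#' learning rate 1e-5, weight decay 3e-5); desk-scale runs on synthetic
#' phantoms override epochs/batch/learning rate.
#'
#' @param epochs number of passes over the training set.
#' @param batch_size minibatch size.
#' @param optimizer only `"adam"` is implemented.
#' @param learning_rate,weight_decay Adam step size and decoupled weight
#'   decay (applied to weight matrices only).
#' @param clip_norm global gradient-norm clip (stabilizer for short
#'   desk-scale runs); `Inf` disables.
#' @param warmup_frac fraction of total steps over which the learning
#'   rate ramps linearly from 0; 0 disables.
#' @param seed RNG seed controlling shuffling (and any augmentation).
#' @export
train_config <- function(epochs = 50L, batch_size = 64L, optimizer = "adam",
                         learning_rate = 1e-5, weight_decay = 3e-5,
                         clip_norm = 1.0, warmup_frac = 0.1,
                         seed = 1L) {
  stopifnot(epochs >= 0, batch_size >= 1, learning_rate > 0, weight_decay >= 0,
            clip_norm > 0, warmup_frac >= 0, warmup_frac < 1)
  if (!identical(optimizer, "adam")) stop("only the adam optimizer is implemented")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 optimizer = optimizer, learning_rate = learning_rate,
                 weight_decay = weight_decay, clip_norm = clip_norm,
                 warmup_frac = warmup_frac, seed = as.integer(seed)),
            class = "maxgr_train_config")
}

# global L2 norm over a gradient tree, and uniform rescaling
grad_tree_norm <- function(g) {
  acc <- 0
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk)
    else acc <<- acc + sum(x * x)
    invisible(NULL)
  }
  walk(g)
  sqrt(acc)
}

grad_tree_scale <- function(g, f) {
  if (is.list(g)) lapply(g, grad_tree_scale, f = f) else g * f
}

softmax_xent <- function(logits, y) {
  n <- nrow(logits)
  p <- row_softmax(logits)
  ii <- cbind(seq_len(n), y)
  loss <- -mean(log(pmax(p[ii], 1e-12)))
  d <- p
  d[ii] <- d[ii] - 1
  list(loss = loss, dlogits = d / n, prob = p)
}

# one Adam step on a parameter tree; state mirrors the tree with m/v slots.
# Decoupled weight decay on matrices whose name starts with "W"; GRN
# gamma/beta are skipped entirely when frozen.
adam_update_tree <- function(p, g, s, lr, wd, t, frozen_grn,
                             beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(p)) {
    if (is.list(p[[nm]])) {
      r <- adam_update_tree(p[[nm]], g[[nm]], s[[nm]], lr, wd, t, frozen_grn,
                            beta1, beta2, eps)
      p[[nm]] <- r$p; s[[nm]] <- r$s
    } else {
      if (frozen_grn && nm %in% c("gamma", "beta")) next
      gv <- g[[nm]]
      if (is.null(s[[nm]])) s[[nm]] <- list(m = 0 * p[[nm]], v = 0 * p[[nm]])
      st <- s[[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * gv
      st$v <- beta2 * st$v + (1 - beta2) * gv * gv
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      upd <- lr * mhat / (sqrt(vhat) + eps)
      if (wd > 0 && startsWith(nm, "W")) upd <- upd + lr * wd * p[[nm]]
      p[[nm]] <- p[[nm]] - upd
      s[[nm]] <- st
    }
  }
  list(p = p, s = s)
}

#' Train a model
#'
#' Minibatch training with softmax cross-entropy and Adam.  Fully seeded:
#' the same seed, data and initial weights give identical final weights on
#' CPU.  If sample ids are supplied for both subsets, any overlap is a
#' hard leakage error.  Optional on-the-fly augmentation is applied to
#' training batches only (validation images are never augmented).
#'
#' @param model a [maxgrnet()] model.
#' @param x,y training images `(N, H, W, 3)` (preprocessed) and integer
#'   labels in `1..num_classes`.
#' @param val_x,val_y optional validation set, evaluated after each epoch.
#' @param cfg a [train_config()].
#' @param train_ids,val_ids optional stable sample ids used for the
#'   leakage check.
#' @param augment_fn optional `function(image, seed)` applied to each
#'   training image each time it is drawn.
#' @param verbose print per-epoch progress.
#' @return list with `model` (trained), `history` (per-epoch data frame
#'   with train loss/accuracy and validation accuracy).
#' @export
train_model <- function(model, x, y, val_x = NULL, val_y = NULL,
                        cfg = train_config(), train_ids = NULL, val_ids = NULL,
                        augment_fn = NULL, verbose = FALSE) {
  x <- as_nhwc(x)
  n <- dim(x)[1]
  stopifnot(length(y) == n, all(y >= 1L), all(y <= model$config$num_classes))
  if (!is.null(train_ids) && !is.null(val_ids)) {
    ov <- intersect(train_ids, val_ids)
    if (length(ov) > 0)
      stop(sprintf("train/validation leakage: %d shared sample id(s), e.g. '%s'",
                   length(ov), ov[1]))
  }
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        train_acc = numeric(), val_acc = numeric())
  if (cfg$epochs == 0L) return(list(model = model, history = history))

  state <- vector("list", length(model$ops))
  names(state) <- vapply(model$ops, `[[`, "", "id")
  t_step <- 0L
  steps_per_epoch <- length(seq(1L, n, by = cfg$batch_size))
  warmup_steps <- ceiling(cfg$warmup_frac * cfg$epochs * steps_per_epoch)
  withr::with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      perm <- sample.int(n)
      losses <- numeric(); accs <- numeric()
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- perm[start:min(start + cfg$batch_size - 1L, n)]
        xb <- x[idx, , , , drop = FALSE]
        if (!is.null(augment_fn)) {
          for (j in seq_along(idx))
            xb[j, , , ] <- augment_fn(xb[j, , , ],
                                      seed = sample.int(.Machine$integer.max, 1L))
        }
        yb <- y[idx]
        logits <- model_forward(model, xb, keep_cache = TRUE)
        ce <- softmax_xent(logits, yb)
        bk <- model_backward(model, attr(logits, "caches"), ce$dlogits)
        t_step <- t_step + 1L
        gnorm <- grad_tree_norm(bk$grads)
        if (is.finite(cfg$clip_norm) && gnorm > cfg$clip_norm)
          bk$grads <- grad_tree_scale(bk$grads, cfg$clip_norm / gnorm)
        lr_t <- cfg$learning_rate *
          if (warmup_steps > 0L) min(1, t_step / warmup_steps) else 1
        for (i in seq_along(model$ops)) {
          id <- model$ops[[i]]$id
          r <- adam_update_tree(model$ops[[i]]$params, bk$grads[[id]],
                                state[[id]], lr_t,
                                cfg$weight_decay, t_step,
                                model$config$grn_frozen)
          model$ops[[i]]$params <- r$p
          state[[id]] <- r$s
        }
        losses <- c(losses, ce$loss)
        accs <- c(accs, mean(max.col(logits, ties.method = "first") == yb))
      }
      va <- NA_real_
      if (!is.null(val_x)) {
        pred <- predict(model, val_x, type = "class")
        va <- mean(pred == val_y)
      }
      history <- rbind(history, data.frame(
        epoch = ep, train_loss = mean(losses), train_acc = mean(accs),
        val_acc = va))
      if (verbose)
        message(sprintf("epoch %d: loss %.4f train acc %.3f val acc %s",
                        ep, mean(losses), mean(accs),
                        ifelse(is.na(va), "-", sprintf("%.3f", va))))
    }
  })
  list(model = model, history = history)
}

#' Stratified k-fold split
#'
#' Partitions sample indices into `k` folds with per-fold class
#' proportions within one sample of the global proportions, under a
#' seeded shuffle.
#'
#' @param labels class labels (any atomic type).
#' @param k number of folds (`>= 2`); every class must have at least `k`
#'   members.
#' @param seed RNG seed.
#' @return list of `k` elements, each `list(train = ids, test = ids)`
#'   (integer indices into `labels`).
#' @export
stratified_kfold <- function(labels, k = 5L, seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  tab <- table(labels)
  small <- names(tab)[tab < k]
  if (length(small) > 0)
    stop(sprintf("class '%s' has fewer than k = %d members", small[1], k))
  fold_of <- integer(length(labels))
  withr::with_seed(as.integer(seed), {
    for (cl in names(tab)) {
      ids <- sample(which(labels == cl))
      # rotate the fold cycle so remainders spread over folds evenly
      fold_of[ids] <- ((seq_along(ids) - 1L + sample.int(k, 1L)) %% k) + 1L
    }
  })
  lapply(seq_len(k), function(f)
    list(train = which(fold_of != f), test = which(fold_of == f)))
}

#' Five-fold cross-validation harness
#'
#' Trains a fresh model per fold on its training split (any augmentation
#' stays inside the fold's training subset) and evaluates on the held-out
#' fold.  Folds are stratified by default.  Shared ids between a fold's
#' train and test sets are a hard error.
#'
#' @param model_factory `function(fold)` returning a fresh untrained model.
#' @param x,y images and labels (see [train_model()]).
#' @param k number of folds.
#' @param train_cfg a [train_config()].
#' @param seed seed for the fold split.
#' @param stratify use stratified folds (recommended; `FALSE` gives a
#'   plain shuffled split).
#' @param augment_fn optional per-image training augmentation.
#' @return a `CVResult`: list with `folds` (per-fold metrics reports),
#'   `summary` (mean and sd per metric, sd with denominator `k - 1`), and
#'   `fold_vectors` (per-fold scalar vectors for paired testing).
#' @export
run_crossval <- function(model_factory, x, y, k = 5L,
                         train_cfg = train_config(), seed = 1L,
                         stratify = TRUE, augment_fn = NULL) {
  x <- as_nhwc(x)
  n <- dim(x)[1]
  folds <- if (stratify) stratified_kfold(y, k, seed)
  else {
    perm <- withr::with_seed(as.integer(seed), sample.int(n))
    lapply(seq_len(k), function(f) {
      te <- perm[seq(f, n, by = k)]
      list(train = setdiff(seq_len(n), te), test = te)
    })
  }
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- folds[[f]]$train; te <- folds[[f]]$test
    if (length(intersect(tr, te)) > 0)
      stop("fold leakage: shared ids between train and test")
    model <- model_factory(f)
    fit <- train_model(model, x[tr, , , , drop = FALSE], y[tr],
                       cfg = train_cfg, augment_fn = augment_fn)
    scores <- predict(fit$model, x[te, , , , drop = FALSE], type = "prob")
    pred <- max.col(scores, ties.method = "first")
    rep_f <- confusion_and_metrics(y[te], pred, model$config$num_classes)
    rep_f$ovr_auc <- ovr_roc_auc(y[te], scores)
    reports[[f]] <- rep_f
  }
  fold_vectors <- list(
    accuracy = vapply(reports, function(r) r$overall_accuracy, 0),
    macro_precision = vapply(reports, function(r) r$macro$precision, 0),
    macro_recall = vapply(reports, function(r) r$macro$recall, 0),
    macro_f1 = vapply(reports, function(r) r$macro$f1, 0))
  summary <- data.frame(
    metric = names(fold_vectors),
    mean = vapply(fold_vectors, mean, 0),
    sd = vapply(fold_vectors, stats::sd, 0),
    row.names = NULL)
  structure(list(folds = reports, summary = summary,
                 fold_vectors = fold_vectors, k = k),
            class = "maxgr_cv_result")
}
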