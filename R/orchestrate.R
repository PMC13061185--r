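# Command orchestration: each run_* function validates its inputs, does
# one pipeline stage through the package API, writes its artifacts plus a
# run manifest, and returns the artifact paths.  The thin command-line
# wrapper in inst/cli/maxgrnet.R dispatches to maxgrnet_cli().

write_manifest <- function(out_dir, command, config, inputs, outputs) {
  manifest <- list(
    command = command,
    config = config,
    inputs = inputs,
    outputs = outputs,
    package_version = as.character(utils::packageVersion("maxgrnet")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  path
}

load_yaml_config <- function(path) if (is.null(path)) list() else yaml::read_yaml(path)

# model_config() from the model.* keys of a YAML config list.  When the
# config gives no architecture and the input is small, fall back to the
# desk-scale tiny geometry instead of the full-size defaults (whose
# partition size does not divide small inputs).
config_from_yaml <- function(yml, num_classes = NULL) {
  m <- yml$model %||% list()
  args <- m[intersect(names(m), names(formals(model_config)))]
  if (!is.null(num_classes) && is.null(args$num_classes))
    args$num_classes <- num_classes
  small <- (args$input_size %||% 224L) <= 128L
  if (small && is.null(m$stage_channels)) {
    defaults <- list(stem_channels = 8L, stage_depths = c(1L, 1L, 1L, 1L),
                     stage_channels = c(8L, 16L, 32L, 64L),
                     partition_size = 2L, mlp_expansion = 2, head_dim = 8L)
    args <- utils::modifyList(defaults, args)
  }
  do.call(model_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Orchestrated pipeline commands
#'
#' Single entry point used by the `inst/cli/maxgrnet.R` script.  Each
#' command validates its options, runs one stage through the package
#' functions, writes its artifacts and a `run_manifest.json` snapshot
#' (config, seeds, inputs, outputs, timestamp) into `opts$out`.
#'
#' Commands: `generate-synthetic`, `split`, `balance`, `train`,
#' `evaluate`, `crossval`, `explain`, `faithfulness`, `compare`.
#'
#' @param command command name.
#' @param opts named list of options (see the CLI script for the set
#'   accepted per command).
#' @return invisible list of artifact paths.
#' @export
maxgrnet_cli <- function(command, opts = list()) {
  handlers <- list(
    "generate-synthetic" = run_generate_synthetic,
    "split" = run_split,
    "balance" = run_balance,
    "train" = run_train,
    "evaluate" = run_evaluate,
    "crossval" = run_crossval_cmd,
    "explain" = run_explain,
    "faithfulness" = run_faithfulness,
    "compare" = run_compare)
  if (!command %in% names(handlers))
    stop(sprintf("unknown command '%s'; valid commands: %s", command,
                 paste(names(handlers), collapse = ", ")))
  h <- handlers[[command]]
  invisible(h(opts))
}

ensure_out <- function(opts) {
  out <- opts$out %||% stop("option 'out' (output directory) is required")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  out
}

run_generate_synthetic <- function(opts) {
  out <- ensure_out(opts)
  spec <- phantom_spec(image_size = opts$size %||% 64L,
                       n_per_class = opts$n %||% 50L,
                       noise_sigma = opts$noise %||% 0.02,
                       seed = opts$seed %||% 1L)
  idx <- write_phantom_dataset(spec, file.path(out, "images"),
                               mask_dir = file.path(out, "masks"))
  icsv <- file.path(out, "index.csv")
  utils::write.csv(idx, icsv, row.names = FALSE)
  mf <- write_manifest(out, "generate-synthetic", unclass(spec),
                       list(), list(index = icsv))
  list(index = icsv, manifest = mf)
}

run_split <- function(opts) {
  out <- ensure_out(opts)
  idx <- dataset_index(opts$data %||% stop("option 'data' is required"))
  ratios <- opts$ratios %||% c(train = 0.8, val = 0.1, test = 0.1)
  idx <- split_holdout(idx, ratios, seed = opts$seed %||% 1L)
  icsv <- file.path(out, "index.csv")
  utils::write.csv(idx, icsv, row.names = FALSE)
  mf <- write_manifest(out, "split", list(ratios = ratios, seed = opts$seed %||% 1L),
                       list(data = opts$data), list(index = icsv))
  list(index = icsv, manifest = mf)
}

run_balance <- function(opts) {
  out <- ensure_out(opts)
  idx <- utils::read.csv(opts$index %||% stop("option 'index' is required"))
  plan <- plan_balancing(idx, opts$target %||% stop("option 'target' is required"),
                         ratios = opts$ratios %||% c(train = 0.7, val = 0.2, test = 0.1),
                         seed = opts$seed %||% 1L)
  balanced <- apply_balancing(idx, plan)
  viol <- verify_no_leakage(balanced)
  if (nrow(viol) > 0) stop("balancing produced leakage violations")
  pcsv <- file.path(out, "balancing_plan.csv")
  utils::write.csv(plan$per_subset, pcsv, row.names = FALSE)
  bcsv <- file.path(out, "balanced_index.csv")
  utils::write.csv(balanced, bcsv, row.names = FALSE)
  if (isTRUE(opts$materialize))
    materialize_balanced(idx, plan, file.path(out, "augmented"),
                         seed = opts$seed %||% 1L)
  mf <- write_manifest(out, "balance",
                       list(target = opts$target, seed = opts$seed %||% 1L),
                       list(index = opts$index),
                       list(plan = pcsv, balanced_index = bcsv))
  list(plan = pcsv, balanced_index = bcsv, manifest = mf)
}

# load a class-per-subdirectory tree into memory at a given size
load_image_tree <- function(root, size) {
  idx <- dataset_index(root)
  classes <- sort(unique(idx$class_label))
  n <- nrow(idx)
  x <- array(0, c(n, size, size, 3))
  for (i in seq_len(n))
    x[i, , , ] <- preprocess_image(idx$path[i], size = size, normalize = FALSE)
  list(x = x, y = match(idx$class_label, classes), classes = classes,
       ids = idx$image_id)
}

normalize_batch <- function(x) {
  for (i in seq_len(dim(x)[1])) x[i, , , ] <- normalize_image(x[i, , , ])
  x
}

run_train <- function(opts) {
  out <- ensure_out(opts)
  yml <- load_yaml_config(opts$config)
  size <- opts$size %||% yml$model$input_size %||% 64L
  data <- load_image_tree(opts$data %||% stop("option 'data' is required"), size)
  cfg <- config_from_yaml(utils::modifyList(yml, list(model = utils::modifyList(
    yml$model %||% list(), list(input_size = size)))),
    num_classes = length(data$classes))
  tc <- train_config(epochs = opts$epochs %||% yml$train$epochs %||% 5L,
                     batch_size = opts$batch %||% yml$train$batch_size %||% 16L,
                     learning_rate = opts$lr %||% yml$train$learning_rate %||% 3e-3,
                     weight_decay = yml$train$weight_decay %||% 3e-5,
                     seed = opts$seed %||% 1L)
  split <- stratified_kfold(data$y, k = 5L, seed = tc$seed)[[1]]
  fit <- train_model(maxgrnet(cfg, seed = tc$seed),
                     normalize_batch(data$x[split$train, , , , drop = FALSE]),
                     data$y[split$train],
                     normalize_batch(data$x[split$test, , , , drop = FALSE]),
                     data$y[split$test],
                     cfg = tc,
                     train_ids = data$ids[split$train],
                     val_ids = data$ids[split$test])
  mpath <- file.path(out, "model.rds")
  save_model(fit$model, mpath)
  hcsv <- file.path(out, "history.csv")
  utils::write.csv(fit$history, hcsv, row.names = FALSE)
  plot_history(fit$history, file.path(out, "accuracy_curves.png"))
  mf <- write_manifest(out, "train", list(model = unclass(cfg), train = unclass(tc)),
                       list(data = opts$data),
                       list(model = mpath, history = hcsv))
  list(model = mpath, history = hcsv, manifest = mf)
}

run_evaluate <- function(opts) {
  out <- ensure_out(opts)
  model <- load_model(opts$model %||% stop("option 'model' is required"))
  data <- load_image_tree(opts$data %||% stop("option 'data' is required"),
                          model$config$input_size)
  scores <- predict(model, normalize_batch(data$x), type = "prob")
  pred <- max.col(scores, ties.method = "first")
  rep_m <- confusion_and_metrics(data$y, pred, model$config$num_classes)
  ovr <- ovr_roc_auc(data$y, scores)
  mjson <- file.path(out, "metrics.json")
  jsonlite::write_json(list(overall_accuracy = rep_m$overall_accuracy,
                            macro = rep_m$macro, macro_auc = ovr$macro_auc,
                            per_class = rep_m$per_class, n = rep_m$n),
                       mjson, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  ccsv <- file.path(out, "confusion.csv")
  utils::write.csv(rep_m$confusion, ccsv)
  plot_confusion(rep_m$confusion, file.path(out, "confusion.png"), data$classes)
  plot_roc(ovr, file.path(out, "roc.png"), data$classes)
  mf <- write_manifest(out, "evaluate", list(),
                       list(model = opts$model, data = opts$data),
                       list(metrics = mjson, confusion = ccsv))
  list(metrics = mjson, confusion = ccsv, manifest = mf)
}

run_crossval_cmd <- function(opts) {
  out <- ensure_out(opts)
  yml <- load_yaml_config(opts$config)
  size <- opts$size %||% yml$model$input_size %||% 64L
  data <- load_image_tree(opts$data %||% stop("option 'data' is required"), size)
  cfg <- config_from_yaml(utils::modifyList(yml, list(model = utils::modifyList(
    yml$model %||% list(), list(input_size = size)))),
    num_classes = length(data$classes))
  tc <- train_config(epochs = opts$epochs %||% 3L,
                     batch_size = opts$batch %||% 16L,
                     learning_rate = opts$lr %||% 3e-3,
                     seed = opts$seed %||% 1L)
  cv <- run_crossval(function(f) maxgrnet(cfg, seed = tc$seed + f),
                     normalize_batch(data$x), data$y,
                     k = opts$k %||% 5L, train_cfg = tc, seed = tc$seed)
  scsv <- file.path(out, "cv_summary.csv")
  utils::write.csv(cv$summary, scsv, row.names = FALSE)
  fcsv <- file.path(out, "cv_folds.csv")
  utils::write.csv(data.frame(fold = seq_len(cv$k),
                              as.data.frame(cv$fold_vectors)),
                   fcsv, row.names = FALSE)
  mf <- write_manifest(out, "crossval", list(model = unclass(cfg),
                                             train = unclass(tc),
                                             k = opts$k %||% 5L),
                       list(data = opts$data),
                       list(summary = scsv, folds = fcsv))
  list(summary = scsv, folds = fcsv, manifest = mf)
}

run_explain <- function(opts) {
  out <- ensure_out(opts)
  model <- load_model(opts$model %||% stop("option 'model' is required"))
  img <- preprocess_image(opts$image %||% stop("option 'image' is required"),
                          size = model$config$input_size, normalize = FALSE)
  sal <- gradcam(model, normalize_image(img), layer = opts$layer)
  scsv <- file.path(out, "saliency.csv")
  utils::write.csv(sal$values, scsv, row.names = FALSE)
  grDevices::png(file.path(out, "saliency.png"), 480, 480)
  graphics::image(t(normalize_saliency(sal))[, nrow(sal$values):1],
                  col = grDevices::hcl.colors(64, "Inferno"),
                  main = sprintf("Grad-CAM (class %d)", sal$target_class))
  grDevices::dev.off()
  mf <- write_manifest(out, "explain", list(layer = sal$layer_id),
                       list(model = opts$model, image = opts$image),
                       list(saliency = scsv))
  list(saliency = scsv, manifest = mf)
}

run_faithfulness <- function(opts) {
  out <- ensure_out(opts)
  model <- load_model(opts$model %||% stop("option 'model' is required"))
  data <- load_image_tree(opts$data %||% stop("option 'data' is required"),
                          model$config$input_size)
  cfg <- blur_config(kernel = opts$kernel %||% 51L,
                     sigma = opts$sigma %||% 8.0,
                     steps = opts$steps %||% 50L)
  fr <- evaluate_faithfulness(model, data$x, data$y,
                              explainer = opts$explainer %||% "gradcam",
                              cfg = cfg, image_ids = data$ids,
                              seed = opts$seed %||% 1L)
  rcsv <- file.path(out, "faithfulness_per_image.csv")
  utils::write.csv(fr$results, rcsv, row.names = FALSE)
  sjson <- file.path(out, "faithfulness_summary.json")
  jsonlite::write_json(fr$summary, sjson, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  plot_faithfulness_curves(fr, file.path(out, "faithfulness_curves.png"),
                           label = opts$explainer %||% "gradcam")
  mf <- write_manifest(out, "faithfulness", unclass(cfg),
                       list(model = opts$model, data = opts$data),
                       list(per_image = rcsv, summary = sjson))
  list(per_image = rcsv, summary = sjson, manifest = mf)
}

run_compare <- function(opts) {
  out <- ensure_out(opts)
  a <- utils::read.csv(opts$a %||% stop("option 'a' is required"))
  b <- utils::read.csv(opts$b %||% stop("option 'b' is required"))
  if (!"image_id" %in% names(a) && "fold" %in% names(a)) {
    a$image_id <- a$fold; b$image_id <- b$fold   # fold-level comparison
  }
  pairing <- common_subset_pairing(a, b)
  metrics <- intersect(c("insertion_auc", "one_minus_deletion", "accuracy",
                         "macro_f1"), names(a))
  pairs <- lapply(metrics, function(m)
    list(a = pairing$a[[m]], b = pairing$b[[m]]))
  names(pairs) <- metrics
  tab <- paired_comparison_table(pairs)
  tab$n <- pairing$n
  ccsv <- file.path(out, "comparison.csv")
  utils::write.csv(tab, ccsv, row.names = FALSE)
  mf <- write_manifest(out, "compare", list(metrics = metrics),
                       list(a = opts$a, b = opts$b), list(comparison = ccsv))
  list(comparison = ccsv, manifest = mf)
}
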