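# Figure emission (PNG, base graphics): accuracy curves, confusion
# heat map, one-vs-rest ROC, mean insertion/deletion curves.

#' Plot per-epoch accuracy curves
#' @param history data frame from [train_model()].
#' @param file output PNG path.
#' @export
plot_history <- function(history, file) {
  grDevices::png(file, width = 720, height = 480)
  on.exit(grDevices::dev.off())
  graphics::plot(history$epoch, history$train_acc, type = "l", lwd = 2,
                 col = "steelblue", ylim = c(0, 1), xlab = "epoch",
                 ylab = "accuracy", main = "Training curves")
  if (!all(is.na(history$val_acc)))
    graphics::lines(history$epoch, history$val_acc, lwd = 2, col = "firebrick")
  graphics::legend("bottomright", c("train", "validation"),
                   col = c("steelblue", "firebrick"), lwd = 2, bty = "n")
  invisible(file)
}

#' Plot a confusion-matrix heat map
#' @param confusion K x K matrix (rows true, columns predicted).
#' @param file output PNG path.
#' @param class_names optional class labels.
#' @export
plot_confusion <- function(confusion, file, class_names = NULL) {
  K <- nrow(confusion)
  if (is.null(class_names)) class_names <- rownames(confusion)
  if (is.null(class_names)) class_names <- as.character(seq_len(K))
  grDevices::png(file, width = 560, height = 520)
  on.exit(grDevices::dev.off())
  graphics::image(seq_len(K), seq_len(K), t(confusion[K:1, , drop = FALSE]),
                  col = grDevices::hcl.colors(32, "Blues", rev = TRUE),
                  axes = FALSE, xlab = "predicted", ylab = "true",
                  main = "Confusion matrix")
  graphics::axis(1, seq_len(K), class_names)
  graphics::axis(2, seq_len(K), rev(class_names))
  for (i in seq_len(K)) for (j in seq_len(K))
    graphics::text(j, K - i + 1, confusion[i, j])
  invisible(file)
}

#' Plot one-vs-rest ROC curves
#' @param ovr result of [ovr_roc_auc()].
#' @param file output PNG path.
#' @param class_names optional class labels.
#' @export
plot_roc <- function(ovr, file, class_names = NULL) {
  K <- length(ovr$per_class)
  if (is.null(class_names)) class_names <- as.character(seq_len(K))
  grDevices::png(file, width = 560, height = 520)
  on.exit(grDevices::dev.off())
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 2, col = "grey",
                 xlab = "false positive rate", ylab = "true positive rate",
                 main = "One-vs-rest ROC")
  cols <- grDevices::hcl.colors(max(K, 2), "Dark 3")
  for (k in seq_len(K)) {
    r <- ovr$roc[[k]]
    if (!is.null(r)) graphics::lines(r$fpr, r$tpr, col = cols[k], lwd = 2)
  }
  graphics::legend("bottomright",
                   sprintf("%s (AUC %.3f)", class_names, ovr$per_class),
                   col = cols[seq_len(K)], lwd = 2, bty = "n")
  invisible(file)
}

#' Plot mean insertion/deletion curves
#'
#' Mean confidence (with a +-1 sd band) against the fraction of pixels
#' restored/removed, one panel per mode.
#'
#' @param fr result of [evaluate_faithfulness()].
#' @param file output PNG path.
#' @param label curve label (e.g. the explainer name).
#' @export
plot_faithfulness_curves <- function(fr, file, label = "Grad-CAM") {
  cv <- fr$curves
  grDevices::png(file, width = 900, height = 420)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, 2))
  for (mode in c("insertion", "deletion")) {
    m <- cv[[mode]]
    mu <- colMeans(m); sdv <- apply(m, 2, stats::sd)
    graphics::plot(cv$fractions, mu, type = "l", lwd = 2, ylim = c(0, 1),
                   xlab = "fraction of pixels", ylab = "confidence",
                   main = sprintf("%s (%s)", mode, label))
    graphics::polygon(c(cv$fractions, rev(cv$fractions)),
                      c(pmin(mu + sdv, 1), rev(pmax(mu - sdv, 0))),
                      col = grDevices::adjustcolor("steelblue", 0.25),
                      border = NA)
    graphics::lines(cv$fractions, mu, lwd = 2, col = "steelblue")
  }
  invisible(file)
}
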