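# Confusion-matrix metrics, macro averaging, and one-vs-rest ROC/AUC.

#' Confusion matrix and per-class / macro metrics
#'
#' Builds the K x K confusion matrix (rows = true, columns = predicted)
#' and derives per-class one-vs-rest TP/FP/TN/FN with
#' accuracy = (TP+TN)/(TP+FP+TN+FN), precision = TP/(TP+FP),
#' recall = TP/(TP+FN), F1 = 2PR/(P+R).  Macro values are unweighted
#' means over classes; `overall_accuracy` is trace/total.  Ratios with a
#' zero denominator are reported as 0 with a warning.
#'
#' @param true_labels,pred_labels integer labels in `1..K` (or factors
#'   with `K` levels).
#' @param K number of classes.
#' @return a `MetricsReport` list: `confusion`, `counts` (per-class
#'   TP/FP/TN/FN), `per_class`, `macro`, `overall_accuracy`, `n`.
#' @export
confusion_and_metrics <- function(true_labels, pred_labels, K) {
  true_labels <- as.integer(true_labels); pred_labels <- as.integer(pred_labels)
  if (length(true_labels) != length(pred_labels))
    stop("label vectors must have equal length")
  if (any(true_labels < 1L | true_labels > K) ||
      any(pred_labels < 1L | pred_labels > K))
    stop(sprintf("labels must lie in 1..K (K = %d)", K))
  n <- length(true_labels)
  cm <- table(factor(true_labels, levels = seq_len(K)),
              factor(pred_labels, levels = seq_len(K)))
  cm <- matrix(as.integer(cm), K, K,
               dimnames = list(true = seq_len(K), pred = seq_len(K)))
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- n - tp - fp - fn
  safe_div <- function(num, den, what) {
    bad <- den == 0
    if (any(bad))
      warning(sprintf("%s undefined for class(es) %s (zero denominator); reporting 0",
                      what, paste(which(bad), collapse = ",")), call. = FALSE)
    ifelse(bad, 0, num / den)
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- safe_div(2 * precision * recall, precision + recall, "F1")
  acc_c <- (tp + tn) / n
  list(confusion = cm,
       counts = data.frame(class = seq_len(K), tp = tp, fp = fp, tn = tn, fn = fn),
       per_class = data.frame(class = seq_len(K), accuracy = acc_c,
                              precision = precision, recall = recall, f1 = f1),
       macro = list(accuracy = mean(acc_c), precision = mean(precision),
                    recall = mean(recall), f1 = mean(f1)),
       overall_accuracy = sum(tp) / n,
       n = n)
}

# ROC curve of one score vector against binary truth; thresholds at every
# distinct score (ties collapsed), trapezoid AUC == Mann-Whitney with
# half-credit for ties
binary_roc <- function(truth, score) {
  ord <- order(score, decreasing = TRUE)
  truth <- truth[ord]; score <- score[ord]
  np <- sum(truth); nn <- sum(!truth)
  # collapse tied scores so the curve moves in blocks
  last_of_block <- c(score[-1] != score[-length(score)], TRUE)
  tp <- cumsum(truth)[last_of_block]
  fpn <- cumsum(!truth)[last_of_block]
  tpr <- c(0, tp / np)
  fpr <- c(0, fpn / nn)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}

#' One-vs-rest ROC curves and macro AUC
#'
#' For each class, the ROC of its score column against all remaining
#' classes pooled; AUC by the trapezoid rule over the ROC.  The macro AUC
#' is the unweighted mean of class AUCs; classes absent from
#' `true_labels` get `NA` and are excluded from the macro with a warning.
#'
#' @param true_labels integer labels `1..K`.
#' @param class_scores numeric `N x K` score matrix (higher = more
#'   confident).
#' @return list with `per_class` (AUC per class), `macro_auc` and `roc`
#'   (per-class ROC point lists for plotting).
#' @export
ovr_roc_auc <- function(true_labels, class_scores) {
  class_scores <- as.matrix(class_scores)
  K <- ncol(class_scores)
  true_labels <- as.integer(true_labels)
  stopifnot(length(true_labels) == nrow(class_scores))
  aucs <- rep(NA_real_, K)
  rocs <- vector("list", K)
  for (k in seq_len(K)) {
    truth <- true_labels == k
    if (!any(truth) || all(truth)) next
    r <- binary_roc(truth, class_scores[, k])
    aucs[k] <- r$auc
    rocs[[k]] <- r
  }
  if (anyNA(aucs))
    warning(sprintf("class(es) %s absent from true_labels; excluded from macro AUC",
                    paste(which(is.na(aucs)), collapse = ",")), call. = FALSE)
  list(per_class = aucs, macro_auc = mean(aucs, na.rm = TRUE), roc = rocs)
}
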