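# Confusion-matrix metrics, macro averaging, one-vs-rest ROC/AUC,
# stratified folds.

test_that("perfect predictions give all metrics 1", {
  y <- rep(1:4, each = 10)
  r <- confusion_and_metrics(y, y, 4)
  expect_equal(r$overall_accuracy, 1)
  expect_equal(r$macro$precision, 1)
  expect_equal(r$macro$recall, 1)
  expect_equal(r$macro$f1, 1)
  expect_equal(diag(r$confusion), rep(10L, 4), ignore_attr = TRUE)
})

test_that("the printed per-class correct counts give overall accuracy 0.9675", {
  # 4 classes x 100 test images, correct counts 100, 100, 92, 95
  truth <- rep(1:4, each = 100)
  pred <- truth
  pred[truth == 3][1:8] <- 1          # 8 misclassified out of class 3
  pred[truth == 4][1:5] <- 2          # 5 misclassified out of class 4
  r <- confusion_and_metrics(truth, pred, 4)
  expect_equal(diag(r$confusion), c(100L, 100L, 92L, 95L), ignore_attr = TRUE)
  expect_equal(r$overall_accuracy, 387 / 400)
  expect_equal(r$overall_accuracy, 0.9675)
})

test_that("2-class hand case matches the defining ratios", {
  # confusion ((8,2),(1,9)): overall 17/20; class-1 precision 8/9, recall 0.8
  truth <- c(rep(1, 10), rep(2, 10))
  pred <- c(rep(1, 8), 2, 2, 1, rep(2, 9))
  r <- confusion_and_metrics(truth, pred, 2)
  expect_equal(r$confusion, matrix(c(8L, 1L, 2L, 9L), 2, 2),
               ignore_attr = TRUE)
  expect_equal(r$overall_accuracy, 0.85)
  expect_equal(r$per_class$precision[1], 8 / 9)
  expect_equal(r$per_class$recall[1], 0.8)
})

test_that("metrics agree with an independent per-sample counting oracle", {
  set.seed(7)
  for (rep in 1:5) {
    K <- sample(2:5, 1)
    n <- 60
    truth <- sample(K, n, replace = TRUE)
    pred <- sample(K, n, replace = TRUE)
    truth[1:K] <- 1:K                    # ensure every class occurs
    r <- suppressWarnings(confusion_and_metrics(truth, pred, K))
    for (k in seq_len(K)) {
      tp <- sum(truth == k & pred == k)
      fp <- sum(truth != k & pred == k)
      fn <- sum(truth == k & pred != k)
      tn <- n - tp - fp - fn
      expect_equal(r$counts$tp[k], tp)
      expect_equal(r$counts$tn[k], tn)
      if (tp + fp > 0) expect_equal(r$per_class$precision[k], tp / (tp + fp))
      if (tp + fn > 0) expect_equal(r$per_class$recall[k], tp / (tp + fn))
      expect_equal(r$per_class$accuracy[k], (tp + tn) / n)
      expect_equal(r$counts$tp[k] + r$counts$fp[k] + r$counts$tn[k] +
                     r$counts$fn[k], n)
    }
    expect_equal(r$overall_accuracy, mean(truth == pred))
  }
})

test_that("zero-denominator ratios warn and report 0; F1 = P when P = R", {
  truth <- c(1, 1, 2, 2)
  pred <- c(1, 1, 1, 1)                 # class 2 never predicted
  expect_warning(r <- confusion_and_metrics(truth, pred, 2), "precision")
  expect_equal(r$per_class$precision[2], 0)
  # harmonic-mean fixed point
  y <- c(1, 1, 2, 2); p <- c(1, 2, 2, 1)
  r2 <- confusion_and_metrics(y, p, 2)
  expect_equal(r2$per_class$f1, r2$per_class$precision)
  expect_equal(r2$per_class$f1, r2$per_class$recall)
})

test_that("one-vs-rest AUC: one-hot scores give 1, constant scores give 0.5", {
  y <- rep(1:3, each = 5)
  onehot <- diag(3)[y, ]
  r <- ovr_roc_auc(y, onehot)
  expect_equal(r$per_class, rep(1, 3))
  expect_equal(r$macro_auc, 1)
  r0 <- ovr_roc_auc(y, matrix(0.3, 15, 3))
  expect_equal(r0$per_class, rep(0.5, 3))
})

test_that("binary AUC equals the Mann-Whitney pair-counting statistic", {
  # 6-sample hand case with a tie
  y <- c(1, 1, 1, 2, 2, 2)
  s <- c(0.9, 0.6, 0.4, 0.6, 0.3, 0.1)   # class-1 scores, one tied pair
  r <- ovr_roc_auc(y, cbind(s, 1 - s))
  pos <- s[y == 1]; neg <- s[y == 2]
  u <- 0
  for (p in pos) for (q in neg) u <- u + (p > q) + 0.5 * (p == q)
  expect_equal(r$per_class[1], u / (length(pos) * length(neg)))
  # cross-check against an independent ROC implementation
  skip_if_not_installed("pROC")
  proc_auc <- as.numeric(pROC::auc(pROC::roc(
    response = as.integer(y == 1), predictor = s, quiet = TRUE,
    direction = "<")))
  expect_equal(r$per_class[1], proc_auc)
})

test_that("ovr AUC on random scores matches pROC per class", {
  skip_if_not_installed("pROC")
  set.seed(11)
  y <- sample(1:3, 40, replace = TRUE)
  y[1:3] <- 1:3
  s <- matrix(runif(120), 40, 3)
  r <- ovr_roc_auc(y, s)
  for (k in 1:3) {
    pa <- as.numeric(pROC::auc(pROC::roc(response = as.integer(y == k),
                                         predictor = s[, k], quiet = TRUE,
                                         direction = "<")))
    expect_equal(r$per_class[k], pa, tolerance = 1e-12)
  }
})

test_that("a class absent from the truth is excluded from the macro with a warning", {
  y <- rep(1:2, each = 5)
  s <- matrix(runif(30), 10, 3)
  expect_warning(r <- ovr_roc_auc(y, s), "absent")
  expect_true(is.na(r$per_class[3]))
  expect_equal(r$macro_auc, mean(r$per_class[1:2]))
})

test_that("stratified folds: balanced 4x100 at k = 5 gives 80 with 20/class", {
  y <- rep(1:4, each = 100)
  folds <- stratified_kfold(y, k = 5, seed = 1)
  for (f in folds) {
    expect_equal(length(f$test), 80)
    expect_equal(as.vector(table(y[f$test])), rep(20, 4))
    expect_equal(sort(c(f$train, f$test)), seq_along(y))
  }
  # all test folds are disjoint
  all_test <- unlist(lapply(folds, `[[`, "test"))
  expect_equal(sort(all_test), seq_along(y))
})

test_that("fold proportions stay within one sample of global proportions", {
  set.seed(3)
  y <- sample(1:3, 83, replace = TRUE, prob = c(.5, .3, .2))
  y[1:9] <- rep(1:3, 3)
  folds <- stratified_kfold(y, k = 4, seed = 2)
  for (cl in 1:3) {
    per_fold <- vapply(folds, function(f) sum(y[f$test] == cl), 0L)
    expect_lte(max(per_fold) - min(per_fold), 1L)
  }
  expect_error(stratified_kfold(c(1, 1, 1, 2), k = 3), "fewer than k")
})
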