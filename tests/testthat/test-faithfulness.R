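# Insertion/deletion curves: blur baseline behavior, closed-form toys,
# endpoint contracts, trapezoid AUC, ordering optimality.

# toy scorer: "confidence" = mean intensity of a fixed support set in
# channel 1, clamped to [0, 1]; returns a 2-class probability matrix
toy_scorer <- function(support) {
  function(batch) {
    f <- apply(batch, 1, function(img) mean(img[, , 1][support]))
    f <- pmin(pmax(f, 0), 1)
    cbind(f, 1 - f)
  }
}

test_that("blur of a constant image is unchanged and kernel 1 is identity", {
  img <- array(0.37, c(16, 16, 3))
  out <- blur_baseline(img, blur_config(kernel = 7, sigma = 2))
  expect_equal(out, img, tolerance = 1e-7)
  set.seed(1)
  img2 <- array(runif(16 * 16 * 3), c(16, 16, 3))
  expect_identical(blur_baseline(img2, blur_config(kernel = 1, sigma = 1)), img2)
})

test_that("blur reduces total variation on random images", {
  set.seed(2)
  tv <- function(img) {
    s <- 0
    for (ch in 1:3) {
      m <- img[, , ch]
      s <- s + sum(abs(diff(m))) + sum(abs(t(diff(t(m)))))
    }
    s
  }
  for (rep in 1:5) {
    img <- array(runif(24 * 24 * 3), c(24, 24, 3))
    out <- blur_baseline(img, blur_config(kernel = 9, sigma = 3))
    expect_lt(tv(out), tv(img))
  }
})

test_that("even blur kernels are a configuration error", {
  expect_error(blur_config(kernel = 50), "odd")
  expect_error(blur_config(sigma = 0), "positive")
})

test_that("deletion/insertion on the 4x4 single-pixel toy are closed-form", {
  # region R = a 2x2 block of ones, rest zeros; scorer = mean of R;
  # saliency = indicator of R; zero baseline; 16 single-pixel steps
  img <- array(0, c(4, 4, 3))
  support <- cbind(c(1, 1, 2, 2), c(1, 2, 1, 2))
  img[, , 1][support] <- 1
  sal <- matrix(0, 4, 4); sal[support] <- 1
  sc <- toy_scorer(support)
  cfg <- blur_config(kernel = 3, sigma = 1, steps = 16)
  dc <- deletion_curve(sc, img, sal, target_class = 1, cfg, baseline = "black")
  expect_equal(dc$fractions, (0:16) / 16)
  expect_equal(dc$confidences, c(1, .75, .5, .25, rep(0, 13)))
  ic <- insertion_curve(sc, img, sal, target_class = 1, cfg, baseline = "black")
  expect_equal(ic$confidences, c(0, .25, .5, .75, rep(1, 13)))
  expect_equal(auc_trapezoid(ic), 14 / 16)         # stated closed form
  # endpoint symmetry: insertion at t=1 and deletion at t=0 are the original
  expect_equal(ic$confidences[17], dc$confidences[1])
})

test_that("a constant model yields a constant curve", {
  const_scorer <- function(batch) matrix(c(0.42, 0.58), nrow = dim(batch)[1],
                                         ncol = 2, byrow = TRUE)
  set.seed(3)
  img <- array(runif(8 * 8 * 3), c(8, 8, 3))
  sal <- matrix(runif(64), 8, 8)
  dc <- deletion_curve(const_scorer, img, sal, 1, blur_config(steps = 10))
  expect_equal(dc$confidences, rep(0.42, 11))
})

test_that("curve endpoints are the original and fully-substituted images", {
  set.seed(4)
  img <- array(runif(8 * 8 * 3), c(8, 8, 3))
  support <- cbind(rep(1:3, 3), rep(1:3, each = 3))
  sc <- toy_scorer(support)
  cfg <- blur_config(kernel = 5, sigma = 2, steps = 7)
  base <- blur_baseline(img, cfg)
  sal <- matrix(runif(64), 8, 8)
  dc <- deletion_curve(sc, img, sal, 1, cfg)
  expect_equal(dc$confidences[1], unname(sc(array(img, c(1, dim(img))))[1, 1]))
  expect_equal(dc$confidences[8], unname(sc(array(base, c(1, dim(base))))[1, 1]))
  # permuting the saliency changes the path but not the endpoints
  sal2 <- matrix(sample(as.vector(sal)), 8, 8)
  dc2 <- deletion_curve(sc, img, sal2, 1, cfg)
  expect_equal(dc2$confidences[c(1, 8)], dc$confidences[c(1, 8)])
})

test_that("trapezoid AUC: constant one is 1, linear ramp is 1/2, and short
           curves are rejected", {
  cv <- list(fractions = seq(0, 1, length.out = 11), confidences = rep(1, 11))
  expect_equal(auc_trapezoid(cv), 1)
  cv$confidences <- seq(0, 1, length.out = 11)
  expect_equal(auc_trapezoid(cv), 0.5)
  expect_error(auc_trapezoid(list(fractions = 0, confidences = 1)),
               "at least 2")
})

test_that("the true-support saliency maximizes insertion AUC over all
           support placements (3x3 exhaustive oracle)", {
  img <- array(0, c(3, 3, 3))
  support <- cbind(c(1, 2, 3), c(1, 2, 3))
  img[, , 1][support] <- 1
  sc <- toy_scorer(support)
  cfg <- blur_config(kernel = 3, sigma = 1, steps = 9)
  # enumerate every way to place the 3 support pixels among the 9 ranks
  rank_sets <- utils::combn(9, 3)
  sup_lin <- support[, 1] + (support[, 2] - 1) * 3
  aucs <- apply(rank_sets, 2, function(rs) {
    # saliency whose descending order puts the support pixels at ranks rs:
    # the pixel ranked r gets value 10 - r
    sal_vals <- numeric(9)
    sal_vals[sup_lin] <- 10 - rs
    sal_vals[setdiff(1:9, sup_lin)] <- 10 - setdiff(1:9, rs)
    sal <- matrix(sal_vals, 3, 3)
    auc_trapezoid(insertion_curve(sc, img, sal, 1, cfg, baseline = "black"))
  })
  best <- which.max(aucs)
  expect_equal(rank_sets[, best], 1:3)             # support first is optimal
  expect_equal(max(aucs), aucs[1])
})

test_that("correct-only protocol includes exactly the correct images", {
  fit <- trained_tiny()
  ph <- phantom_set()
  sub <- ph$val_idx[1:12]
  pred <- predict(fit$model, ph$norm[sub, , , ], type = "class")
  fr <- evaluate_faithfulness(fit$model, ph$images[sub, , , ], ph$labels[sub],
                              explainer = "random",
                              cfg = blur_config(steps = 5),
                              image_ids = ph$ids[sub], seed = 1)
  expect_equal(nrow(fr$results), sum(pred == ph$labels[sub]))
  expect_equal(fr$results$one_minus_deletion,
               1 - fr$results$deletion_auc)        # exact arithmetic identity
  expect_true(all(fr$results$insertion_auc >= 0 & fr$results$insertion_auc <= 1))
  fr_all <- evaluate_faithfulness(fit$model, ph$images[sub, , , ],
                                  ph$labels[sub], explainer = "random",
                                  cfg = blur_config(steps = 5),
                                  correct_only = FALSE,
                                  image_ids = ph$ids[sub], seed = 1)
  expect_equal(nrow(fr_all$results), length(sub))
  # labels chosen so that no prediction can match -> explicit error
  wrong <- (pred %% 4) + 1
  expect_error(
    evaluate_faithfulness(fit$model, ph$images[sub, , , ], wrong,
                          explainer = "random", cfg = blur_config(steps = 5),
                          image_ids = ph$ids[sub], seed = 1),
    "no images included")
})

test_that("non-finite saliency is a validation error", {
  sc <- toy_scorer(cbind(1, 1))
  img <- array(0.5, c(4, 4, 3))
  sal <- matrix(1, 4, 4); sal[2, 2] <- NA
  expect_error(deletion_curve(sc, img, sal, 1, blur_config(steps = 4)),
               "non-finite")
  expect_error(deletion_curve(sc, img, matrix(1, 3, 3), 1,
                              blur_config(steps = 4)), "does not match")
})
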