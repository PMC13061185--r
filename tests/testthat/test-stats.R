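# Statistical machinery: bootstrap, paired t, exact Wilcoxon signed-rank,
# Holm step-down, common-subset pairing.

test_that("bootstrap CI of a constant sample is zero-width at the constant", {
  ci <- bootstrap_mean_ci(rep(3.7, 10), n_boot = 500, seed = 1)
  expect_equal(ci$mean, 3.7)
  expect_equal(ci$low, 3.7)
  expect_equal(ci$high, 3.7)
})

test_that("bootstrap is reproducible per seed and differs across seeds", {
  x <- rnorm(20)
  a <- bootstrap_mean_ci(x, n_boot = 1000, seed = 5)
  b <- bootstrap_mean_ci(x, n_boot = 1000, seed = 5)
  c_ <- bootstrap_mean_ci(x, n_boot = 1000, seed = 6)
  expect_identical(a, b)
  expect_false(identical(a$low, c_$low))
  expect_error(bootstrap_mean_ci(numeric(0)), "non-empty")
})

test_that("exhaustive bootstrap on (1,2,3) matches full 27-resample enumeration", {
  x <- c(1, 2, 3)
  got <- bootstrap_mean_ci(x, alpha = 0.05, exhaustive = TRUE)
  # oracle: enumerate all 3^3 resamples directly
  grid <- expand.grid(1:3, 1:3, 1:3)
  means <- apply(grid, 1, function(ii) mean(x[ii]))
  q <- quantile(means, c(0.025, 0.975), names = FALSE)
  expect_equal(got$low, q[1])
  expect_equal(got$high, q[2])
  expect_equal(got$mean, 2)
})

test_that("bootstrap CI width shrinks roughly as 1/sqrt(n)", {
  set.seed(9)
  x1 <- rnorm(50); x2 <- rnorm(450)
  w1 <- with(bootstrap_mean_ci(x1, n_boot = 3000, seed = 2), high - low)
  w2 <- with(bootstrap_mean_ci(x2, n_boot = 3000, seed = 2), high - low)
  expect_gt(w1 / w2, 2)                  # expected ratio 3, generous band
  expect_lt(w1 / w2, 4.5)
})

test_that("paired t-test: delta is the mean difference; degenerate input errors", {
  a <- c(1, 2, 3, 4, 5); b <- c(0.5, 2.5, 2, 4.5, 4)
  r <- paired_t_test(a, b)
  expect_equal(r$delta, mean(a) - mean(b))
  expect_true(r$ci_low <= r$delta && r$delta <= r$ci_high)
  expect_equal(r$df, 4)
  # matches the base implementation it wraps
  expect_equal(r$p, t.test(a, b, paired = TRUE)$p.value)
  expect_error(paired_t_test(a, a + 2), "degenerate")
  expect_error(paired_t_test(1, 2), "at least 2")
})

test_that("widening the confidence level widens the CI monotonically", {
  a <- c(0.1, 0.4, 0.3, 0.9, 0.6); b <- c(0.2, 0.1, 0.4, 0.5, 0.3)
  w90 <- with(paired_t_test(a, b, conf_level = 0.90), ci_high - ci_low)
  w95 <- with(paired_t_test(a, b, conf_level = 0.95), ci_high - ci_low)
  w99 <- with(paired_t_test(a, b, conf_level = 0.99), ci_high - ci_low)
  expect_true(w90 < w95 && w95 < w99)
})

test_that("fold means 0.9494 vs 0.9319 give delta +0.0175 (mean-difference identity)", {
  # five fold-wise accuracy pairs constructed to have the stated means;
  # the paired delta depends only on the means
  spread <- c(-0.010, -0.005, 0, 0.005, 0.010)
  a <- 0.9494 + spread
  b <- 0.9319 + rev(spread)
  expect_equal(paired_t_test(a, b)$delta, 0.0175, tolerance = 1e-12)
})

test_that("exact Wilcoxon floor: n = 5 same-sign differences give p = 0.0625", {
  # regardless of magnitudes, with all five differences positive the
  # two-sided exact p is 2/2^5
  expect_equal(wilcoxon_signed_rank(c(5, 1, 9, 2.2, 4), c(1, 0.5, 3, 2.1, 0.2)),
               0.0625)
  expect_equal(wilcoxon_signed_rank(1:5 + c(.1, .2, .3, .4, .5), 1:5), 0.0625)
})

test_that("Wilcoxon is symmetric under swapping the samples", {
  set.seed(4)
  a <- rnorm(12); b <- rnorm(12)
  expect_equal(wilcoxon_signed_rank(a, b), wilcoxon_signed_rank(b, a))
})

test_that("Wilcoxon matches a full 2^6 enumeration oracle (with ties)", {
  a <- c(3, 1, 4, 1.5, 9, 2.6)
  b <- c(2, 2, 2, 2, 2, 2.0)
  d <- a - b
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  # oracle: enumerate every sign assignment of the 6 ranks
  ws <- apply(expand.grid(rep(list(c(0, 1)), 6)), 1, function(s) sum(r[s == 1]))
  p_le <- mean(ws <= obs + 1e-9)
  p_ge <- mean(ws >= obs - 1e-9)
  expect_equal(wilcoxon_signed_rank(a, b), min(1, 2 * min(p_le, p_ge)))
})

test_that("Wilcoxon agrees with stats::wilcox.test in the tie-free exact case", {
  set.seed(8)
  for (rep in 1:5) {
    a <- rnorm(10); b <- rnorm(10)
    expect_equal(wilcoxon_signed_rank(a, b),
                 wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  expect_error(wilcoxon_signed_rank(c(1, 2), c(1, 2)), "zero")
})

test_that("Holm step-down: hand cases and elementwise dominance", {
  expect_equal(holm_adjust(0.03), 0.03)                       # m = 1
  expect_equal(holm_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.06, 0.06, 0.06))                     # hand step-down
  expect_equal(holm_adjust(rep(0.02, 4)), rep(0.08, 4))       # cumulative max
  set.seed(2)
  p <- runif(7)
  expect_true(all(holm_adjust(p) >= p))
  expect_true(all(holm_adjust(p) <= 1))
  expect_error(holm_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("common_subset_pairing intersects by id with consistent order", {
  a <- data.frame(image_id = c("c", "a", "b"), v = 1:3)
  b <- data.frame(image_id = c("b", "d", "a"), v = 4:6)
  pr <- common_subset_pairing(a, b)
  expect_equal(pr$n, 2)
  expect_equal(pr$ids, c("a", "b"))
  expect_equal(pr$a$v, c(2, 3))
  expect_equal(pr$b$v, c(6, 4))
  expect_error(common_subset_pairing(a, data.frame(image_id = "zz", v = 1)),
               "empty intersection")
  expect_error(common_subset_pairing(rbind(a, a[1, ]), b), "unique")
})

test_that("379 and 377 ids sharing 369 pair to n = 369", {
  shared <- sprintf("img_%04d", 1:369)
  a <- data.frame(image_id = c(shared, sprintf("a_%02d", 1:10)), v = 1)
  b <- data.frame(image_id = c(shared, sprintf("b_%02d", 1:8)), v = 2)
  expect_equal(nrow(a), 379)
  expect_equal(nrow(b), 377)
  expect_equal(common_subset_pairing(a, b)$n, 369)
})

test_that("paired_comparison_table fills delta, CIs and Holm family", {
  set.seed(5)
  pairs <- list(
    m1 = list(a = rnorm(5, 1), b = rnorm(5)),
    m2 = list(a = rnorm(5, 0.5), b = rnorm(5)),
    m3 = list(a = rnorm(5), b = rnorm(5)),
    m4 = list(a = rnorm(5), b = rnorm(5)))
  tab <- paired_comparison_table(pairs)
  expect_equal(nrow(tab), 4)
  expect_true(all(tab$p_holm >= tab$p_t))
  expect_equal(tab$p_holm, as.vector(p.adjust(tab$p_t, "holm")))
  expect_true(all(tab$ci_low <= tab$delta & tab$delta <= tab$ci_high))
})
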