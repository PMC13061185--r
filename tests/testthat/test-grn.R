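# Global Response Normalization: the three-phase formula, its residual
# identity, scale covariance, gradients, and the GRN-MLP composition.

test_that("grn_apply is the identity at gamma = beta = 0 and on zeros", {
  set.seed(1)
  x <- array(rnorm(2 * 4 * 4 * 3), c(2, 4, 4, 3))
  expect_identical(grn_apply(x, numeric(3), numeric(3)), x)
  z <- array(0, c(1, 2, 2, 2))
  expect_identical(grn_apply(z, numeric(2), numeric(2)), z)
  # zero input stays zero for any gamma/beta = 0 scaling of it
  expect_equal(grn_apply(z, c(0, 0), c(0, 0)), z)
})

test_that("grn_apply matches the hand-computed three-phase example", {
  # 2 channels over a 1x2 grid: channel 1 = (3,4) so g1 = 5; channel 2 = 0
  # so g2 = 0; mean norm 2.5; n = (2, 0); gamma = 1, beta = 0, eps ~ 0:
  # channel 1 -> (9, 12) (= x*n + x), channel 2 stays 0
  x <- array(0, c(1, 1, 2, 2))
  x[1, 1, , 1] <- c(3, 4)
  out <- grn_apply(x, gamma = c(1, 1), beta = c(0, 0), eps = 1e-14)
  expect_equal(out[1, 1, , 1], c(9, 12), tolerance = 1e-9)
  expect_equal(out[1, 1, , 2], c(0, 0))
})

test_that("grn_apply agrees with an independent per-element script", {
  # straight-line reimplementation with explicit loops, per sample
  oracle <- function(x, gamma, beta, eps) {
    out <- x
    for (n in seq_len(dim(x)[1])) {
      g <- sapply(seq_len(dim(x)[4]), function(c) sqrt(sum(x[n, , , c]^2)))
      nn <- g / (mean(g) + eps)
      for (c in seq_len(dim(x)[4]))
        out[n, , , c] <- gamma[c] * (x[n, , , c] * nn[c]) + beta[c] + x[n, , , c]
    }
    out
  }
  set.seed(7)
  x <- array(rnorm(3 * 2 * 5 * 4), c(3, 2, 5, 4))
  gam <- rnorm(4); bet <- rnorm(4)
  expect_equal(grn_apply(x, gam, bet, 1e-6), oracle(x, gam, bet, 1e-6),
               tolerance = 1e-12)
})

test_that("grn normalization is covariant under positive input scaling", {
  # scaling x by s > 0 scales every g_c and their mean by s, so n is
  # unchanged in the eps -> 0 limit
  set.seed(3)
  x <- array(rnorm(1 * 4 * 4 * 3), c(1, 4, 4, 3))
  gam <- rep(1, 3); bet <- numeric(3)
  base <- grn_apply(x, gam, bet, eps = 1e-14) - x       # = gamma * x * n
  scaled <- grn_apply(3 * x, gam, bet, eps = 1e-14) - 3 * x
  expect_equal(scaled / 3, base, tolerance = 1e-9)      # same n
})

test_that("grn_apply validates inputs", {
  x <- array(1, c(1, 2, 2, 3))
  expect_error(grn_apply(x, numeric(2), numeric(3)), "length C")
  xb <- x; xb[1] <- NA
  expect_error(grn_apply(xb, numeric(3), numeric(3)), "non-finite")
})

test_that("grn backward matches finite differences", {
  set.seed(11)
  x <- array(rnorm(2 * 3 * 3 * 4), c(2, 3, 3, 4))
  gam <- rnorm(4) * 0.5; bet <- rnorm(4) * 0.5
  w <- array(rnorm(length(x)), dim(x))
  fw <- maxgrnet:::grn_forward(x, gam, bet, 1e-6)
  bk <- maxgrnet:::grn_backward(w, fw$cache)
  f <- function(xx) sum(w * maxgrnet:::grn_forward(array(xx, dim(x)), gam, bet, 1e-6)$out)
  expect_lt(max(abs(bk$dx - num_grad(f, x))), 1e-6)
  fg <- function(gg) sum(w * maxgrnet:::grn_forward(x, gg, bet, 1e-6)$out)
  expect_lt(max(abs(bk$dgamma - num_grad(fg, gam))), 1e-6)
})

test_that("grn_mlp_forward composes expansion, GELU, GRN and projection", {
  set.seed(5)
  C <- 8L
  p <- maxgrnet:::init_grnmlp_params(C, 2, grn_enabled = TRUE)
  x <- matrix(rnorm(4 * C), 4, C)                       # 4 tokens = 2x2 grid
  out <- grn_mlp_forward(x, p, grn_enabled = TRUE)
  # independent straight-line oracle
  h <- x %*% p$W1
  a <- h * pnorm(h)                                      # exact GELU
  a4 <- array(0, c(1, 2, 2, ncol(a))); a4[1, , , ] <- array(a, c(2, 2, ncol(a)))
  g <- grn_apply(a4, p$gamma, p$beta, 1e-6)
  z <- matrix(g, 4, ncol(a))
  expect_equal(out, z %*% p$W2 + matrix(p$b2, 4, C, byrow = TRUE),
               tolerance = 1e-12)
})

test_that("grn_mlp with GRN off equals the on-path at zero gamma/beta, and
           zero projection gives zero output", {
  set.seed(6)
  C <- 6L
  p <- maxgrnet:::init_grnmlp_params(C, 2, grn_enabled = TRUE)
  p$gamma <- numeric(length(p$gamma)); p$beta <- numeric(length(p$beta))
  x <- matrix(rnorm(9 * C), 9, C)                        # 3x3 grid
  expect_equal(grn_mlp_forward(x, p, grn_enabled = TRUE),
               grn_mlp_forward(x, p, grn_enabled = FALSE), tolerance = 1e-12)
  p0 <- p; p0$W2[] <- 0; p0$b2[] <- 0
  expect_equal(grn_mlp_forward(x, p0), matrix(0, 9, C))
})

test_that("grn_mlp rejects token counts that are not a spatial grid", {
  p <- maxgrnet:::init_grnmlp_params(4L, 2, TRUE)
  x <- matrix(rnorm(5 * 4), 5, 4)
  expect_error(grn_mlp_forward(x, p), "perfect spatial grid")
  expect_error(grn_mlp_forward(x, p, grid = c(2, 2)), "token count")
})
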