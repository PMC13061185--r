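# Global Response Normalization (GRN) and the GRN-MLP feed-forward block.
#
# GRN recalibrates channels using a global spatial statistic, in three
# phases computed independently per sample:
#   aggregation    g_c = ||x_c||_2 over all spatial positions,
#   normalization  n_c = g_c / (mean_c g_c + eps),
#   calibration    y   = gamma_c * (x * n_c) + beta_c + x.
# The residual term makes the layer the identity when gamma = beta = 0,
# which is also the initialization, so enabling GRN never perturbs a model
# at initialization.  gamma/beta are learnable per-channel parameters; a
# freeze switch keeps them pinned at zero for the parameter-free reading
# of the operator.

# core forward on an NHWC array; returns cache for the backward pass
grn_forward <- function(x, gamma, beta, eps = 1e-6) {
  d <- dim(x); N <- d[1]; sp <- d[2] * d[3]; C <- d[4]
  xm <- nhwc_mat(x)
  grp <- rep(seq_len(N), sp)
  g <- sqrt(rowsum(xm * xm, grp))               # (N, C) spatial L2 norms
  m <- rowMeans(g) + eps                        # per-sample mean of norms
  n <- g / m
  coef <- scale_cols(n, gamma)                  # gamma_c * n_{s,c}
  coefexp <- coef[grp, , drop = FALSE]
  outm <- xm * (coefexp + 1)
  outm <- shift_cols(outm, beta)
  out <- outm; dim(out) <- d
  list(out = out,
       cache = list(xm = xm, grp = grp, g = g, m = m, n = n,
                    coefexp = coefexp, gamma = gamma, dims = d))
}

grn_backward <- function(dout, cache) {
  d <- cache$dims; C <- d[4]
  doutm <- dout; dim(doutm) <- c(prod(d[1:3]), C)
  xm <- cache$xm; grp <- cache$grp
  dbeta <- colSums(doutm)
  sx <- rowsum(doutm * xm, grp)                 # (N, C): sum dout*x per ch
  dgamma <- colSums(sx * cache$n)
  dn <- scale_cols(sx, cache$gamma)             # dL/dn
  # n_c = g_c / m, m = mean_c(g) + eps:
  #   dg_k = dn_k / m - sum_c(dn_c g_c) / (m^2 C)
  dg <- dn / cache$m - rowSums(dn * cache$g) / (cache$m^2 * C)
  # g_c = ||x_c||  =>  d g_c / d x = x / g_c (0 where g_c = 0)
  gsafe <- cache$g
  ratio <- ifelse(gsafe > 0, dg / pmax(gsafe, .Machine$double.xmin), 0)
  dxm <- doutm * (cache$coefexp + 1) + xm * ratio[grp, , drop = FALSE]
  dx <- dxm; dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

#' Apply Global Response Normalization
#'
#' Recalibrates the channels of a feature map by its global spatial
#' statistics.  For each sample independently, `g_c` is the L2 norm of
#' channel `c` over all spatial positions, `n_c = g_c / (mean_c(g) + eps)`,
#' and the output is `gamma_c * (x * n_c) + beta_c + x`.  The residual term
#' means `gamma = beta = 0` gives the identity.
#'
#' @param x feature map: numeric array with axes `(H, W, C)` or
#'   `(N, H, W, C)`; all values finite.
#' @param gamma,beta per-channel scale and offset, each of length `C`.
#' @param eps small positive stabilizer added to the channel-mean of norms.
#' @return an array of the same shape as `x`.
#' @examples
#' x <- array(rnorm(2 * 4 * 4 * 3), c(2, 4, 4, 3))
#' identical(grn_apply(x, rep(0, 3), rep(0, 3)), x)  # identity at zero init
#' @export
grn_apply <- function(x, gamma, beta, eps = 1e-6) {
  x3 <- length(dim(x)) == 3L
  x <- as_nhwc(x)
  check_finite(x)
  C <- dim(x)[4]
  if (length(gamma) != C || length(beta) != C)
    stop(sprintf("gamma/beta must have length C = %d (got %d/%d)",
                 C, length(gamma), length(beta)))
  if (!is.numeric(eps) || eps < 0) stop("eps must be a non-negative scalar")
  out <- grn_forward(x, gamma, beta, eps)$out
  if (x3) dim(out) <- dim(out)[2:4]
  out
}

## ---- GRN-MLP ------------------------------------------------------------

# The transformer feed-forward block with GRN inserted between expansion and
# projection: fc1 (C -> C*expansion) -> GELU -> GRN (spatial, full grid) ->
# fc2 (-> C).  With grn_enabled = FALSE the GRN step is skipped (the plain
# MaxViT-style MLP).  Operates on an NHWC array so the GRN spatial
# aggregation sees the full feature-map grid.
grnmlp_forward <- function(x, p, grn_enabled = TRUE, grn_eps = 1e-6) {
  d <- dim(x)
  xm <- nhwc_mat(x)
  l1 <- linear_forward(xm, p$W1, p$b1)
  a <- gelu(l1$out)
  Ce <- ncol(a)
  if (grn_enabled) {
    a4 <- a; dim(a4) <- c(d[1:3], Ce)
    gr <- grn_forward(a4, p$gamma, p$beta, grn_eps)
    z <- nhwc_mat(gr$out)
  } else {
    gr <- NULL
    z <- a
  }
  l2 <- linear_forward(z, p$W2, p$b2)
  out <- l2$out; dim(out) <- c(d[1:3], ncol(p$W2))
  list(out = out,
       cache = list(l1 = l1$cache, z1 = l1$out, gr = gr$cache, l2 = l2$cache,
                    grn_enabled = grn_enabled, dims = d, Ce = Ce))
}

grnmlp_backward <- function(dout, cache) {
  d <- cache$dims
  Cout <- dim(dout)[4]
  doutm <- dout; dim(doutm) <- c(prod(d[1:3]), Cout)
  b2 <- linear_backward(doutm, cache$l2)
  if (cache$grn_enabled) {
    dz <- b2$dx; dim(dz) <- c(d[1:3], cache$Ce)
    gb <- grn_backward(dz, cache$gr)
    da <- nhwc_mat(gb$dx)
    dgamma <- gb$dgamma; dbeta <- gb$dbeta
  } else {
    da <- b2$dx
    dgamma <- NULL; dbeta <- NULL
  }
  dz1 <- da * gelu_grad(cache$z1)
  b1 <- linear_backward(dz1, cache$l1)
  dx <- b1$dx; dim(dx) <- d
  out <- list(dx = dx, dW1 = b1$dW, db1 = b1$db, dW2 = b2$dW, db2 = b2$db)
  if (!is.null(dgamma)) { out$dgamma <- dgamma; out$dbeta <- dbeta }
  out
}

#' Initialize parameters for a GRN-MLP block
#'
#' @param C input/output width.
#' @param expansion hidden/input width ratio.
#' @param grn_enabled include GRN gamma/beta (initialized to zero).
#' @export
init_grnmlp_params <- function(C, expansion, grn_enabled) {
  Ce <- as.integer(round(C * expansion))
  p <- list(W1 = matrix(trunc_normal_fan(C * Ce, C), C, Ce), b1 = numeric(Ce),
            W2 = matrix(trunc_normal_fan(Ce * C, Ce), Ce, C), b2 = numeric(C))
  if (grn_enabled) { p$gamma <- numeric(Ce); p$beta <- numeric(Ce) }
  p
}

#' Feed-forward (GRN-MLP) block of a transformer layer
#'
#' Pointwise expansion to `C * mlp_expansion` channels, GELU, Global
#' Response Normalization on the expanded representation (tokens reshaped
#' to their spatial grid so the L2 aggregation is spatial), and pointwise
#' projection back to `C`.  When `grn_enabled` is `FALSE` the GRN step is
#' skipped, giving the plain MaxViT-style MLP.  The transformer block's
#' outer residual is *not* included here.
#'
#' @param x token array `(tokens, C)` or NHWC array `(N, H, W, C)`.
#' @param params list with `W1`, `b1`, `W2`, `b2` and (when GRN is enabled)
#'   `gamma`, `beta` on the expanded width; see [init_grnmlp_params()] users
#'   such as [maxgrnet()].
#' @param grn_enabled logical; apply the GRN step.
#' @param grn_eps GRN stabilizer.
#' @param grid spatial extent `c(H, W)` of the tokens when `x` is a token
#'   matrix; defaults to a square grid, and errors if the token count is
#'   not a perfect spatial grid.
#' @return same shape as `x`.
#' @export
grn_mlp_forward <- function(x, params, grn_enabled = TRUE, grn_eps = 1e-6,
                            grid = NULL) {
  tokens_in <- is.matrix(x)
  if (tokens_in) {
    t_n <- nrow(x)
    if (is.null(grid)) {
      s <- sqrt(t_n)
      if (s != floor(s))
        stop(sprintf("token count %d is not a perfect spatial grid; pass `grid`", t_n))
      grid <- c(s, s)
    }
    if (prod(grid) != t_n)
      stop("prod(grid) must equal the token count")
    x4 <- x; dim(x4) <- c(1L, grid[1], grid[2], ncol(x))
  } else {
    x4 <- as_nhwc(x)
  }
  out <- grnmlp_forward(x4, params, grn_enabled, grn_eps)$out
  if (tokens_in) dim(out) <- c(prod(grid), dim(out)[4])
  out
}
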