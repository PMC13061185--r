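# Primitive differentiable layers.  Every layer comes as a *_forward()
# returning list(out, cache) and a *_backward(dout, cache) returning
# list(dx, <parameter gradients>).  The backward passes are hand-derived
# and verified against central finite differences in the test suite.

## ---- linear -----------------------------------------------------------

linear_forward <- function(x, W, b) {
  out <- x %*% W
  if (!is.null(b)) out <- shift_cols(out, b)
  list(out = out, cache = list(x = x, W = W))
}

linear_backward <- function(dout, cache) {
  list(dx = dout %*% t(cache$W),
       dW = crossprod(cache$x, dout),
       db = colSums(dout))
}

## ---- layer normalization (over channels, per token/position) ----------

ln_forward <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  out <- shift_cols(scale_cols(xhat, g), b)
  list(out = out, cache = list(xhat = xhat, inv = inv, g = g))
}

ln_backward <- function(dout, cache) {
  xhat <- cache$xhat
  dxhat <- scale_cols(dout, cache$g)
  dg <- colSums(dout * xhat)
  db <- colSums(dout)
  dx <- cache$inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = dg, db = db)
}

## ---- 2-D convolution via im2col + GEMM --------------------------------

pad_nhwc <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  xp <- zeros(d[1], d[2] + 2 * p, d[3] + 2 * p, d[4])
  xp[, p + seq_len(d[2]), p + seq_len(d[3]), ] <- x
  xp
}

im2col <- function(xp, k, stride, Ho, Wo) {
  d <- dim(xp); N <- d[1]; C <- d[4]
  cols <- zeros(N, Ho, Wo, k * k * C)
  t <- 0L
  for (di in seq_len(k)) for (dj in seq_len(k)) {
    ri <- seq(di, by = stride, length.out = Ho)
    ci <- seq(dj, by = stride, length.out = Wo)
    cols[, , , t * C + seq_len(C)] <- xp[, ri, ci, , drop = FALSE]
    t <- t + 1L
  }
  cols
}

col2im_add <- function(dcols, dims_xp, k, stride, Ho, Wo) {
  C <- dims_xp[4]
  dxp <- array(0, dims_xp)
  t <- 0L
  for (di in seq_len(k)) for (dj in seq_len(k)) {
    ri <- seq(di, by = stride, length.out = Ho)
    ci <- seq(dj, by = stride, length.out = Wo)
    dxp[, ri, ci, ] <- dxp[, ri, ci, , drop = FALSE] +
      dcols[, , , t * C + seq_len(C), drop = FALSE]
    t <- t + 1L
  }
  dxp
}

# W: (k*k*Cin, Cout), b: (Cout)
conv2d_forward <- function(x, W, b, k, stride = 1L, pad = 0L) {
  d <- dim(x); N <- d[1]; H <- d[2]; Wd <- d[3]
  Ho <- (H + 2L * pad - k) %/% stride + 1L
  Wo <- (Wd + 2L * pad - k) %/% stride + 1L
  xp <- pad_nhwc(x, pad)
  cols <- im2col(xp, k, stride, Ho, Wo)
  m <- cols; dim(m) <- c(N * Ho * Wo, k * k * d[4])
  out <- shift_cols(m %*% W, b)
  dim(out) <- c(N, Ho, Wo, ncol(W))
  list(out = out,
       cache = list(m = m, W = W, k = k, stride = stride, pad = pad,
                    dims_xp = dim(xp), Ho = Ho, Wo = Wo, dims_x = d))
}

conv2d_backward <- function(dout, cache) {
  d <- dim(dout); N <- d[1]; Ho <- d[2]; Wo <- d[3]; Cout <- d[4]
  doutm <- dout; dim(doutm) <- c(N * Ho * Wo, Cout)
  dW <- crossprod(cache$m, doutm)
  db <- colSums(doutm)
  dcols <- doutm %*% t(cache$W)
  dim(dcols) <- c(N, Ho, Wo, ncol(cache$m))
  dxp <- col2im_add(dcols, cache$dims_xp, cache$k, cache$stride, Ho, Wo)
  p <- cache$pad
  dx <- if (p > 0L)
    dxp[, p + seq_len(cache$dims_x[2]), p + seq_len(cache$dims_x[3]), , drop = FALSE]
  else dxp
  list(dx = dx, dW = dW, db = db)
}

## ---- depthwise 3x3 convolution -----------------------------------------

# W: (k*k, C), b: (C)
dwconv_forward <- function(x, W, b, k = 3L, stride = 1L, pad = 1L) {
  d <- dim(x); N <- d[1]; H <- d[2]; Wd <- d[3]; C <- d[4]
  Ho <- (H + 2L * pad - k) %/% stride + 1L
  Wo <- (Wd + 2L * pad - k) %/% stride + 1L
  xp <- pad_nhwc(x, pad)
  cols <- im2col(xp, k, stride, Ho, Wo)          # (N,Ho,Wo,k*k*C)
  acc <- matrix(rep(b, each = N * Ho * Wo), N * Ho * Wo, C)
  for (t in seq_len(k * k)) {
    sl <- cols[, , , (t - 1L) * C + seq_len(C), drop = FALSE]
    dim(sl) <- c(N * Ho * Wo, C)
    acc <- acc + scale_cols(sl, W[t, ])
  }
  out <- acc; dim(out) <- c(N, Ho, Wo, C)
  list(out = out,
       cache = list(cols = cols, W = W, k = k, stride = stride, pad = pad,
                    dims_xp = dim(xp), Ho = Ho, Wo = Wo, dims_x = d))
}

dwconv_backward <- function(dout, cache) {
  d <- dim(dout); N <- d[1]; Ho <- d[2]; Wo <- d[3]; C <- d[4]
  k <- cache$k
  doutm <- dout; dim(doutm) <- c(N * Ho * Wo, C)
  dW <- matrix(0, k * k, C)
  dcols <- array(0, dim(cache$cols))
  for (t in seq_len(k * k)) {
    sl <- cache$cols[, , , (t - 1L) * C + seq_len(C), drop = FALSE]
    dim(sl) <- c(N * Ho * Wo, C)
    dW[t, ] <- colSums(sl * doutm)
    dsl <- scale_cols(doutm, cache$W[t, ])
    dim(dsl) <- c(N, Ho, Wo, C)
    dcols[, , , (t - 1L) * C + seq_len(C)] <- dsl
  }
  db <- colSums(doutm)
  dxp <- col2im_add(dcols, cache$dims_xp, k, cache$stride, Ho, Wo)
  p <- cache$pad
  dx <- if (p > 0L)
    dxp[, p + seq_len(cache$dims_x[2]), p + seq_len(cache$dims_x[3]), , drop = FALSE]
  else dxp
  list(dx = dx, dW = dW, db = db)
}

## ---- squeeze-and-excitation gate ---------------------------------------

# Global average pool -> bottleneck (GELU) -> sigmoid gate per (sample, channel).
se_forward <- function(x, W1, b1, W2, b2) {
  d <- dim(x); N <- d[1]; H <- d[2]; Wd <- d[3]; C <- d[4]
  sp <- H * Wd
  xm <- nhwc_mat(x)
  grp <- rep(seq_len(N), sp)                    # row n varies fastest in NHWC
  s <- rowsum(xm, grp) / sp                     # (N, C) spatial means
  l1 <- linear_forward(s, W1, b1)
  a1 <- gelu(l1$out)
  l2 <- linear_forward(a1, W2, b2)
  g <- sigmoid(l2$out)                          # (N, C) gates
  gexp <- g[grp, , drop = FALSE]
  out <- xm * gexp; dim(out) <- d
  list(out = out,
       cache = list(xm = xm, grp = grp, sp = sp, g = g, gexp = gexp,
                    l1 = l1$cache, z1 = l1$out, a1 = a1, l2 = l2$cache,
                    dims = d))
}

se_backward <- function(dout, cache) {
  d <- cache$dims
  doutm <- dout; dim(doutm) <- c(prod(d[1:3]), d[4])
  dg <- rowsum(doutm * cache$xm, cache$grp)     # (N, C)
  g <- cache$g
  dz2 <- dg * g * (1 - g)
  b2g <- linear_backward(dz2, cache$l2)
  dz1 <- b2g$dx * gelu_grad(cache$z1)
  b1g <- linear_backward(dz1, cache$l1)
  ds_exp <- b1g$dx[cache$grp, , drop = FALSE] / cache$sp
  dxm <- doutm * cache$gexp + ds_exp
  dx <- dxm; dim(dx) <- d
  list(dx = dx, dW1 = b1g$dW, db1 = b1g$db, dW2 = b2g$dW, db2 = b2g$db)
}

## ---- 2x2 average pooling (downsample shortcut) -------------------------

avgpool2_forward <- function(x) {
  d <- dim(x)
  odd_h <- seq(1L, d[2], by = 2L); odd_w <- seq(1L, d[3], by = 2L)
  out <- (x[, odd_h, odd_w, , drop = FALSE] +
          x[, odd_h + 1L, odd_w, , drop = FALSE] +
          x[, odd_h, odd_w + 1L, , drop = FALSE] +
          x[, odd_h + 1L, odd_w + 1L, , drop = FALSE]) / 4
  list(out = out, cache = list(dims = d))
}

avgpool2_backward <- function(dout, cache) {
  d <- cache$dims
  dx <- array(0, d)
  odd_h <- seq(1L, d[2], by = 2L); odd_w <- seq(1L, d[3], by = 2L)
  q <- dout / 4
  dx[, odd_h, odd_w, ] <- q
  dx[, odd_h + 1L, odd_w, ] <- q
  dx[, odd_h, odd_w + 1L, ] <- q
  dx[, odd_h + 1L, odd_w + 1L, ] <- q
  dx
}
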