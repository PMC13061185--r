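# Mobile inverted-bottleneck convolution (MBConv) block:
#   pre-norm -> 1x1 expand -> GELU -> 3x3 depthwise (stride 2 when
#   downsampling) -> GELU -> squeeze-excitation -> 1x1 project -> residual.
# When downsampling (or changing width) the shortcut is 2x2 average
# pooling followed by a 1x1 projection.
#
# The pre-norm is channel-wise layer normalization per spatial position
# (batch-independent, so train and eval behave identically).

#' Initialize parameters for an MBConv block
#'
#' @param Cin,Cout input and output channel counts.
#' @param expansion pointwise expansion ratio.
#' @param se_ratio squeeze-excitation reduction fraction.
#' @param downsample whether the block halves the spatial size (adds the
#'   pooled/projected shortcut).
#' @export
init_mbconv_params <- function(Cin, Cout, expansion, se_ratio, downsample) {
  Ce <- as.integer(round(Cin * expansion))
  Cse <- max(1L, as.integer(round(Ce * se_ratio)))
  p <- list(
    ln_g = rep(1, Cin), ln_b = numeric(Cin),
    Wexp = matrix(trunc_normal_fan(Cin * Ce, Cin), Cin, Ce), bexp = numeric(Ce),
    Wdw = matrix(trunc_normal_fan(9L * Ce, 9L), 9L, Ce), bdw = numeric(Ce),
    Wse1 = matrix(trunc_normal_fan(Ce * Cse, Ce), Ce, Cse), bse1 = numeric(Cse),
    Wse2 = matrix(trunc_normal_fan(Cse * Ce, Cse), Cse, Ce), bse2 = numeric(Ce),
    Wproj = matrix(trunc_normal_fan(Ce * Cout, Ce), Ce, Cout), bproj = numeric(Cout)
  )
  if (downsample || Cin != Cout) {
    # shortcut projection is the block's identity path: fan-in init
    p$Wsc <- matrix(trunc_normal_fan(Cin * Cout, Cin), Cin, Cout)
    p$bsc <- numeric(Cout)
  }
  p
}

mbconv_forward_impl <- function(x, p, stride, se_enabled = TRUE) {
  d <- dim(x)
  xm <- nhwc_mat(x)
  ln <- ln_forward(xm, p$ln_g, p$ln_b)
  le <- linear_forward(ln$out, p$Wexp, p$bexp)
  a1 <- gelu(le$out)
  a1_4 <- a1; dim(a1_4) <- c(d[1:3], ncol(p$Wexp))
  dw <- dwconv_forward(a1_4, p$Wdw, p$bdw, k = 3L, stride = stride, pad = 1L)
  a2 <- gelu(dw$out)
  if (se_enabled) {
    se <- se_forward(a2, p$Wse1, p$bse1, p$Wse2, p$bse2)
    gated <- se$out
  } else {
    se <- NULL
    gated <- a2
  }
  gm <- nhwc_mat(gated)
  lp <- linear_forward(gm, p$Wproj, p$bproj)
  out <- lp$out; dim(out) <- c(dim(a2)[1:3], ncol(p$Wproj))

  if (stride == 2L) {
    ap <- avgpool2_forward(x)
    scl <- linear_forward(nhwc_mat(ap$out), p$Wsc, p$bsc)
    sc <- scl$out; dim(sc) <- dim(out)
    sc_cache <- list(ap = ap$cache, lin = scl$cache, kind = "pool_proj")
  } else if (!is.null(p$Wsc)) {
    scl <- linear_forward(xm, p$Wsc, p$bsc)
    sc <- scl$out; dim(sc) <- dim(out)
    sc_cache <- list(lin = scl$cache, kind = "proj")
  } else {
    sc <- x
    sc_cache <- list(kind = "identity")
  }
  list(out = out + sc,
       cache = list(ln = ln$cache, le = le$cache, ze = le$out, dw = dw$cache,
                    dw_out = dw$out, zdw = dw$out, se = se$cache,
                    se_enabled = se_enabled, lp = lp$cache,
                    sc = sc_cache, dims = d, stride = stride))
}

mbconv_backward_impl <- function(dout, cache, want_dw = FALSE) {
  d <- cache$dims
  dd <- dim(dout)
  doutm <- dout; dim(doutm) <- c(prod(dd[1:3]), dd[4])
  bp <- linear_backward(doutm, cache$lp)
  dgated <- bp$dx; dim(dgated) <- c(dd[1:3], ncol(bp$dx))
  if (cache$se_enabled) {
    sb <- se_backward(dgated, cache$se)
    da2 <- sb$dx
  } else {
    sb <- NULL
    da2 <- dgated
  }
  ddw <- da2 * gelu_grad(cache$zdw)
  db <- dwconv_backward(ddw, cache$dw)
  da1 <- nhwc_mat(db$dx) * gelu_grad(cache$ze)
  be <- linear_backward(da1, cache$le)
  bl <- ln_backward(be$dx, cache$ln)
  dx <- bl$dx; dim(dx) <- d

  grads <- list(ln_g = bl$dg, ln_b = bl$db,
                Wexp = be$dW, bexp = be$db,
                Wdw = db$dW, bdw = db$db,
                Wproj = bp$dW, bproj = bp$db)
  if (!is.null(sb)) {
    grads$Wse1 <- sb$dW1; grads$bse1 <- sb$db1
    grads$Wse2 <- sb$dW2; grads$bse2 <- sb$db2
  }
  sc <- cache$sc
  if (sc$kind == "pool_proj") {
    bsc <- linear_backward(doutm, sc$lin)
    dpool <- bsc$dx; dim(dpool) <- c(dd[1:3], d[4])
    dx <- dx + avgpool2_backward(dpool, sc$ap)
    grads$Wsc <- bsc$dW; grads$bsc <- bsc$db
  } else if (sc$kind == "proj") {
    bsc <- linear_backward(doutm, sc$lin)
    dxs <- bsc$dx; dim(dxs) <- d
    dx <- dx + dxs
    grads$Wsc <- bsc$dW; grads$bsc <- bsc$db
  } else {
    dx <- dx + dout
  }
  res <- list(dx = dx, grads = grads)
  if (want_dw) res$d_dw <- ddw
  res
}

#' MBConv block forward pass
#'
#' Mobile inverted-bottleneck convolution with squeeze-excitation:
#' pre-norm, pointwise expansion (GELU), 3x3 depthwise convolution
#' (stride 2 when `downsample`), squeeze-excitation gating, pointwise
#' projection, and a residual connection (pooled and projected shortcut
#' when downsampling).
#'
#' @param x feature map `(N, H, W, C)` or `(H, W, C)`.
#' @param params parameter list from [init_mbconv_params()].
#' @param downsample halve the spatial resolution (stride-2 depthwise).
#' @param se_enabled apply the squeeze-excitation gate; with the gate
#'   forced off the block behaves as if SE were removed.
#' @return feature map; spatial size halved when `downsample`.
#' @export
mbconv_forward <- function(x, params, downsample = FALSE, se_enabled = TRUE) {
  x3 <- length(dim(x)) == 3L
  x <- as_nhwc(x)
  check_finite(x)
  out <- mbconv_forward_impl(x, params, if (downsample) 2L else 1L,
                             se_enabled)$out
  if (x3) dim(out) <- dim(out)[2:4]
  out
}
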