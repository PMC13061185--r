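# Windowed multi-head self-attention with relative position bias, used for
# both block (local window) and grid (dilated global) attention.  A full
# attention unit is pre-normalized and residual on both halves:
#   x <- x + Proj(MHSA(LN(x)))        (within each window / grid group)
#   x <- x + GRNMLP(LN(x))            (on the full spatial grid)
#
# Tokens are processed as (T, B, d) arrays (T tokens per group, B =
# groups x heads) so each einsum-like contraction is a short loop over T
# of BLAS-sized vector operations rather than B tiny matrix products.

#' Initialize parameters for an attention unit
#'
#' Layer norms at identity, fan-in truncated-normal QKV/projection
#' weights, zero relative-position bias table, and a [grn_mlp_forward()]
#' parameter set on the expanded width.
#'
#' @param C channel count.
#' @param P window / grid side length.
#' @param heads number of attention heads.
#' @param mlp_expansion feed-forward expansion ratio.
#' @param grn_enabled include GRN gamma/beta in the MLP.
#' @export
init_attention_params <- function(C, P, heads, mlp_expansion, grn_enabled) {
  tbl <- (2L * P - 1L)^2
  list(
    ln1_g = rep(1, C), ln1_b = numeric(C),
    Wqkv = matrix(trunc_normal_fan(C * 3L * C, C), C, 3L * C),
    bqkv = numeric(3L * C),
    bias_table = matrix(0, tbl, heads),
    Wproj = matrix(trunc_normal_fan(C * C, C), C, C), bproj = numeric(C),
    ln2_g = rep(1, C), ln2_b = numeric(C),
    mlp = init_grnmlp_params(C, mlp_expansion, grn_enabled)
  )
}

# core MHSA on a token array (T, B0, C); returns attention rows too so the
# row-stochastic invariant can be checked
attn_core_forward <- function(tk, p, heads, idx) {
  dd <- dim(tk); Tn <- dd[1]; B0 <- dd[2]; C <- dd[3]
  dh <- C %/% heads
  tkm <- tk; dim(tkm) <- c(Tn * B0, C)
  lq <- linear_forward(tkm, p$Wqkv, p$bqkv)
  qkv <- lq$out
  split_heads <- function(m) {
    a <- m; dim(a) <- c(Tn, B0, dh, heads)
    a <- aperm(a, c(1, 2, 4, 3))               # (T, B0, heads, dh)
    dim(a) <- c(Tn, B0 * heads, dh)
    a
  }
  Q <- split_heads(qkv[, seq_len(C), drop = FALSE]) / sqrt(dh)
  K <- split_heads(qkv[, C + seq_len(C), drop = FALSE])
  V <- split_heads(qkv[, 2L * C + seq_len(C), drop = FALSE])
  B <- B0 * heads

  S <- array(0, c(Tn, Tn, B))
  Km <- K; dim(Km) <- c(Tn, B * dh)
  for (i in seq_len(Tn)) {
    qi <- Q[i, , ]                              # (B, dh)
    S[i, , ] <- rowSums(array(Km * rep(qi, each = Tn), c(Tn, B, dh)), dims = 2)
  }
  bias <- array(p$bias_table[idx, ], c(Tn, Tn, heads))
  S <- S + bias[, , rep(seq_len(heads), each = B0), drop = FALSE]

  mx <- S[, 1, ]
  for (j in seq_len(Tn)[-1]) mx <- pmax(mx, S[, j, ])
  A <- array(0, c(Tn, Tn, B)); ssum <- matrix(0, Tn, B)
  for (j in seq_len(Tn)) { A[, j, ] <- exp(S[, j, ] - mx); ssum <- ssum + A[, j, ] }
  for (j in seq_len(Tn)) A[, j, ] <- A[, j, ] / ssum

  O <- array(0, c(Tn, B, dh))
  for (j in seq_len(Tn)) {
    O <- O + array(rep(A[, j, ], times = dh) * rep(V[j, , ], each = Tn),
                   c(Tn, B, dh))
  }
  merge_heads <- function(a) {
    dim(a) <- c(Tn, B0, heads, dh)
    a <- aperm(a, c(1, 2, 4, 3))
    dim(a) <- c(Tn * B0, C)
    a
  }
  Om <- merge_heads(O)
  lp <- linear_forward(Om, p$Wproj, p$bproj)
  out <- lp$out; dim(out) <- dd
  list(out = out, attn = A,
       cache = list(lq = lq$cache, lp = lp$cache, Q = Q, K = K, V = V, A = A,
                    Tn = Tn, B0 = B0, C = C, dh = dh, heads = heads, idx = idx))
}

attn_core_backward <- function(dout, cache) {
  Tn <- cache$Tn; B0 <- cache$B0; C <- cache$C
  dh <- cache$dh; heads <- cache$heads; B <- B0 * heads
  doutm <- dout; dim(doutm) <- c(Tn * B0, C)
  bp <- linear_backward(doutm, cache$lp)
  dO <- bp$dx
  dim(dO) <- c(Tn, B0, dh, heads)
  dO <- aperm(dO, c(1, 2, 4, 3)); dim(dO) <- c(Tn, B, dh)

  A <- cache$A; V <- cache$V; Q <- cache$Q; K <- cache$K
  dA <- array(0, c(Tn, Tn, B))
  dV <- array(0, c(Tn, B, dh))
  for (j in seq_len(Tn)) {
    vje <- array(rep(V[j, , ], each = Tn), c(Tn, B, dh))
    dA[, j, ] <- rowSums(dO * vje, dims = 2)
    dV[j, , ] <- colSums(dO * array(rep(A[, j, ], times = dh), c(Tn, B, dh)))
  }
  r <- matrix(0, Tn, B)
  for (j in seq_len(Tn)) r <- r + dA[, j, ] * A[, j, ]
  dS <- array(0, c(Tn, Tn, B))
  for (j in seq_len(Tn)) dS[, j, ] <- A[, j, ] * (dA[, j, ] - r)

  # relative-position bias gradient: sum over the B0 groups per head
  dS4 <- dS; dim(dS4) <- c(Tn, Tn, B0, heads)
  dbias <- rowSums(aperm(dS4, c(1, 2, 4, 3)), dims = 3)   # (T, T, heads)
  P <- as.integer(round(sqrt(Tn)))
  dtable <- matrix(0, (2L * P - 1L)^2, heads)
  gidx <- as.vector(cache$idx)
  for (h in seq_len(heads)) {
    agg <- rowsum(as.vector(dbias[, , h]), gidx)
    dtable[as.integer(rownames(agg)), h] <- agg
  }

  dQ <- array(0, c(Tn, B, dh))
  for (j in seq_len(Tn)) {
    dQ <- dQ + array(rep(dS[, j, ], times = dh) * rep(K[j, , ], each = Tn),
                     c(Tn, B, dh))
  }
  dK <- array(0, c(Tn, B, dh))
  for (i in seq_len(Tn)) {
    dK <- dK + array(rep(dS[i, , ], times = dh) * rep(Q[i, , ], each = Tn),
                     c(Tn, B, dh))
  }
  dQ <- dQ / sqrt(dh)
  unsplit <- function(a) {
    dim(a) <- c(Tn, B0, heads, dh)
    a <- aperm(a, c(1, 2, 4, 3))
    dim(a) <- c(Tn * B0, dh * heads)
    a
  }
  dqkv <- cbind(unsplit(dQ), unsplit(dK), unsplit(dV))
  bq <- linear_backward(dqkv, cache$lq)
  dtk <- bq$dx; dim(dtk) <- c(Tn, B0, C)
  list(dtk = dtk, dWqkv = bq$dW, dbqkv = bq$db,
       dWproj = bp$dW, dbproj = bp$db, dbias_table = dtable)
}

## ---- full attention unit (attention + GRN-MLP, both residual) ----------

attn_unit_forward <- function(x, p, cfg) {
  d <- dim(x)
  xm <- nhwc_mat(x)
  l1 <- ln_forward(xm, p$ln1_g, p$ln1_b)
  y <- l1$out; dim(y) <- d
  tk <- partition_tokens(y, cfg$P, cfg$type)
  core <- attn_core_forward(tk, p, cfg$heads, cfg$idx)
  att <- unpartition_tokens(core$out, d, cfg$P, cfg$type)
  x1 <- x + att
  x1m <- nhwc_mat(x1)
  l2 <- ln_forward(x1m, p$ln2_g, p$ln2_b)
  z <- l2$out; dim(z) <- d
  mlp <- grnmlp_forward(z, p$mlp, cfg$grn_enabled, cfg$grn_eps)
  out <- x1 + mlp$out
  list(out = out,
       cache = list(l1 = l1$cache, core = core$cache, l2 = l2$cache,
                    mlp = mlp$cache, dims = d, cfg = cfg),
       attn = core$attn)
}

attn_unit_backward <- function(dout, cache) {
  d <- cache$dims; cfg <- cache$cfg
  mb <- grnmlp_backward(dout, cache$mlp)
  dz <- nhwc_mat(mb$dx)
  lb2 <- ln_backward(dz, cache$l2)
  dx1 <- dout + array(lb2$dx, d)
  datt <- partition_tokens(dx1, cfg$P, cfg$type)  # adjoint of unpartition
  cb <- attn_core_backward(datt, cache$core)
  dy <- unpartition_tokens(cb$dtk, d, cfg$P, cfg$type)
  lb1 <- ln_backward(nhwc_mat(dy), cache$l1)
  dx <- dx1 + array(lb1$dx, d)
  grads <- list(ln1_g = lb1$dg, ln1_b = lb1$db,
                Wqkv = cb$dWqkv, bqkv = cb$dbqkv,
                bias_table = cb$dbias_table,
                Wproj = cb$dWproj, bproj = cb$dbproj,
                ln2_g = lb2$dg, ln2_b = lb2$db,
                mlp = list(W1 = mb$dW1, b1 = mb$db1, W2 = mb$dW2, b2 = mb$db2))
  if (!is.null(mb$dgamma)) {
    grads$mlp$gamma <- mb$dgamma; grads$mlp$beta <- mb$dbeta
  }
  list(dx = dx, grads = grads)
}

attn_cfg <- function(P, heads, grn_enabled, grn_eps, type) {
  list(P = P, heads = heads, grn_enabled = grn_enabled, grn_eps = grn_eps,
       type = type, idx = relpos_index(P))
}

#' Block (local window) attention layer
#'
#' Pre-normalized multi-head self-attention with relative position bias
#' inside each non-overlapping `P x P` window, followed by a residual
#' GRN-MLP on the full spatial grid.  Shape is preserved.
#'
#' @param x feature map `(N, H, W, C)` or `(H, W, C)`; `H`, `W` divisible
#'   by `P`.
#' @param params parameter list from [init_attention_params()].
#' @param P window side length.
#' @param head_dim per-head width; `C` must be divisible by it.
#' @param grn_enabled,grn_eps GRN-MLP switches (see [grn_mlp_forward()]).
#' @param return_attn also return the attention weight array
#'   `(T, T, windows*heads)` as attribute `"attn"`.
#' @return feature map of the same shape as `x`.
#' @export
block_attention_forward <- function(x, params, P, head_dim,
                                    grn_enabled = TRUE, grn_eps = 1e-6,
                                    return_attn = FALSE) {
  attention_forward_impl(x, params, P, head_dim, grn_enabled, grn_eps,
                         "block", return_attn)
}

#' Grid (dilated global) attention layer
#'
#' Same computation as [block_attention_forward()] but over grid groups:
#' each group samples every `(H/P)`-th position so attention spans the
#' whole image.
#'
#' @inheritParams block_attention_forward
#' @export
grid_attention_forward <- function(x, params, P, head_dim,
                                   grn_enabled = TRUE, grn_eps = 1e-6,
                                   return_attn = FALSE) {
  attention_forward_impl(x, params, P, head_dim, grn_enabled, grn_eps,
                         "grid", return_attn)
}

attention_forward_impl <- function(x, params, P, head_dim, grn_enabled,
                                   grn_eps, type, return_attn) {
  x3 <- length(dim(x)) == 3L
  x <- as_nhwc(x)
  C <- dim(x)[4]
  if (C %% head_dim != 0L)
    stop(sprintf("channel count %d not divisible by head_dim %d", C, head_dim))
  cfg <- attn_cfg(P, C %/% head_dim, grn_enabled, grn_eps, type)
  fw <- attn_unit_forward(x, params, cfg)
  out <- fw$out
  if (x3) dim(out) <- dim(out)[2:4]
  if (return_attn) attr(out, "attn") <- fw$attn
  out
}
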