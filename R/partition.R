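# Multi-axis token partitioning.
#
# Block attention groups pixels into non-overlapping P x P windows (local
# context); grid attention groups pixels that sit P apart on a dilated
# lattice, i.e. each group samples every (H/P)-th position and therefore
# spans the whole image (global context).  Both are pure index
# permutations, so partition followed by unpartition is exact.
#
# Token layout: (T, B, C) with T = P*P tokens per group and
# B = N * (#groups per image) groups; the group index varies with the
# batch sample fastest.

partition_tokens <- function(x, P, type = c("block", "grid")) {
  type <- match.arg(type)
  d <- dim(x); N <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  if (H %% P != 0L || W %% P != 0L)
    stop(sprintf("spatial size %dx%d not divisible by partition size %d (no implicit padding)",
                 H, W, P))
  gh <- H %/% P; gw <- W %/% P
  if (type == "block") {
    dim(x) <- c(N, P, gh, P, gw, C)       # (n, pi, wi, pj, wj, c)
    x <- aperm(x, c(2, 4, 1, 3, 5, 6))    # (pi, pj, n, wi, wj, c)
  } else {
    dim(x) <- c(N, gh, P, gw, P, C)       # (n, h2, h1, w2, w1, c)
    x <- aperm(x, c(3, 5, 1, 2, 4, 6))    # (h1, w1, n, h2, w2, c)
  }
  dim(x) <- c(P * P, N * gh * gw, C)
  x
}

unpartition_tokens <- function(tk, dims, P, type = c("block", "grid")) {
  type <- match.arg(type)
  N <- dims[1]; H <- dims[2]; W <- dims[3]; C <- dims[4]
  gh <- H %/% P; gw <- W %/% P
  if (type == "block") {
    dim(tk) <- c(P, P, N, gh, gw, C)
    tk <- aperm(tk, c(3, 1, 4, 2, 5, 6))
  } else {
    dim(tk) <- c(P, P, N, gh, gw, C)
    tk <- aperm(tk, c(3, 4, 1, 5, 2, 6))
  }
  dim(tk) <- c(N, H, W, C)
  tk
}

#' Partition a feature map into attention windows
#'
#' Splits an NHWC feature map into `P * P`-token groups: contiguous
#' windows (`type = "block"`) or a dilated grid in which each group spans
#' the whole image by sampling every `(H/P)`-th position
#' (`type = "grid"`).  The inverse is [window_unpartition()];
#' `window_unpartition(window_partition(x))` reproduces `x` exactly.
#'
#' @param x array `(N, H, W, C)` or `(H, W, C)`; `H` and `W` must be
#'   divisible by `P` (no implicit padding).
#' @param P window / grid side length.
#' @param type `"block"` (local windows) or `"grid"` (dilated global grid).
#' @return array `(P*P, n_groups, C)` of tokens, with attributes `dims`
#'   (original shape), `P` and `type` so the inverse needs no extra
#'   arguments.
#' @export
window_partition <- function(x, P, type = c("block", "grid")) {
  type <- match.arg(type)
  x <- as_nhwc(x)
  tk <- partition_tokens(x, P, type)
  attr(tk, "dims") <- dim(x); attr(tk, "P") <- P; attr(tk, "type") <- type
  tk
}

#' Reassemble attention windows into a feature map
#'
#' Exact inverse of [window_partition()].
#'
#' @param tk token array produced by [window_partition()] (or any
#'   `(P*P, n_groups, C)` array if `dims`, `P`, `type` are given).
#' @param dims original `(N, H, W, C)` shape; defaults to the attribute
#'   stored by [window_partition()].
#' @param P,type partition parameters; default to the stored attributes.
#' @return array `(N, H, W, C)`.
#' @export
window_unpartition <- function(tk, dims = attr(tk, "dims"), P = attr(tk, "P"),
                               type = attr(tk, "type")) {
  if (is.null(dims) || is.null(P) || is.null(type))
    stop("dims/P/type must be supplied when tk lacks partition attributes")
  unpartition_tokens(as.vector(tk) |> array(dim(tk)), dims, P, type)
}

# relative-position index matrix for a P x P window: entry (i, j) is the
# index into a (2P-1)^2 bias table for the offset between tokens i and j
relpos_index <- function(P) {
  pos <- expand.grid(h = seq_len(P), w = seq_len(P))  # h fastest, matches layout
  T <- P * P
  idx <- matrix(0L, T, T)
  for (i in seq_len(T)) for (j in seq_len(T)) {
    dh <- pos$h[i] - pos$h[j] + P
    dw <- pos$w[i] - pos$w[j] + P
    idx[i, j] <- (dh - 1L) * (2L * P - 1L) + dw
  }
  idx
}
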