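# Low-level numeric helpers shared by the network layers.
#
# Feature maps are stored NHWC: a 4-axis array with dim (batch N, height H,
# width W, channels C).  R is column-major, so flattening an NHWC array with
# `dim<-` to a (N*H*W, C) matrix keeps channels as contiguous columns, which
# is what every pointwise (1x1 / linear) operation needs.

#' @keywords internal
as_nhwc <- function(x) {
  if (is.matrix(x)) stop("expected a 3- or 4-axis array, got a matrix")
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(3L, 4L)))
    stop("expected an array with 3 (H,W,C) or 4 (N,H,W,C) axes")
  if (length(d) == 3L) dim(x) <- c(1L, d)
  x
}

#' @keywords internal
check_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) stop(sprintf("non-finite values in %s", what))
  invisible(x)
}

# column-wise scale / shift on a (rows, C) matrix without sweep()'s overhead
#' @keywords internal
scale_cols <- function(m, s) m * rep(s, each = nrow(m))

#' @keywords internal
shift_cols <- function(m, s) m + rep(s, each = nrow(m))

# flatten NHWC array to (N*H*W, C) matrix; inverse via dim<-
#' @keywords internal
nhwc_mat <- function(x) {
  d <- dim(x)
  dim(x) <- c(prod(d[1:3]), d[4])
  x
}

#' @keywords internal
gelu <- function(x) x * stats::pnorm(x)

#' @keywords internal
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

#' @keywords internal
sigmoid <- function(x) 1 / (1 + exp(-x))

# truncated-normal initialiser (+-2 sd).  Residual transformer branches
# use the flat sd = 0.02 convention (they start near-identity behind a
# pre-norm); layers that *carry* the signal (stem convolutions, shortcut
# projections) must scale with fan-in or the activations shrink
# geometrically with depth -- use trunc_normal_fan for those.
#' @keywords internal
trunc_normal <- function(n, sd = 0.02) {
  lo <- stats::pnorm(-2); hi <- stats::pnorm(2)
  stats::qnorm(stats::runif(n, lo, hi)) * sd
}

# He-style fan-in scaling, truncated at +-2 sd
#' @keywords internal
trunc_normal_fan <- function(n, fan_in) {
  trunc_normal(n, sd = sqrt(2 / fan_in))
}

#' @keywords internal
zeros <- function(...) array(0, dim = c(...))

# softmax over the rows of a matrix (each row a distribution)
#' @keywords internal
row_softmax <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Bilinear upsampling of a 2-D map
#'
#' Resamples a matrix to a new size with bilinear interpolation, treating
#' pixels as cell centres (`align_corners = FALSE` convention): output pixel
#' centre `i` maps to input coordinate `(i - 0.5) * H_in / H_out + 0.5`.
#' Used to lift coarse saliency maps to input resolution.
#'
#' @param m numeric matrix.
#' @param out_h,out_w output size in pixels.
#' @return an `out_h` x `out_w` matrix.
#' @keywords internal
bilinear_upsample <- function(m, out_h, out_w) {
  hin <- nrow(m); win <- ncol(m)
  src <- function(n_out, n_in) {
    p <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
    pmin(pmax(p, 1), n_in)
  }
  ys <- src(out_h, hin); xs <- src(out_w, win)
  y0 <- pmin(floor(ys), hin - 1L); y0[hin == 1L] <- 1L
  x0 <- pmin(floor(xs), win - 1L); x0[win == 1L] <- 1L
  y1 <- pmin(y0 + 1L, hin); x1 <- pmin(x0 + 1L, win)
  wy <- ys - y0; wx <- xs - x0
  a <- m[y0, x0, drop = FALSE]; b <- m[y0, x1, drop = FALSE]
  c_ <- m[y1, x0, drop = FALSE]; d <- m[y1, x1, drop = FALSE]
  wy <- matrix(wy, out_h, out_w); wx <- matrix(wx, out_h, out_w, byrow = TRUE)
  (1 - wy) * ((1 - wx) * a + wx * b) + wy * ((1 - wx) * c_ + wx * d)
}
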