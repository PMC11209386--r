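#' Construct a feature map
#'
#' Feature maps are plain numeric arrays in `(batch, channel, height, width)`
#' order; every network operation in the package uses this layout.
#'
#' @param values numeric array or vector.
#' @param dim length-4 integer vector `(N, C, H, W)`; may be omitted when
#'   `values` already carries a rank-4 `dim` attribute.
#' @return a rank-4 numeric array.
#' @export
feature_map <- function(values, dim = base::dim(values)) {
  if (is.null(dim) || length(dim) != 4L)
    stop("a feature map needs a rank-4 dim (batch, channel, height, width)")
  if (any(dim < 1L)) stop("feature map dimensions must all be >= 1")
  x <- array(as.numeric(values), dim = dim)
  if (!all(is.finite(x))) stop("feature map values must all be finite")
  x
}

fm_dims <- function(x) {
  d <- dim(x)
  list(N = d[1L], C = d[2L], H = d[3L], W = d[4L])
}

# Concatenate feature maps along the channel axis.
concat_channels <- function(...) {
  xs <- list(...)
  d1 <- dim(xs[[1L]])
  Cs <- vapply(xs, function(x) dim(x)[2L], integer(1))
  out <- array(0, c(d1[1L], sum(Cs), d1[3L], d1[4L]))
  at <- 0L
  for (x in xs) {
    out[, at + seq_len(dim(x)[2L]), , ] <- x
    at <- at + dim(x)[2L]
  }
  out
}

# One-dimensional bilinear interpolation matrix (n_out x n_in) under the
# half-pixel (align-corners off) convention, edge-clamped.
bilinear_matrix <- function(n_out, n_in) {
  A <- matrix(0, n_out, n_in)
  if (n_in == 1L) { A[, 1L] <- 1; return(A) }
  src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  i0 <- floor(src)
  t <- src - i0
  i0c <- pmin(pmax(i0, 0), n_in - 1) + 1
  i1c <- pmin(pmax(i0 + 1, 0), n_in - 1) + 1
  for (r in seq_len(n_out)) {
    A[r, i0c[r]] <- A[r, i0c[r]] + (1 - t[r])
    A[r, i1c[r]] <- A[r, i1c[r]] + t[r]
  }
  A
}

# Apply separable row/column interpolation matrices A (Ho x H), B (Wo x W)
# to every (n, c) slice: out[n,c,,] = A %*% x[n,c,,] %*% t(B).
# Linear, so the adjoint is the same call with t(A), t(B).
resize_apply <- function(x, A, B) {
  d <- dim(x)
  N <- d[1L]; C <- d[2L]; H <- d[3L]; W <- d[4L]
  Ho <- nrow(A); Wo <- nrow(B)
  xm <- matrix(aperm(x, c(3L, 1L, 2L, 4L)), nrow = H)  # H x (N*C*W)
  y <- A %*% xm                                        # Ho x (N*C*W)
  y <- aperm(array(y, c(Ho, N, C, W)), c(4L, 2L, 3L, 1L))  # W x N x C x Ho
  ym <- matrix(y, nrow = W)                            # W x (N*C*Ho)
  z <- B %*% ym                                        # Wo x (N*C*Ho)
  out <- array(z, c(Wo, N, C, Ho))
  aperm(out, c(2L, 3L, 4L, 1L))
}

# Bilinear resize of a (N, C, H, W) tensor to (Ho, Wo).
resize_bilinear_nchw <- function(x, Ho, Wo) {
  d <- dim(x)
  resize_apply(x, bilinear_matrix(Ho, d[3L]), bilinear_matrix(Wo, d[4L]))
}

# Adjoint of resize_bilinear_nchw for gradients.
resize_bilinear_bwd_nchw <- function(grad, H, W) {
  d <- dim(grad)
  resize_apply(grad, t(bilinear_matrix(d[3L], H)), t(bilinear_matrix(d[4L], W)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))
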