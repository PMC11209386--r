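# Layer primitives with explicit forward/backward passes.
#
# Conventions: all activations are (N, C, H, W) arrays; every *_fwd returns
# list(out, cache) and the matching *_bwd consumes (grad, cache) and returns
# the input gradient plus parameter gradients. Batch-norm running statistics
# live in an environment on the model (mutated during training-mode
# forwards) so the trainable parameter tree stays purely functional.

he_init <- function(dims, fan_in) {
  array(rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

init_conv <- function(c_in, c_out, k) {
  list(W = he_init(c(c_out, c_in, k, k), fan_in = c_in * k * k),
       b = numeric(c_out))
}

init_bn <- function(C) list(gamma = rep(1, C), beta = rep(0, C))

# --- convolution (stride 1, same padding, odd kernel) ------------------------

conv_fwd <- function(x, p, k = dim(p$W)[3L]) {
  d <- dim(x)
  if (k == 1L) return(conv1x1_fwd(x, p))
  pad <- (k - 1L) %/% 2L
  cols <- im2col_nchw(x, d[1L], d[2L], d[3L], d[4L], k, pad)
  Wm <- matrix(p$W, nrow = dim(p$W)[1L])
  ym <- Wm %*% cols + p$b                      # (Cout) x (N*H*W)
  out <- aperm(array(ym, c(nrow(ym), d[1L], d[3L], d[4L])), c(2L, 1L, 3L, 4L))
  list(out = out, cache = list(cols = cols, d = d, k = k, pad = pad, W = p$W))
}

conv_bwd <- function(grad, cache) {
  if (cache$k == 1L) return(conv1x1_bwd(grad, cache))
  d <- cache$d
  gm <- matrix(aperm(grad, c(2L, 1L, 3L, 4L)), nrow = dim(grad)[2L])
  Wm <- matrix(cache$W, nrow = dim(cache$W)[1L])
  dW <- array(gm %*% t(cache$cols), dim = dim(cache$W))
  db <- rowSums(gm)
  dcols <- t(Wm) %*% gm
  dx <- col2im_nchw(dcols, d[1L], d[2L], d[3L], d[4L], cache$k, cache$pad)
  list(dx = dx, grads = list(W = dW, b = db))
}

# 1x1 convolutions reduce to a channel-mixing matrix multiply.
conv1x1_fwd <- function(x, p) {
  d <- dim(x)
  xm <- matrix(aperm(x, c(2L, 1L, 3L, 4L)), nrow = d[2L])   # C x (N*H*W)
  Wm <- matrix(p$W, nrow = dim(p$W)[1L])
  ym <- Wm %*% xm + p$b
  out <- aperm(array(ym, c(nrow(ym), d[1L], d[3L], d[4L])), c(2L, 1L, 3L, 4L))
  list(out = out, cache = list(xm = xm, d = d, k = 1L, W = p$W))
}

conv1x1_bwd <- function(grad, cache) {
  d <- cache$d
  gm <- matrix(aperm(grad, c(2L, 1L, 3L, 4L)), nrow = dim(grad)[2L])
  Wm <- matrix(cache$W, nrow = dim(cache$W)[1L])
  dW <- array(gm %*% t(cache$xm), dim = dim(cache$W))
  db <- rowSums(gm)
  dxm <- t(Wm) %*% gm
  dx <- aperm(array(dxm, c(d[2L], d[1L], d[3L], d[4L])), c(2L, 1L, 3L, 4L))
  list(dx = dx, grads = list(W = dW, b = db))
}

# --- batch normalisation -----------------------------------------------------

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

bn_fwd <- function(x, p, stats, key, training) {
  d <- dim(x)
  C <- d[2L]
  xm <- matrix(aperm(x, c(2L, 1L, 3L, 4L)), nrow = C)  # C x (N*H*W)
  m <- ncol(xm)
  if (training) {
    mu <- rowMeans(xm)
    v <- rowMeans(xm * xm) - mu * mu
    v <- pmax(v, 0)
    rs <- get0(key, envir = stats, inherits = FALSE)
    if (is.null(rs)) rs <- list(mean = numeric(C), var = rep(1, C))
    assign(key, list(mean = (1 - BN_MOMENTUM) * rs$mean + BN_MOMENTUM * mu,
                     var  = (1 - BN_MOMENTUM) * rs$var + BN_MOMENTUM * v),
           envir = stats)
  } else {
    rs <- get0(key, envir = stats, inherits = FALSE)
    if (is.null(rs)) rs <- list(mean = numeric(C), var = rep(1, C))
    mu <- rs$mean
    v <- rs$var
  }
  inv <- 1 / sqrt(v + BN_EPS)
  xhat <- (xm - mu) * inv
  ym <- p$gamma * xhat + p$beta
  out <- aperm(array(ym, c(C, d[1L], d[3L], d[4L])), c(2L, 1L, 3L, 4L))
  list(out = out,
       cache = list(xhat = xhat, inv = inv, gamma = p$gamma, d = d,
                    training = training))
}

bn_bwd <- function(grad, cache) {
  d <- cache$d
  C <- d[2L]
  gm <- matrix(aperm(grad, c(2L, 1L, 3L, 4L)), nrow = C)
  dgamma <- rowSums(gm * cache$xhat)
  dbeta <- rowSums(gm)
  dxhat <- gm * cache$gamma
  if (cache$training) {
    dxm <- cache$inv * (dxhat - rowMeans(dxhat) -
                          cache$xhat * rowMeans(dxhat * cache$xhat))
  } else {
    dxm <- cache$inv * dxhat
  }
  dx <- aperm(array(dxm, c(C, d[1L], d[3L], d[4L])), c(2L, 1L, 3L, 4L))
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

# --- pointwise and pooling ---------------------------------------------------

relu_fwd <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_bwd <- function(grad, cache) grad * cache

pool_fwd <- function(x, k) {
  d <- dim(x)
  r <- maxpool_nchw(x, d[1L], d[2L], d[3L], d[4L], k)
  list(out = r$out, cache = list(argmax = r$argmax, d = d))
}

pool_bwd <- function(grad, cache) {
  d <- cache$d
  maxpool_bwd_nchw(grad, cache$argmax, d[1L], d[2L], d[3L], d[4L])
}

upsample2_fwd <- function(x) {
  d <- dim(x)
  list(out = resize_bilinear_nchw(x, 2L * d[3L], 2L * d[4L]),
       cache = c(d[3L], d[4L]))
}

upsample2_bwd <- function(grad, cache) {
  resize_bilinear_bwd_nchw(grad, cache[1L], cache[2L])
}
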