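#' Pyramid channel attention configuration
#'
#' The pyramid channel attention module (PCAM) summarises a feature map at
#' several scales with non-overlapping max pooling (spatial pyramid pooling,
#' SPP), gates the pooled description per channel with a shared-MLP sigmoid
#' attention vector, and concatenates the gated description back onto the
#' input.
#'
#' @param pool_sizes ordered positive integers; max-pooling window (= stride)
#'   per pyramid branch. Default `c(2, 3, 5, 6)`.
#' @param reduction_ratio positive integer `r`; the attention MLP bottleneck
#'   width is `max(C / r, 1)` for `C` attended channels.
#' @param fuse_to_input_channels if `TRUE` (default) a pre-activated 1x1
#'   convolution maps the concatenated `(1 + n_branches) * C` channels back
#'   to `C`, making the module drop-in inside an encoder stage.
#' @param mlp_relu insert a ReLU between the two shared MLP layers (default
#'   `TRUE`).
#' @return an object of class `pcam_config`.
#' @export
pcam_config <- function(pool_sizes = c(2L, 3L, 5L, 6L), reduction_ratio = 16L,
                        fuse_to_input_channels = TRUE, mlp_relu = TRUE) {
  pool_sizes <- as.integer(pool_sizes)
  if (length(pool_sizes) == 0L || any(pool_sizes < 1L))
    stop("pool_sizes must be a nonempty vector of positive integers")
  if (reduction_ratio < 1L) stop("reduction_ratio must be >= 1")
  structure(list(pool_sizes = pool_sizes,
                 reduction_ratio = as.integer(reduction_ratio),
                 fuse_to_input_channels = isTRUE(fuse_to_input_channels),
                 mlp_relu = isTRUE(mlp_relu)),
            class = "pcam_config")
}

#' Shared-MLP channel attention weights
#'
#' Two weight matrices `W0 (hidden x C)` and `W1 (C x hidden)` applied to
#' both the global-average-pooled and global-max-pooled channel descriptors;
#' the two MLP outputs are summed and squashed with a sigmoid.
#'
#' @param channels number of attended channels `C`.
#' @param reduction_ratio bottleneck ratio `r`; hidden width `max(C/r, 1)`.
#' @return list with elements `W0`, `W1`.
#' @export
cam_weights <- function(channels, reduction_ratio = 16L) {
  hidden <- max(channels %/% reduction_ratio, 1L)
  list(W0 = he_init(c(hidden, channels), fan_in = channels),
       W1 = he_init(c(channels, hidden), fan_in = hidden))
}

check_pool_geometry <- function(pool_sizes, H, W) {
  bad <- pool_sizes[pool_sizes > H | pool_sizes > W]
  if (length(bad) > 0L)
    stop(sprintf("pool size %d exceeds feature map spatial size %dx%d",
                 bad[1L], H, W))
}

#' Spatial pyramid pooling
#'
#' Max-pools the input with each configured window size (kernel = stride,
#' ceil mode at borders), bilinearly upsamples every pooled map back to the
#' input resolution (half-pixel convention), and concatenates the branches
#' along channels in pool-size order.
#'
#' @param x feature map `(N, C, H, W)`.
#' @param config a [pcam_config()].
#' @return object of class `pyramid_descriptor`: list with `branches` (one
#'   `(N, C, H, W)` map per pool size) and `concatenated`
#'   (`(N, C * n_branches, H, W)`).
#' @export
spatial_pyramid_pool <- function(x, config = pcam_config()) {
  f <- spp_fwd(x, config$pool_sizes)
  structure(list(branches = f$branches, concatenated = f$S,
                 pool_sizes = config$pool_sizes),
            class = "pyramid_descriptor")
}

spp_fwd <- function(x, pool_sizes) {
  d <- dim(x)
  check_pool_geometry(pool_sizes, d[3L], d[4L])
  branches <- vector("list", length(pool_sizes))
  caches <- vector("list", length(pool_sizes))
  for (i in seq_along(pool_sizes)) {
    pf <- pool_fwd(x, pool_sizes[i])
    branches[[i]] <- resize_bilinear_nchw(pf$out, d[3L], d[4L])
    caches[[i]] <- list(pool = pf$cache, pdim = dim(pf$out))
  }
  S <- do.call(concat_channels, branches)
  list(S = S, branches = branches, caches = caches, d = d)
}

spp_bwd <- function(dS, cache) {
  d <- cache$d
  C <- d[2L]
  dx <- array(0, d)
  for (i in seq_along(cache$caches)) {
    db <- dS[, (i - 1L) * C + seq_len(C), , , drop = FALSE]
    pd <- cache$caches[[i]]$pdim
    dp <- resize_bilinear_bwd_nchw(db, pd[3L], pd[4L])
    dx <- dx + pool_bwd(dp, cache$caches[[i]]$pool)
  }
  dx
}

#' Channel attention
#'
#' Computes per-channel sigmoid gates
#' `Mc = sigmoid(W1 f(W0 avgpool(S)) + W1 f(W0 maxpool(S)))` where the
#' pooling is global over space, the MLP weights are shared between the two
#' paths and `f` is a ReLU (or identity when `mlp_relu = FALSE`).
#'
#' @param S feature map `(N, C, H, W)`.
#' @param weights a [cam_weights()] list sized for `C` channels.
#' @param mlp_relu logical, see [pcam_config()].
#' @return a `C x N` matrix of attention weights, entries strictly in (0, 1).
#' @export
channel_attention <- function(S, weights, mlp_relu = TRUE) {
  if (dim(S)[2L] != ncol(weights$W0))
    stop(sprintf("channel mismatch: map has %d channels, weights expect %d",
                 dim(S)[2L], ncol(weights$W0)))
  cam_fwd(S, weights, mlp_relu)$Mc
}

cam_fwd <- function(S, w, mlp_relu) {
  d <- dim(S)
  N <- d[1L]; C <- d[2L]; HW <- d[3L] * d[4L]
  m <- matrix(aperm(S, c(3L, 4L, 2L, 1L)), nrow = HW)   # HW x (C*N)
  gap <- matrix(colMeans(m), C, N)
  amax <- max.col(t(m), ties.method = "first")          # per column of m
  gmp <- matrix(m[amax + (seq_along(amax) - 1L) * HW], C, N)
  path <- function(g) {
    pre <- w$W0 %*% g
    h <- if (mlp_relu) pmax(pre, 0) else pre
    list(o = w$W1 %*% h, h = h, pre = pre)
  }
  pa <- path(gap)
  pm <- path(gmp)
  Mc <- sigmoid(pa$o + pm$o)
  list(Mc = Mc,
       cache = list(gap = gap, gmp = gmp, amax = amax, pa = pa, pm = pm,
                    Mc = Mc, d = d, HW = HW, mlp_relu = mlp_relu))
}

cam_bwd <- function(dMc, cache, w) {
  d <- cache$d
  N <- d[1L]; C <- d[2L]; HW <- cache$HW
  ds <- dMc * cache$Mc * (1 - cache$Mc)
  back_path <- function(p, g) {
    dW1 <- ds %*% t(p$h)
    dh <- crossprod(w$W1, ds)
    if (cache$mlp_relu) dh <- dh * (p$pre > 0)
    dW0 <- dh %*% t(g)
    dg <- crossprod(w$W0, dh)
    list(dW0 = dW0, dW1 = dW1, dg = dg)
  }
  ba <- back_path(cache$pa, cache$gap)
  bm <- back_path(cache$pm, cache$gmp)
  # scatter descriptor gradients back over space
  dm <- matrix(rep(as.numeric(ba$dg) / HW, each = HW), nrow = HW)
  j <- seq_len(C * N)
  dm[cache$amax + (j - 1L) * HW] <- dm[cache$amax + (j - 1L) * HW] +
    as.numeric(bm$dg)
  dS <- aperm(array(dm, c(d[3L], d[4L], C, N)), c(4L, 3L, 1L, 2L))
  list(dS = dS, grads = list(W0 = ba$dW0 + bm$dW0, W1 = ba$dW1 + bm$dW1))
}

#' Initialise PCAM parameters
#'
#' @param channels input channel count `C`.
#' @param config a [pcam_config()].
#' @return nested parameter list (`cam`, and `fuse_bn`/`fuse_conv` when
#'   fusion is enabled).
#' @export
init_pcam <- function(channels, config = pcam_config()) {
  nb <- length(config$pool_sizes)
  p <- list(cam = cam_weights(channels * nb, config$reduction_ratio))
  if (config$fuse_to_input_channels) {
    cc <- channels * (nb + 1L)
    p$fuse_bn <- init_bn(cc)
    p$fuse_conv <- init_conv(cc, channels, 1L)
  }
  p
}

#' Pyramid channel attention forward pass
#'
#' Computes `SMc = [F, S * Mc(S)]` where `S` is the SPP description of the
#' input `F` and `Mc` the channel attention gates; when fusion is enabled a
#' pre-activated (BN-ReLU) 1x1 convolution maps the concatenation back to
#' the input channel count.
#'
#' @param x feature map `(N, C, H, W)`.
#' @param config a [pcam_config()].
#' @param params parameters from [init_pcam()] for `C` channels.
#' @param training logical; affects batch-norm statistics in the fusion.
#' @param attention_override optional `C * n_branches x N` matrix replacing
#'   the computed gates (diagnostics: all-ones reduces the module to plain
#'   concatenation before fusion).
#' @return feature map with `C` channels (fusion on) or
#'   `(1 + n_branches) * C` channels (fusion off).
#' @export
pcam_forward <- function(x, config = pcam_config(),
                         params = init_pcam(dim(x)[2L], config),
                         training = FALSE, attention_override = NULL) {
  stats <- new.env(parent = emptyenv())
  pcam_fwd(x, params, config, training, stats, key = "pcam",
           attention_override = attention_override)$out
}

pcam_fwd <- function(x, p, config, training, stats, key,
                     attention_override = NULL) {
  d <- dim(x)
  sp <- spp_fwd(x, config$pool_sizes)
  S <- sp$S
  C4 <- dim(S)[2L]
  if (C4 != ncol(p$cam$W0))
    stop(sprintf("channel mismatch: pyramid has %d channels, weights expect %d",
                 C4, ncol(p$cam$W0)))
  if (is.null(attention_override)) {
    cf <- cam_fwd(S, p$cam, config$mlp_relu)
    Mc <- cf$Mc
  } else {
    cf <- NULL
    Mc <- matrix(attention_override, C4, d[1L])
  }
  McArr <- aperm(array(Mc, c(C4, d[1L], d[3L], d[4L])), c(2L, 1L, 3L, 4L))
  attended <- S * McArr
  P <- concat_channels(x, attended)
  cache <- list(sp = sp, cf = cf, S = S, McArr = McArr, d = d, C4 = C4,
                override = !is.null(attention_override))
  if (config$fuse_to_input_channels) {
    b <- bn_fwd(P, p$fuse_bn, stats, paste0(key, ".fuse_bn"), training)
    r <- relu_fwd(b$out)
    cv <- conv_fwd(r$out, p$fuse_conv)
    cache$bn <- b$cache; cache$relu <- r$cache; cache$conv <- cv$cache
    list(out = cv$out, cache = cache)
  } else {
    list(out = P, cache = cache)
  }
}

pcam_bwd <- function(grad, cache, p, config) {
  grads <- list()
  if (config$fuse_to_input_channels) {
    cb <- conv_bwd(grad, cache$conv)
    grads$fuse_conv <- cb$grads
    rg <- relu_bwd(cb$dx, cache$relu)
    bb <- bn_bwd(rg, cache$bn)
    grads$fuse_bn <- bb$grads
    dP <- bb$dx
  } else {
    dP <- grad
  }
  C <- cache$d[2L]
  dx_direct <- dP[, seq_len(C), , , drop = FALSE]
  dattended <- dP[, C + seq_len(cache$C4), , , drop = FALSE]
  dS <- dattended * cache$McArr
  if (!cache$override) {
    dMc <- apply(dattended * cache$S, c(2L, 1L), sum)   # C4 x N
    cbk <- cam_bwd(dMc, cache$cf$cache, p$cam)
    dS <- dS + cbk$dS
    grads$cam <- cbk$grads
  } else {
    grads$cam <- list(W0 = array(0, dim(p$cam$W0)),
                      W1 = array(0, dim(p$cam$W1)))
  }
  dx <- dx_direct + spp_bwd(dS, cache$sp)
  list(dx = dx, grads = grads)
}
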