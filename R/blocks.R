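#' Convolution block configuration
#'
#' @param in_channels,out_channels positive integers.
#' @param kernel_size odd positive integer (default 3) so that same-padding
#'   preserves the spatial size.
#' @param dropblock a [dropblock_params()] object (used by the residual
#'   block only).
#' @return object of class `block_config`; `use_projection_shortcut` is
#'   derived from the channel counts.
#' @export
block_config <- function(in_channels, out_channels, kernel_size = 3L,
                         dropblock = dropblock_params()) {
  kernel_size <- as.integer(kernel_size)
  if (kernel_size < 1L || kernel_size %% 2L == 0L)
    stop("kernel_size must be an odd positive integer")
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 kernel_size = kernel_size,
                 dropblock = dropblock,
                 use_projection_shortcut = in_channels != out_channels),
            class = "block_config")
}

#' Initialise a pre-activated residual DropBlock (PRDC) block
#'
#' @param config a [block_config()].
#' @return nested parameter list (`bn1`, `conv1`, `bn2`, `conv2`, and `proj`
#'   when the shortcut needs a 1x1 projection).
#' @export
init_prdc <- function(config) {
  k <- config$kernel_size
  p <- list(bn1 = init_bn(config$in_channels),
            conv1 = init_conv(config$in_channels, config$out_channels, k),
            bn2 = init_bn(config$out_channels),
            conv2 = init_conv(config$out_channels, config$out_channels, k))
  if (config$use_projection_shortcut)
    p$proj <- init_conv(config$in_channels, config$out_channels, 1L)
  p
}

#' Pre-activated residual DropBlock block forward pass
#'
#' Residual branch `[BN -> ReLU -> conv -> DropBlock] x 2` added to an
#' identity shortcut (1x1 projection when the channel counts differ):
#' `y = shortcut(x) + F(x)`. Spatial size is preserved.
#'
#' @param x feature map with `config$in_channels` channels.
#' @param config a [block_config()].
#' @param params parameters from [init_prdc()].
#' @param training logical; enables DropBlock and batch statistics.
#' @return feature map with `config$out_channels` channels.
#' @export
prdc_forward <- function(x, config, params = init_prdc(config),
                         training = FALSE) {
  stats <- new.env(parent = emptyenv())
  prdc_fwd(x, params, config, training, stats, key = "prdc")$out
}

prdc_fwd <- function(x, p, config, training, stats, key) {
  if (dim(x)[2L] != config$in_channels)
    stop(sprintf("channel mismatch: input has %d channels, block expects %d",
                 dim(x)[2L], config$in_channels))
  db <- config$dropblock
  b1 <- bn_fwd(x, p$bn1, stats, paste0(key, ".bn1"), training)
  r1 <- relu_fwd(b1$out)
  c1 <- conv_fwd(r1$out, p$conv1)
  d1 <- dropblock_fwd(c1$out, db, training)
  b2 <- bn_fwd(d1$out, p$bn2, stats, paste0(key, ".bn2"), training)
  r2 <- relu_fwd(b2$out)
  c2 <- conv_fwd(r2$out, p$conv2)
  d2 <- dropblock_fwd(c2$out, db, training)
  if (config$use_projection_shortcut) {
    sc <- conv_fwd(x, p$proj)
    short <- sc$out
    sc_cache <- sc$cache
  } else {
    short <- x
    sc_cache <- NULL
  }
  list(out = short + d2$out,
       cache = list(b1 = b1$cache, r1 = r1$cache, c1 = c1$cache,
                    d1 = d1$cache, b2 = b2$cache, r2 = r2$cache,
                    c2 = c2$cache, d2 = d2$cache, sc = sc_cache,
                    proj = config$use_projection_shortcut))
}

prdc_bwd <- function(grad, cache) {
  g2 <- dropblock_bwd(grad, cache$d2)
  cb2 <- conv_bwd(g2, cache$c2)
  rb2 <- relu_bwd(cb2$dx, cache$r2)
  bb2 <- bn_bwd(rb2, cache$b2)
  g1 <- dropblock_bwd(bb2$dx, cache$d1)
  cb1 <- conv_bwd(g1, cache$c1)
  rb1 <- relu_bwd(cb1$dx, cache$r1)
  bb1 <- bn_bwd(rb1, cache$b1)
  grads <- list(bn1 = bb1$grads, conv1 = cb1$grads,
                bn2 = bb2$grads, conv2 = cb2$grads)
  if (cache$proj) {
    sb <- conv_bwd(grad, cache$sc)
    grads$proj <- sb$grads
    dx <- bb1$dx + sb$dx
  } else {
    dx <- bb1$dx + grad
  }
  list(dx = dx, grads = grads)
}

#' Initialise a plain (baseline U-Net) convolution block
#'
#' @param config a [block_config()].
#' @return nested parameter list.
#' @export
init_plain <- function(config) {
  k <- config$kernel_size
  list(conv1 = init_conv(config$in_channels, config$out_channels, k),
       bn1 = init_bn(config$out_channels),
       conv2 = init_conv(config$out_channels, config$out_channels, k),
       bn2 = init_bn(config$out_channels))
}

#' Plain convolution block forward pass
#'
#' Baseline U-Net block `y = F(x)`: two `conv -> BN -> ReLU` stages, no
#' shortcut, no DropBlock. Kept so ablations can swap block types under an
#' identical stage/channel layout.
#'
#' @inheritParams prdc_forward
#' @return feature map with `config$out_channels` channels.
#' @export
plain_conv_block <- function(x, config, params = init_plain(config),
                             training = FALSE) {
  stats <- new.env(parent = emptyenv())
  plain_fwd(x, params, config, training, stats, key = "plain")$out
}

plain_fwd <- function(x, p, config, training, stats, key) {
  if (dim(x)[2L] != config$in_channels)
    stop(sprintf("channel mismatch: input has %d channels, block expects %d",
                 dim(x)[2L], config$in_channels))
  c1 <- conv_fwd(x, p$conv1)
  b1 <- bn_fwd(c1$out, p$bn1, stats, paste0(key, ".bn1"), training)
  r1 <- relu_fwd(b1$out)
  c2 <- conv_fwd(r1$out, p$conv2)
  b2 <- bn_fwd(c2$out, p$bn2, stats, paste0(key, ".bn2"), training)
  r2 <- relu_fwd(b2$out)
  list(out = r2$out,
       cache = list(c1 = c1$cache, b1 = b1$cache, r1 = r1$cache,
                    c2 = c2$cache, b2 = b2$cache, r2 = r2$cache))
}

plain_bwd <- function(grad, cache) {
  g <- relu_bwd(grad, cache$r2)
  bb2 <- bn_bwd(g, cache$b2)
  cb2 <- conv_bwd(bb2$dx, cache$c2)
  g <- relu_bwd(cb2$dx, cache$r1)
  bb1 <- bn_bwd(g, cache$b1)
  cb1 <- conv_bwd(bb1$dx, cache$c1)
  list(dx = cb1$dx,
       grads = list(conv1 = cb1$grads, bn1 = bb1$grads,
                    conv2 = cb2$grads, bn2 = bb2$grads))
}
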