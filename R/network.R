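#' Model configuration
#'
#' Describes the U-shaped encoder-decoder: `depth` down/up-sampling stages
#' of convolution blocks with channel widths doubling from `base_channels`,
#' pyramid channel attention in the encoder, skip connections, and a
#' single-channel sigmoid head. `block_type` and `use_pcam` select the
#' ablation variant (plain blocks without attention reproduce the baseline
#' U-Net stage/channel layout exactly).
#'
#' @param depth number of down/up-sampling stages (default 4).
#' @param base_channels channels of the first stage (default 32), doubling
#'   per stage.
#' @param in_channels input image channels (default 3).
#' @param pcam a [pcam_config()].
#' @param dropblock a [dropblock_params()].
#' @param use_pcam include pyramid channel attention (default `TRUE`).
#' @param block_type `"prdc"` (pre-activated residual DropBlock block) or
#'   `"plain"` (baseline U-Net block).
#' @param pcam_placement `"every_encoder_stage"` (default: after each
#'   encoder block, feeding both the skip connection and the downsample) or
#'   `"bottleneck_only"`.
#' @return object of class `model_config`.
#' @export
model_config <- function(depth = 4L, base_channels = 32L, in_channels = 3L,
                         pcam = pcam_config(), dropblock = dropblock_params(),
                         use_pcam = TRUE, block_type = c("prdc", "plain"),
                         pcam_placement = c("every_encoder_stage",
                                            "bottleneck_only")) {
  depth <- as.integer(depth)
  if (depth < 1L) stop("depth must be >= 1")
  structure(list(depth = depth,
                 base_channels = as.integer(base_channels),
                 in_channels = as.integer(in_channels),
                 pcam = pcam, dropblock = dropblock,
                 use_pcam = isTRUE(use_pcam),
                 block_type = match.arg(block_type),
                 pcam_placement = match.arg(pcam_placement)),
            class = "model_config")
}

#' Ablation variant configurations
#'
#' Returns the `model_config` for one of the four ablation variants:
#' `"baseline"` (plain blocks, no attention), `"baseline+PCAM"`,
#' `"baseline+PRDC"`, `"baseline+PCAM+PRDC"`.
#'
#' @param variant variant name.
#' @param ... further arguments passed to [model_config()].
#' @return a [model_config()].
#' @export
variant_config <- function(variant = c("baseline", "baseline+PCAM",
                                       "baseline+PRDC",
                                       "baseline+PCAM+PRDC"), ...) {
  variant <- match.arg(variant)
  model_config(use_pcam = variant %in% c("baseline+PCAM",
                                         "baseline+PCAM+PRDC"),
               block_type = if (variant %in% c("baseline+PRDC",
                                               "baseline+PCAM+PRDC"))
                 "prdc" else "plain",
               ...)
}

enc_channels <- function(config) config$base_channels * 2L^(seq_len(config$depth) - 1L)

init_block <- function(config, c_in, c_out) {
  bc <- block_config(c_in, c_out, 3L, config$dropblock)
  if (config$block_type == "prdc") init_prdc(bc) else init_plain(bc)
}

block_dispatch_fwd <- function(config, x, p, c_in, c_out, training, stats, key) {
  bc <- block_config(c_in, c_out, 3L, config$dropblock)
  if (config$block_type == "prdc")
    prdc_fwd(x, p, bc, training, stats, key)
  else
    plain_fwd(x, p, bc, training, stats, key)
}

block_dispatch_bwd <- function(config, grad, cache) {
  if (config$block_type == "prdc") prdc_bwd(grad, cache) else plain_bwd(grad, cache)
}

#' Build a segmentation model
#'
#' Instantiates all parameters of the configured network with He
#' initialisation. Building twice from the same seed yields identical
#' parameters.
#'
#' @param config a [model_config()].
#' @param seed optional integer seed for reproducible initialisation.
#' @return object of class `pcam_model`.
#' @export
build_model <- function(config = model_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ch <- enc_channels(config)
  d <- config$depth
  params <- list(enc = vector("list", d), dec = vector("list", d))
  c_in <- config$in_channels
  for (i in seq_len(d)) {
    st <- list(block = init_block(config, c_in, ch[i]))
    if (config$use_pcam && config$pcam_placement == "every_encoder_stage")
      st$pcam <- init_pcam(ch[i], config$pcam)
    params$enc[[i]] <- st
    c_in <- ch[i]
  }
  cb <- config$base_channels * 2L^d
  params$bottleneck <- list(block = init_block(config, ch[d], cb))
  if (config$use_pcam && config$pcam_placement == "bottleneck_only")
    params$bottleneck$pcam <- init_pcam(cb, config$pcam)
  c_up <- cb
  for (i in rev(seq_len(d))) {
    params$dec[[i]] <- list(up = init_conv(c_up, ch[i], 1L),
                            block = init_block(config, 2L * ch[i], ch[i]))
    c_up <- ch[i]
  }
  params$head <- init_conv(ch[1L], 1L, 1L)
  structure(list(config = config, params = params,
                 stats = new.env(parent = emptyenv())),
            class = "pcam_model")
}

#' Number of trainable parameters
#' @param model a `pcam_model`.
#' @return integer count.
#' @export
n_parameters <- function(model) {
  sum(vapply(flatten_params(model$params), length, integer(1)))
}

#' Number of pyramid attention modules in a model
#' @param model a `pcam_model`.
#' @return integer count.
#' @export
n_pcam_modules <- function(model) {
  n <- sum(vapply(model$params$enc, function(s) !is.null(s$pcam), logical(1)))
  n + !is.null(model$params$bottleneck$pcam)
}

check_input_geometry <- function(config, d) {
  div <- 2L^config$depth
  if (d[3L] %% div != 0L || d[4L] %% div != 0L)
    stop(sprintf(paste0("input spatial size %dx%d is not divisible by 2^depth",
                        " = %d; pad the image to a multiple first"),
                 d[3L], d[4L], div))
  if (d[2L] != config$in_channels)
    stop(sprintf("input has %d channels, model expects %d",
                 d[2L], config$in_channels))
}

net_fwd <- function(model, x, training = FALSE) {
  cfg <- model$config
  check_input_geometry(cfg, dim(x))
  ch <- enc_channels(cfg)
  d <- cfg$depth
  stats <- model$stats
  p <- model$params
  skips <- vector("list", d)
  cache <- list(enc = vector("list", d), dec = vector("list", d))
  h <- x
  c_in <- cfg$in_channels
  for (i in seq_len(d)) {
    bf <- block_dispatch_fwd(cfg, h, p$enc[[i]]$block, c_in, ch[i],
                             training, stats, sprintf("enc%d", i))
    h <- bf$out
    st <- list(block = bf$cache)
    if (!is.null(p$enc[[i]]$pcam)) {
      pf <- pcam_fwd(h, p$enc[[i]]$pcam, cfg$pcam, training, stats,
                     sprintf("enc%d.pcam", i))
      h <- pf$out
      st$pcam <- pf$cache
    }
    skips[[i]] <- h
    pl <- pool_fwd(h, 2L)
    st$pool <- pl$cache
    h <- pl$out
    cache$enc[[i]] <- st
    c_in <- ch[i]
  }
  cb <- cfg$base_channels * 2L^d
  bf <- block_dispatch_fwd(cfg, h, p$bottleneck$block, ch[d], cb,
                           training, stats, "bottleneck")
  h <- bf$out
  cache$bottleneck <- list(block = bf$cache)
  if (!is.null(p$bottleneck$pcam)) {
    pf <- pcam_fwd(h, p$bottleneck$pcam, cfg$pcam, training, stats,
                   "bottleneck.pcam")
    h <- pf$out
    cache$bottleneck$pcam <- pf$cache
  }
  for (i in rev(seq_len(d))) {
    uf <- upsample2_fwd(h)
    uc <- conv_fwd(uf$out, p$dec[[i]]$up)
    cc <- concat_channels(uc$out, skips[[i]])
    bf <- block_dispatch_fwd(cfg, cc, p$dec[[i]]$block, 2L * ch[i], ch[i],
                             training, stats, sprintf("dec%d", i))
    cache$dec[[i]] <- list(up = uf$cache, upconv = uc$cache, block = bf$cache)
    h <- bf$out
  }
  hd <- conv_fwd(h, p$head)
  cache$head <- hd$cache
  list(logits = hd$out, cache = cache)
}

net_bwd <- function(model, dlogits, cache) {
  cfg <- model$config
  ch <- enc_channels(cfg)
  d <- cfg$depth
  p <- model$params
  grads <- list(enc = vector("list", d), dec = vector("list", d))
  hb <- conv_bwd(dlogits, cache$head)
  grads$head <- hb$grads
  dh <- hb$dx
  dskips <- vector("list", d)
  for (i in seq_len(d)) {
    bb <- block_dispatch_bwd(cfg, dh, cache$dec[[i]]$block)
    dcc <- bb$dx
    dup <- dcc[, seq_len(ch[i]), , , drop = FALSE]
    dskips[[i]] <- dcc[, ch[i] + seq_len(ch[i]), , , drop = FALSE]
    ub <- conv_bwd(dup, cache$dec[[i]]$upconv)
    dh <- upsample2_bwd(ub$dx, cache$dec[[i]]$up)
    grads$dec[[i]] <- list(up = ub$grads, block = bb$grads)
  }
  gb <- list()
  if (!is.null(cache$bottleneck$pcam)) {
    pb <- pcam_bwd(dh, cache$bottleneck$pcam, p$bottleneck$pcam, cfg$pcam)
    gb$pcam <- pb$grads
    dh <- pb$dx
  }
  bb <- block_dispatch_bwd(cfg, dh, cache$bottleneck$block)
  gb$block <- bb$grads
  grads$bottleneck <- gb
  dh <- bb$dx
  for (i in rev(seq_len(d))) {
    dh <- pool_bwd(dh, cache$enc[[i]]$pool) + dskips[[i]]
    gs <- list()
    if (!is.null(cache$enc[[i]]$pcam)) {
      pb <- pcam_bwd(dh, cache$enc[[i]]$pcam, p$enc[[i]]$pcam, cfg$pcam)
      gs$pcam <- pb$grads
      dh <- pb$dx
    }
    bb <- block_dispatch_bwd(cfg, dh, cache$enc[[i]]$block)
    gs$block <- bb$grads
    grads$enc[[i]] <- gs
    dh <- bb$dx
  }
  # encoder stage order in grads$enc must match params$enc field order
  for (i in seq_len(d)) {
    if (!is.null(grads$enc[[i]]$pcam))
      grads$enc[[i]] <- grads$enc[[i]][c("block", "pcam")]
  }
  if (!is.null(grads$bottleneck$pcam))
    grads$bottleneck <- grads$bottleneck[c("block", "pcam")]
  list(grads = grads, dx = dh)
}

#' Predict vessel probabilities
#'
#' Runs the network in inference mode (DropBlock inactive, batch norm using
#' running statistics); the same input always yields the same output.
#'
#' @param object a `pcam_model`.
#' @param x input tensor `(N, in_channels, H, W)` with `H`, `W` divisible by
#'   `2^depth`.
#' @param ... unused.
#' @return probability array `(N, H, W)` with entries in `[0, 1]`.
#' @export
predict.pcam_model <- function(object, x, ...) {
  if (length(dim(x)) == 3L) dim(x) <- c(1L, dim(x))
  f <- net_fwd(object, x, training = FALSE)
  p <- sigmoid(f$logits)
  array(p, dim = dim(p)[c(1L, 3L, 4L)])
}

#' Threshold a probability map
#'
#' Uses the `>=` convention, so ties at the threshold become foreground.
#'
#' @param p numeric array of probabilities.
#' @param threshold scalar in `[0, 1]`.
#' @return integer 0/1 array of the same shape.
#' @export
binarize <- function(p, threshold = 0.5) {
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  out <- array(as.integer(p >= threshold), dim = dim(p))
  out
}

# --- parameter tree utilities ------------------------------------------------

flatten_params <- function(p, prefix = "") {
  if (is.numeric(p)) {
    out <- list(p)
    names(out) <- prefix
    return(out)
  }
  out <- list()
  nms <- names(p)
  if (is.null(nms)) nms <- as.character(seq_along(p))
  for (i in seq_along(p)) {
    if (is.null(p[[i]])) next
    out <- c(out, flatten_params(p[[i]], paste0(prefix, "/", nms[i])))
  }
  out
}

unflatten_params <- function(flat, template) {
  i <- 0L
  rebuild <- function(t) {
    if (is.numeric(t)) {
      i <<- i + 1L
      v <- flat[[i]]
      if (!is.null(dim(t))) dim(v) <- dim(t)
      return(v)
    }
    out <- t
    for (k in seq_along(t)) if (!is.null(t[[k]])) out[[k]] <- rebuild(t[[k]])
    out
  }
  rebuild(template)
}

#' Save a model checkpoint
#'
#' Writes a single file containing the full configuration, all trainable
#' parameters, batch-norm running statistics, and the package version.
#'
#' @param model a `pcam_model`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config = model$config, params = model$params,
               stats = as.list(model$stats),
               version = as.character(utils::packageVersion("pcamseg"))),
          path)
  invisible(path)
}

#' Load a model checkpoint
#' @param path file written by [save_checkpoint()].
#' @return a `pcam_model`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  stats <- new.env(parent = emptyenv())
  for (k in names(ck$stats)) assign(k, ck$stats[[k]], envir = stats)
  structure(list(config = ck$config, params = ck$params, stats = stats),
            class = "pcam_model")
}
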