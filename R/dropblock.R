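#' DropBlock parameters
#'
#' DropBlock is a structured form of dropout for convolutional feature maps:
#' instead of zeroing independent units it zeroes contiguous `beta x beta`
#' squares, which removes semantic regions rather than isolated activations.
#' With `block_size = 1` it reduces exactly to ordinary dropout.
#'
#' @param keep_prob probability of keeping a unit, in `(0, 1]`.
#' @param block_size odd positive integer `beta`, side of each dropped square.
#' @param shared_channels logical; if `TRUE` (default) one mask per sample is
#'   shared across all channels, otherwise each channel draws its own mask.
#' @return an object of class `dropblock_params`.
#' @export
dropblock_params <- function(keep_prob = 0.9, block_size = 7,
                             shared_channels = TRUE) {
  if (!is.numeric(keep_prob) || keep_prob <= 0 || keep_prob > 1)
    stop("keep_prob must lie in (0, 1]")
  block_size <- as.integer(block_size)
  if (block_size < 1L) stop("block_size must be a positive integer")
  if (block_size %% 2L == 0L) stop("block_size must be odd")
  structure(list(keep_prob = keep_prob, block_size = block_size,
                 shared_channels = isTRUE(shared_channels)),
            class = "dropblock_params")
}

#' Seed rate of DropBlock
#'
#' Computes the per-position seed probability `rho` such that dropping a
#' `beta x beta` square around every seed removes, in expectation, a fraction
#' `1 - keep_prob` of the `w x h` feature map. Seeds are only planted in the
#' `(w - beta + 1) x (h - beta + 1)` interior so squares never cross borders:
#'
#' `rho = (1 - keep_prob) * w * h / (beta^2 * (w - beta + 1) * (h - beta + 1))`
#'
#' @param keep_prob keep probability in `(0, 1]`.
#' @param width,height feature-map width `w` and height `h`.
#' @param block_size square side `beta`; must not exceed `width` or `height`.
#' @return the seed rate `rho` (nonnegative scalar).
#' @export
dropblock_gamma <- function(keep_prob, width, height, block_size) {
  if (!is.numeric(keep_prob) || keep_prob <= 0 || keep_prob > 1)
    stop("keep_prob must lie in (0, 1]")
  if (block_size > width || block_size > height)
    stop(sprintf("block_size %d exceeds feature size %dx%d",
                 block_size, height, width))
  (1 - keep_prob) * (width * height) /
    (block_size^2 * (width - block_size + 1) * (height - block_size + 1))
}

# Sample one binary keep-mask (H x W). Seeds ~ Bernoulli(rho) in the interior;
# each seed zeroes the beta x beta square centred on it.
sample_dropblock_mask <- function(H, W, keep_prob, beta) {
  rho <- dropblock_gamma(keep_prob, W, H, beta)
  half <- (beta - 1L) %/% 2L
  hs <- (1L + half):(H - half)   # valid seed centres
  ws <- (1L + half):(W - half)
  seeds <- matrix(rbinom(length(hs) * length(ws), 1L, min(rho, 1)) == 1L,
                  length(hs), length(ws))
  mask <- matrix(1, H, W)
  idx <- which(seeds, arr.ind = TRUE)
  if (nrow(idx) > 0L) {
    for (i in seq_len(nrow(idx))) {
      hc <- hs[idx[i, 1L]]
      wc <- ws[idx[i, 2L]]
      mask[(hc - half):(hc + half), (wc - half):(wc + half)] <- 0
    }
  }
  mask
}

#' Apply DropBlock to a feature map
#'
#' In training mode, plants block seeds at the rate given by
#' [dropblock_gamma()], zeroes the corresponding `beta x beta` squares and
#' rescales surviving activations by `total / kept` so the expected
#' activation magnitude matches inference. In inference mode the input is
#' returned unchanged. Randomness comes from the R session RNG; seed it for
#' reproducibility.
#'
#' @param x feature map, `(N, C, H, W)` array.
#' @param params a [dropblock_params()] object.
#' @param training logical; masks are only sampled when `TRUE`.
#' @return a feature map of the same shape.
#' @export
dropblock <- function(x, params, training = FALSE) {
  dropblock_fwd(x, params, training)$out
}

dropblock_fwd <- function(x, params, training) {
  if (!training || params$keep_prob >= 1) {
    return(list(out = x, cache = NULL))
  }
  d <- dim(x)
  N <- d[1L]; C <- d[2L]; H <- d[3L]; W <- d[4L]
  beta <- params$block_size
  if (beta > H || beta > W)
    stop(sprintf("block_size %d exceeds feature size %dx%d", beta, H, W))
  scale_mask <- array(0, d)
  groups <- if (params$shared_channels) 1L else C
  for (n in seq_len(N)) {
    for (g in seq_len(groups)) {
      m <- sample_dropblock_mask(H, W, params$keep_prob, beta)
      kept <- sum(m)
      sm <- if (kept == 0) m else m * (length(m) / kept)
      if (params$shared_channels) {
        for (c in seq_len(C)) scale_mask[n, c, , ] <- sm
      } else {
        scale_mask[n, g, , ] <- sm
      }
    }
  }
  list(out = x * scale_mask, cache = scale_mask)
}

dropblock_bwd <- function(grad, cache) {
  if (is.null(cache)) grad else grad * cache
}
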