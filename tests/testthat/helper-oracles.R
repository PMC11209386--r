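# Independent oracles used to cross-check the package implementation.
# These are deliberately naive double-loop versions, kept free of any code
# path they validate.

ns <- asNamespace("pcamseg")

# Non-overlapping max pooling (kernel = stride = k, ceil mode) on a matrix.
brute_maxpool <- function(m, k) {
  H <- nrow(m); W <- ncol(m)
  Ho <- ceiling(H / k); Wo <- ceiling(W / k)
  out <- matrix(-Inf, Ho, Wo)
  for (i in seq_len(Ho)) {
    for (j in seq_len(Wo)) {
      rows <- ((i - 1) * k + 1):min(i * k, H)
      cols <- ((j - 1) * k + 1):min(j * k, W)
      out[i, j] <- max(m[rows, cols])
    }
  }
  out
}

# Half-pixel bilinear resize of a matrix, edge-clamped, scalar loops.
naive_bilinear <- function(m, Ho, Wo) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, Ho, Wo)
  for (i in seq_len(Ho)) {
    sy <- (i - 0.5) * H / Ho - 0.5
    y0 <- floor(sy); ty <- sy - y0
    y0c <- min(max(y0, 0), H - 1) + 1
    y1c <- min(max(y0 + 1, 0), H - 1) + 1
    for (j in seq_len(Wo)) {
      sx <- (j - 0.5) * W / Wo - 0.5
      x0 <- floor(sx); tx <- sx - x0
      x0c <- min(max(x0, 0), W - 1) + 1
      x1c <- min(max(x0 + 1, 0), W - 1) + 1
      out[i, j] <- (1 - ty) * ((1 - tx) * m[y0c, x0c] + tx * m[y0c, x1c]) +
        ty * ((1 - tx) * m[y1c, x0c] + tx * m[y1c, x1c])
    }
  }
  out
}

# Direct evaluation of the channel-attention formula on descriptor vectors:
# sigmoid(W1 f(W0 avg) + W1 f(W0 max)) with shared weights.
cam_direct <- function(avg_vec, max_vec, W0, W1, relu = TRUE) {
  f <- function(v) if (relu) pmax(v, 0) else v
  1 / (1 + exp(-(W1 %*% f(W0 %*% avg_vec) + W1 %*% f(W0 %*% max_vec))))
}

# Hand-computed segmentation scores from raw counts.
metrics_direct <- function(tp, fp, tn, fn) {
  list(iou = tp / (tp + fp + fn),
       acc = (tp + tn) / (tp + fp + tn + fn),
       sen = tp / (tp + fn),
       spe = tn / (tn + fp),
       f1 = 2 * tp / (2 * tp + fp + fn))
}

# Small deterministic phantom sets for training tests.
tiny_phantoms <- function(n, seed, size = c(64L, 64L)) {
  generate_dataset(n, phantom_params(size = size), seed = seed)
}

rand_fm <- function(dims, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(rnorm(prod(dims)), dim = dims)
}
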