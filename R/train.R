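#' Training configuration
#'
#' All training hyperparameters are repository conventions (the choice of
#' optimiser, schedule and loss is open); defaults are Adam, learning rate
#' 1e-3, batch size 4, 50 epochs, pixelwise binary cross-entropy.
#'
#' @param epochs,batch_size,lr positive scalars.
#' @param optimizer only `"adam"` is provided.
#' @param loss `"bce"` or `"bce+dice"` (BCE plus a soft-Dice term, useful on
#'   short schedules with heavy class imbalance).
#' @param seed integer seed controlling initialisation, shuffling, DropBlock
#'   and augmentation.
#' @param augment optional [augmentation_config()] applied per-sample,
#'   per-epoch; `NULL` disables augmentation.
#' @param threshold binarisation threshold used when evaluating (default 0.5).
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 50L, batch_size = 4L, lr = 1e-3,
                         optimizer = "adam", loss = c("bce", "bce+dice"),
                         seed = 1L, augment = NULL, threshold = 0.5) {
  if (epochs < 1L || batch_size < 1L || lr <= 0)
    stop("epochs, batch_size and lr must be positive")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 optimizer = match.arg(optimizer, "adam"),
                 loss = match.arg(loss), seed = as.integer(seed),
                 augment = augment, threshold = threshold),
            class = "train_config")
}

# BCE from logits: softplus(z) - y*z, numerically stable for large |z|.
bce_from_logits <- function(z, y) {
  sp <- ifelse(z > 0, z + log1p(exp(-z)), log1p(exp(z)))
  mean(sp - y * z)
}

# Loss value and gradient w.r.t. logits.
loss_and_grad <- function(z, y, loss) {
  p <- sigmoid(z)
  n <- length(z)
  l <- bce_from_logits(z, y)
  dz <- (p - y) / n
  if (loss == "bce+dice") {
    s <- 1
    num <- 2 * sum(p * y) + s
    den <- sum(p) + sum(y) + s
    l <- l + (1 - num / den)
    dp <- -(2 * y * den - num) / den^2
    dz <- dz + dp * p * (1 - p)
  }
  list(loss = l, dz = dz)
}

adam_init <- function(pflat) {
  list(m = lapply(pflat, function(x) x * 0),
       v = lapply(pflat, function(x) x * 0), t = 0L)
}

adam_step <- function(pflat, gflat, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  gflat <- gflat[names(pflat)]  # align gradients to parameters by path
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (k in names(pflat)) {
    g <- gflat[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g * g
    mhat <- state$m[[k]] / corr1
    vhat <- state$v[[k]] / corr2
    pflat[[k]] <- pflat[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(pflat = pflat, state = state)
}

# Stack samples into (N, C, H, W) input and (N, 1, H, W) target tensors.
samples_to_tensors <- function(samples) {
  H <- nrow(samples[[1L]]$vessel_mask)
  W <- ncol(samples[[1L]]$vessel_mask)
  N <- length(samples)
  x <- array(0, c(N, 3L, H, W))
  y <- array(0, c(N, 1L, H, W))
  for (i in seq_len(N)) {
    x[i, , , ] <- aperm(samples[[i]]$image, c(3L, 1L, 2L))
    y[i, 1L, , ] <- samples[[i]]$vessel_mask
  }
  list(x = x, y = y)
}

#' Train a model
#'
#' Minibatch Adam on pixelwise loss. Deterministic under a fixed
#' `config$seed`. Training aborts with a diagnostic if the loss becomes
#' non-finite. The model with the lowest epoch loss is retained as
#' `best_model`.
#'
#' @param model a `pcam_model` from [build_model()].
#' @param samples nonempty list of `fundus_sample` objects with equal sizes.
#' @param config a [train_config()].
#' @param batch_order optional list (one integer vector per epoch) fixing
#'   the sample visit order; used by [run_ablation()] to share the data
#'   stream across variants.
#' @return list with `model` (final), `best_model`, and `history`
#'   (data.frame of per-epoch mean loss).
#' @export
train <- function(model, samples, config = train_config(),
                  batch_order = NULL) {
  if (length(samples) == 0L) stop("training set is empty")
  set.seed(config$seed)
  if (is.null(batch_order))
    batch_order <- replicate(config$epochs, sample(length(samples)),
                             simplify = FALSE)
  pflat <- flatten_params(model$params)
  opt <- adam_init(pflat)
  history <- numeric(config$epochs)
  best <- Inf
  best_params <- model$params
  best_stats <- as.list(model$stats)
  for (ep in seq_len(config$epochs)) {
    ord <- batch_order[[ep]]
    losses <- c()
    for (start in seq(1L, length(ord), by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, length(ord))]
      batch <- samples[idx]
      if (!is.null(config$augment))
        batch <- lapply(batch, augment_sample, config = config$augment)
      tb <- samples_to_tensors(batch)
      fw <- net_fwd(model, tb$x, training = TRUE)
      lg <- loss_and_grad(fw$logits, tb$y, config$loss)
      if (!is.finite(lg$loss))
        stop(sprintf("training diverged: non-finite loss at epoch %d", ep))
      bw <- net_bwd(model, array(lg$dz, dim = dim(fw$logits)), fw$cache)
      gflat <- flatten_params(bw$grads)
      st <- adam_step(pflat, gflat, opt, config$lr)
      pflat <- st$pflat
      opt <- st$state
      model$params <- unflatten_params(pflat, model$params)
      losses <- c(losses, lg$loss)
    }
    history[ep] <- mean(losses)
    if (history[ep] < best) {
      best <- history[ep]
      best_params <- model$params
      best_stats <- as.list(model$stats)
    }
  }
  bm <- model
  bm$params <- best_params
  bm$stats <- new.env(parent = emptyenv())
  for (k in names(best_stats)) assign(k, best_stats[[k]], envir = bm$stats)
  list(model = model, best_model = bm,
       history = data.frame(epoch = seq_len(config$epochs), loss = history))
}

#' Evaluate a model on labelled samples
#'
#' Predicts every sample (patch-based when the image exceeds `patch_size`),
#' binarises at `threshold`, counts confusions inside the FoV mask and
#' aggregates.
#'
#' @param model a `pcam_model`.
#' @param samples list of `fundus_sample` objects.
#' @param threshold binarisation threshold.
#' @param mode aggregation mode, see [aggregate_reports()].
#' @param patch_size,stride patch inference geometry; `NULL` `patch_size`
#'   predicts whole images.
#' @return list with `aggregate` (a `metric_report`) and `per_image`
#'   (data.frame, one row per sample).
#' @export
evaluate_model <- function(model, samples, threshold = 0.5,
                           mode = c("pooled", "mean"), patch_size = NULL,
                           stride = NULL) {
  mode <- match.arg(mode)
  reports <- vector("list", length(samples))
  rows <- NULL
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    pm <- predict_sample(model, s, patch_size = patch_size, stride = stride)
    pred <- binarize(pm, threshold)
    cc <- confusion(pred, s$vessel_mask, s$fov_mask)
    reports[[i]] <- metrics(cc)
    rows <- rbind(rows, data.frame(id = s$id, as.data.frame(reports[[i]])))
  }
  list(aggregate = aggregate_reports(reports, mode = mode), per_image = rows)
}

#' Predict a single fundus sample
#'
#' @param model a `pcam_model`.
#' @param sample a `fundus_sample`.
#' @param patch_size,stride when `patch_size` is given the image is tiled
#'   with [make_patch_grid()] (default stride `patch_size / 2`), each patch
#'   predicted, and overlaps averaged back with [stitch_patches()].
#' @return `H x W` probability matrix.
#' @export
predict_sample <- function(model, sample, patch_size = NULL, stride = NULL) {
  img <- sample$image
  H <- dim(img)[1L]; W <- dim(img)[2L]
  if (is.null(patch_size)) {
    x <- array(aperm(img, c(3L, 1L, 2L)), c(1L, 3L, H, W))
    return(matrix(predict(model, x), H, W))
  }
  if (is.null(stride)) stride <- max(patch_size %/% 2L, 1L)
  grid <- make_patch_grid(H, W, patch_size, stride)
  patches <- extract_patches(img, grid)
  maps <- lapply(patches, function(pt) {
    x <- array(aperm(pt, c(3L, 1L, 2L)), c(1L, 3L, patch_size, patch_size))
    matrix(predict(model, x), patch_size, patch_size)
  })
  stitch_patches(maps, grid, H, W)
}

#' Run the ablation grid
#'
#' Builds, trains and evaluates each requested variant under identical data,
#' seeds and hyperparameters: the per-epoch sample order is drawn once from
#' `config$seed` and reused for every variant, so differences between rows
#' are architectural.
#'
#' @param train_samples,test_samples lists of `fundus_sample` objects.
#' @param variants character vector of [variant_config()] names.
#' @param config a [train_config()].
#' @param ... passed to [variant_config()] (e.g. `depth`, `base_channels`).
#' @return data.frame with one row per variant and columns
#'   `acc, sen, spe, f1, iou`.
#' @export
run_ablation <- function(train_samples, test_samples,
                         variants = c("baseline", "baseline+PCAM",
                                      "baseline+PRDC", "baseline+PCAM+PRDC"),
                         config = train_config(), ...) {
  if (length(variants) < 1L) stop("need at least one variant")
  set.seed(config$seed)
  batch_order <- replicate(config$epochs, sample(length(train_samples)),
                           simplify = FALSE)
  out <- NULL
  for (v in variants) {
    cfg <- variant_config(v, ...)
    model <- build_model(cfg, seed = config$seed)
    tr <- train(model, train_samples, config, batch_order = batch_order)
    ev <- evaluate_model(tr$model, test_samples, threshold = config$threshold)
    a <- ev$aggregate
    out <- rbind(out, data.frame(variant = v, acc = a$acc, sen = a$sen,
                                 spe = a$spe, f1 = a$f1, iou = a$iou))
  }
  out
}
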