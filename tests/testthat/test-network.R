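tiny_cfg <- function(...) {
  model_config(depth = 2, base_channels = 4,
               pcam = pcam_config(reduction_ratio = 4),
               dropblock = dropblock_params(0.9, 3), ...)
}

test_that("forward pass preserves spatial size and probability range", {
  m <- build_model(tiny_cfg(), seed = 1)
  for (sz in c(16, 32, 64, 96)) {
    x <- rand_fm(c(1, 3, sz, sz), seed = sz)
    p <- predict(m, x)
    expect_identical(dim(p), c(1L, as.integer(sz), as.integer(sz)))
    expect_true(all(is.finite(p)))
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("building and predicting are deterministic", {
  m1 <- build_model(tiny_cfg(), seed = 9)
  m2 <- build_model(tiny_cfg(), seed = 9)
  expect_identical(m1$params, m2$params)
  x <- rand_fm(c(1, 3, 16, 16), seed = 1)
  expect_identical(predict(m1, x), predict(m1, x))
})

test_that("a zeroed head yields probability one half everywhere", {
  m <- build_model(tiny_cfg(), seed = 2)
  m$params$head$W[] <- 0
  m$params$head$b[] <- 0
  p <- predict(m, rand_fm(c(1, 3, 16, 16), seed = 3))
  expect_true(all(p == 0.5))
})

test_that("attention placement controls the number of attention modules", {
  expect_identical(n_pcam_modules(build_model(tiny_cfg(), seed = 1)), 2L)
  expect_identical(
    n_pcam_modules(build_model(tiny_cfg(pcam_placement = "bottleneck_only"),
                               seed = 1)), 1L)
  expect_identical(n_pcam_modules(build_model(tiny_cfg(use_pcam = FALSE),
                                              seed = 1)), 0L)
})

test_that("parameter count matches a closed-form tally of the architecture", {
  cfg <- model_config(depth = 1, base_channels = 8, in_channels = 3,
                      pcam = pcam_config())  # pools 2,3,5,6; r = 16
  m <- build_model(cfg, seed = 1)
  conv_n <- function(ci, co, k) co * ci * k * k + co
  bn_n <- function(c) 2 * c
  prdc_n <- function(ci, co) bn_n(ci) + conv_n(ci, co, 3) +
    bn_n(co) + conv_n(co, co, 3) + if (ci != co) conv_n(ci, co, 1) else 0
  pcam_n <- function(c, nb = 4, r = 16) {
    c4 <- c * nb
    hidden <- max(c4 %/% r, 1)
    hidden * c4 + c4 * hidden +          # shared MLP, no biases
      bn_n(c * (nb + 1)) + conv_n(c * (nb + 1), c, 1)
  }
  expected <- prdc_n(3, 8) + pcam_n(8) +  # encoder stage
    prdc_n(8, 16) +                       # bottleneck
    conv_n(16, 8, 1) + prdc_n(16, 8) +    # decoder stage
    conv_n(8, 1, 1)                       # head
  expect_identical(n_parameters(m), as.integer(expected))
})

test_that("indivisible input sizes are rejected with padding advice", {
  m <- build_model(tiny_cfg(), seed = 1)
  expect_error(predict(m, rand_fm(c(1, 3, 18, 18))), "pad")
  expect_error(predict(m, rand_fm(c(1, 4, 16, 16))), "channels")
})

test_that("binarize follows the >= tie convention", {
  p <- array(c(0, 0.2, 0.5, 0.7, 1), c(1, 5, 1))
  expect_true(all(binarize(p, 0) == 1))
  expect_identical(sum(binarize(p, 1)), 1L)   # only the exact 1.0 survives
  half <- array(0.5, c(2, 2))
  expect_true(all(binarize(half, 0.5) == 1))
  expect_error(binarize(half, 1.5), "threshold")
})

test_that("analytic gradients match finite differences on a tiny network", {
  cfg <- model_config(depth = 1, base_channels = 4, in_channels = 2,
                      pcam = pcam_config(pool_sizes = c(2, 3),
                                         reduction_ratio = 2),
                      dropblock = dropblock_params(1, 3))  # DropBlock off
  m <- build_model(cfg, seed = 7)
  set.seed(42)
  x <- array(rnorm(2 * 8 * 8), c(1, 2, 8, 8))
  y <- array(rbinom(64, 1, 0.3), c(1, 1, 8, 8))
  loss_of <- function(model) {
    f <- ns$net_fwd(model, x, training = TRUE)
    ns$loss_and_grad(f$logits, y, "bce+dice")$loss
  }
  f <- ns$net_fwd(m, x, training = TRUE)
  lg <- ns$loss_and_grad(f$logits, y, "bce+dice")
  bw <- ns$net_bwd(m, array(lg$dz, dim = dim(f$logits)), f$cache)
  pflat <- ns$flatten_params(m$params)
  gflat <- ns$flatten_params(bw$grads)[names(pflat)]
  expect_setequal(names(ns$flatten_params(bw$grads)), names(pflat))
  eps <- 1e-5
  set.seed(99)
  for (trial in 1:25) {
    k <- sample(length(pflat), 1)
    j <- sample(length(pflat[[k]]), 1)
    pp <- pflat
    pp[[k]][j] <- pp[[k]][j] + eps
    mp <- m; mp$params <- ns$unflatten_params(pp, m$params)
    lp <- loss_of(mp)
    pp[[k]][j] <- pp[[k]][j] - 2 * eps
    mm <- m; mm$params <- ns$unflatten_params(pp, m$params)
    fd <- (lp - loss_of(mm)) / (2 * eps)
    an <- gflat[[k]][j]
    expect_lt(abs(fd - an) / max(abs(fd), abs(an), 1e-4), 1e-3)
  }
})

test_that("checkpoints round-trip bit-for-bit through prediction", {
  m <- build_model(tiny_cfg(), seed = 4)
  x <- rand_fm(c(1, 3, 16, 16), seed = 5)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_identical(predict(m, x), predict(m2, x))
  expect_identical(m2$config$depth, m$config$depth)
  unlink(path)
})

test_that("the baseline variant shares the stage and channel skeleton", {
  mb <- build_model(variant_config("baseline", depth = 2, base_channels = 4),
                    seed = 1)
  mf <- build_model(variant_config("baseline+PCAM+PRDC", depth = 2,
                                   base_channels = 4), seed = 1)
  expect_identical(n_pcam_modules(mb), 0L)
  for (i in 1:2) {
    expect_identical(dim(mb$params$enc[[i]]$block$conv1$W),
                     dim(mf$params$enc[[i]]$block$conv1$W))
    expect_identical(dim(mb$params$dec[[i]]$block$conv1$W),
                     dim(mf$params$dec[[i]]$block$conv1$W))
  }
  expect_identical(dim(mb$params$head$W), dim(mf$params$head$W))
})
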