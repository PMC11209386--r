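test_that("patch grids cover every pixel with clamped final origins", {
  g <- make_patch_grid(576, 576, 128, 64)
  rows <- unique(g$origins[, "row"])
  expect_length(rows, 8)                       # 0,64,...,448
  expect_equal(max(rows), 448)                 # clamped to H - patch
  expect_identical(nrow(g$origins), 64L)
  expect_false(any(duplicated(g$origins)))
  # row-major ordering
  expect_true(all(diff(order(g$origins[, "row"], g$origins[, "col"])) == 1))
  # coverage count, built directly from the origins
  cover <- matrix(0, 576, 576)
  for (i in seq_len(nrow(g$origins)))
    cover[g$origins[i, 1] + 1:128, g$origins[i, 2] + 1:128] <-
      cover[g$origins[i, 1] + 1:128, g$origins[i, 2] + 1:128] + 1
  expect_true(all(cover >= 1))
  # stride = patch on a divisible image: exactly-once coverage
  g2 <- make_patch_grid(64, 64, 16, 16)
  cover <- matrix(0, 64, 64)
  for (i in seq_len(nrow(g2$origins)))
    cover[g2$origins[i, 1] + 1:16, g2$origins[i, 2] + 1:16] <-
      cover[g2$origins[i, 1] + 1:16, g2$origins[i, 2] + 1:16] + 1
  expect_true(all(cover == 1))
  expect_error(make_patch_grid(50, 50, 64, 32), "exceeds")
  expect_error(make_patch_grid(50, 50, 16, 20), "stride")
})

test_that("stitching the extracted patches reproduces the image and is linear", {
  set.seed(1)
  x <- matrix(runif(48 * 40), 48, 40)
  g <- make_patch_grid(48, 40, 16, 8)
  patches <- extract_patches(x, g)
  expect_equal(stitch_patches(patches, g), x, tolerance = 1e-12)
  scaled <- lapply(patches, function(p) 3 * p)
  expect_equal(stitch_patches(scaled, g), 3 * stitch_patches(patches, g),
               tolerance = 1e-12)
})

test_that("FoV estimation recovers a bright disk to high IoU", {
  H <- 584; W <- 565
  yy <- matrix(seq_len(H), H, W); xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  disk <- ((yy - H / 2)^2 + (xx - W / 2)^2 <= 200^2) * 1
  img <- array(0, c(H, W, 3))
  img[, , 1] <- disk * 0.8
  fov <- generate_fov_mask(img)
  inter <- sum(fov & disk); union <- sum(fov | disk)
  expect_gte(inter / union, 0.99)
  expect_warning(empty <- generate_fov_mask(array(0, c(20, 20, 3))), "dark")
  expect_true(all(empty == 0))
  expect_true(all(generate_fov_mask(img, threshold = 0) == 1))
})

test_that("resizing treats images and masks by their own rules", {
  s <- generate_phantom(phantom_params(), seed = 21)
  r <- resize_sample(s, c(576, 576))
  expect_identical(dim(r$image), c(576L, 576L, 3L))
  expect_identical(dim(r$vessel_mask), c(576L, 576L))
  expect_true(all(r$vessel_mask %in% c(0L, 1L)))
  same <- resize_sample(s, dim(s$vessel_mask))
  expect_equal(same$image, s$image, tolerance = 1e-6)
  # area is approximately preserved through an up/down round trip
  up <- resize_sample(s, c(128, 128))
  back <- resize_sample(up, c(64, 64))
  expect_lt(abs(sum(back$vessel_mask) - sum(s$vessel_mask)) /
              sum(s$vessel_mask), 0.05)
})

test_that("augmentation applies one shared transform and spares masks from photometry", {
  s <- generate_phantom(phantom_params(), seed = 22)
  cfg <- augmentation_config()
  set.seed(10); a1 <- augment_sample(s, cfg)
  set.seed(10); a2 <- augment_sample(s, cfg)
  expect_identical(a1$vessel_mask, a2$vessel_mask)
  expect_identical(a1$image, a2$image)
  # a quarter-turn permutes pixels, so vessel area is exact
  rot90 <- augmentation_config(rotation = c(90, 90), flip_h = 0, flip_v = 0,
                               shift = 0, zoom = c(1, 1))
  set.seed(11); r <- augment_sample(s, rot90)
  expect_identical(sum(r$vessel_mask), sum(s$vessel_mask))
  # photometric-only jitter leaves the masks bitwise alone
  photo <- augmentation_config(rotation = 0, flip_h = 0, flip_v = 0,
                               shift = 0, zoom = c(1, 1))
  set.seed(12); pj <- augment_sample(s, photo)
  expect_identical(pj$vessel_mask, s$vessel_mask)
  expect_identical(pj$fov_mask, s$fov_mask)
  expect_false(identical(pj$image, s$image))
  # vessels outside the FoV never increase under the shared transform
  outside_before <- sum(s$vessel_mask & !s$fov_mask)
  set.seed(13); g <- augment_sample(s, augmentation_config(brightness = 0,
                                                           contrast = 0,
                                                           saturation = 0))
  expect_lte(sum(g$vessel_mask & !g$fov_mask), outside_before)
})

test_that("fold schemes partition identifiers as documented", {
  ids <- sprintf("im%02d", 1:20)
  folds <- make_folds(ids, "stare")
  expect_length(folds, 10)
  all_test <- character(0)
  for (f in folds) {
    expect_length(f$train_ids, 18)
    expect_length(f$test_ids, 2)
    expect_length(intersect(f$train_ids, f$test_ids), 0)
    all_test <- c(all_test, f$test_ids)
  }
  expect_false(any(duplicated(all_test)))
  expect_setequal(all_test, ids)
  drive <- make_folds(sprintf("d%02d", 1:40), "drive")
  expect_length(drive, 1)
  expect_length(drive[[1]]$train_ids, 20)
  expect_length(drive[[1]]$test_ids, 20)
  kf <- make_folds(sprintf("x%02d", 1:17), list(type = "kfold", k = 5,
                                                test_size = 4), seed = 3)
  expect_setequal(unlist(lapply(kf, `[[`, "test_ids")), sprintf("x%02d", 1:17))
  expect_false(any(duplicated(unlist(lapply(kf, `[[`, "test_ids")))))
  expect_error(make_folds(sprintf("x%02d", 1:17),
                          list(type = "kfold", k = 2, test_size = 4)),
               "cannot cover")
  expect_error(make_folds(ids, list(type = "fixed", train_ids = ids[1:10],
                                    test_ids = ids[10:20])), "overlap")
})

test_that("the generic loader round-trips a phantom dataset", {
  root <- file.path(tempdir(), "phantomset")
  unlink(root, recursive = TRUE)
  written <- generate_dataset(6, phantom_params(), seed = 50, dir = root)
  loaded <- load_dataset(root, "generic")
  expect_length(loaded, 6)
  for (i in seq_along(loaded)) {
    s <- loaded[[i]]
    expect_s3_class(s, "fundus_sample")
    expect_true(all(s$vessel_mask %in% c(0L, 1L)))
    expect_identical(dim(s$image)[1:2], dim(s$vessel_mask))
    expect_identical(dim(s$fov_mask), dim(s$vessel_mask))
    orig <- written[[which(sapply(written, `[[`, "id") == s$id)]]
    expect_identical(s$vessel_mask, orig$vessel_mask)
    expect_identical(s$fov_mask, orig$fov_mask)
  }
  unlink(root, recursive = TRUE)
})

test_that("degenerate dataset directories fail loudly", {
  empty <- file.path(tempdir(), "emptyset")
  dir.create(file.path(empty, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(empty, "masks"), showWarnings = FALSE)
  expect_error(load_dataset(empty, "generic"), "no samples")
  expect_error(load_dataset(file.path(tempdir(), "nowhere-at-all"), "generic"),
               "does not exist")
  # GIF inputs are rejected with conversion advice
  s <- generate_phantom(phantom_params(), seed = 60)
  write_image_png(s$image, file.path(empty, "images", "a.png"))
  file.create(file.path(empty, "masks", "a.gif"))
  expect_error(load_dataset(empty, "generic"), "GIF")
  unlink(empty, recursive = TRUE)
})

test_that("the drive layout assigns roles from its subtrees", {
  root <- file.path(tempdir(), "driveset")
  unlink(root, recursive = TRUE)
  for (sub in c("training", "test")) {
    for (d in c("images", "1st_manual", "mask"))
      dir.create(file.path(root, sub, d), recursive = TRUE,
                 showWarnings = FALSE)
  }
  ph <- generate_dataset(3, phantom_params(), seed = 70)
  put <- function(s, sub) {
    write_image_png(s$image, file.path(root, sub, "images",
                                       paste0(s$id, ".png")))
    write_mask_png(s$vessel_mask, file.path(root, sub, "1st_manual",
                                            paste0(s$id, ".png")))
    write_mask_png(s$fov_mask, file.path(root, sub, "mask",
                                         paste0(s$id, ".png")))
  }
  put(ph[[1]], "training"); put(ph[[2]], "training"); put(ph[[3]], "test")
  loaded <- load_dataset(root, "drive")
  roles <- sapply(loaded, `[[`, "role")
  expect_identical(sum(roles == "train"), 2L)
  expect_identical(sum(roles == "test"), 1L)
  unlink(root, recursive = TRUE)
})
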