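#' Construct a fundus sample
#'
#' A sample bundles an RGB image with its binary vessel ground truth and a
#' field-of-view (FoV) mask sharing the same geometry. Images are `H x W x 3`
#' arrays in `[0, 1]` (row = image row); masks are `H x W` 0/1 matrices.
#' Vessel annotations are not required to lie inside the FoV; evaluation
#' intersects with the FoV mask.
#'
#' @param image `H x W x 3` numeric array in `[0, 1]`.
#' @param vessel_mask,fov_mask `H x W` binary matrices.
#' @param id identifier string.
#' @param role optional `"train"`/`"test"` tag from the dataset layout.
#' @return object of class `fundus_sample`.
#' @export
fundus_sample <- function(image, vessel_mask, fov_mask, id, role = NA_character_) {
  d <- dim(image)
  if (length(d) != 3L || d[3L] != 3L)
    stop(sprintf("sample '%s': image must be H x W x 3", id))
  if (!identical(d[1:2], dim(vessel_mask)) || !identical(d[1:2], dim(fov_mask)))
    stop(sprintf("sample '%s': image and masks have mismatched geometry", id))
  structure(list(image = image,
                 vessel_mask = binarize_mask(vessel_mask),
                 fov_mask = binarize_mask(fov_mask),
                 id = id, role = role),
            class = "fundus_sample")
}

binarize_mask <- function(m) {
  out <- matrix(as.integer(m > 0.5), nrow(m), ncol(m))
  out
}

# --- image I/O (EBImage) -----------------------------------------------------

SUPPORTED_EXT <- c("png", "tif", "tiff", "jpg", "jpeg")

read_image_rgb <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "gif")
    stop(sprintf("'%s': GIF is not readable here; convert to PNG/TIFF first",
                 basename(path)))
  if (!ext %in% SUPPORTED_EXT)
    stop(sprintf("'%s': unsupported image format '%s'", basename(path), ext))
  dat <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(dat)) == 2L) {
    img <- t(dat)
    img <- array(rep(img, 3L), c(dim(img), 3L))
  } else {
    img <- aperm(dat[, , 1:3, drop = FALSE], c(2L, 1L, 3L))
  }
  pmin(pmax(img, 0), 1)
}

read_mask <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "gif")
    stop(sprintf("'%s': GIF is not readable here; convert to PNG/TIFF first",
                 basename(path)))
  dat <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(dat)) > 2L) dat <- dat[, , 1L]
  binarize_mask(t(dat))
}

#' Write a binary mask as 8-bit PNG (0/255)
#' @param mask `H x W` binary matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  EBImage::writeImage(EBImage::Image(t(mask * 1)), path, type = "png")
  invisible(path)
}

#' Write an RGB image as 8-bit PNG
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  img <- EBImage::Image(aperm(image, c(2L, 1L, 3L)), colormode = "Color")
  EBImage::writeImage(img, path, type = "png")
  invisible(path)
}

#' Write a probability map
#'
#' Writes `.png` at 8 bits (the deepest the available PNG writer supports)
#' or `.tif`/`.tiff` at 16 bits for full-precision export.
#'
#' @param p `H x W` matrix in `[0, 1]`.
#' @param path output path; the extension selects the format.
#' @return `path`, invisibly.
#' @export
write_probability_png <- function(p, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    EBImage::writeImage(EBImage::Image(t(p)), path, type = "tiff",
                        bits.per.sample = 16L)
  } else {
    EBImage::writeImage(EBImage::Image(t(p)), path, type = "png")
  }
  invisible(path)
}

# --- dataset loading ---------------------------------------------------------

list_images <- function(dir) {
  if (!dir.exists(dir)) return(character(0))
  fs <- list.files(dir, full.names = TRUE)
  fs[tolower(tools::file_ext(fs)) %in% c(SUPPORTED_EXT, "gif")]
}

stem <- function(path) tools::file_path_sans_ext(basename(path))

find_match <- function(id, files) {
  hits <- files[vapply(files, function(f) startsWith(stem(f), id) ||
                         startsWith(id, stem(f)) || grepl(id, stem(f), fixed = TRUE),
                       logical(1))]
  if (length(hits) == 0L) return(NA_character_)
  hits[[1L]]
}

load_pairs <- function(img_files, mask_files, fov_files, role) {
  samples <- list()
  for (f in img_files) {
    id <- stem(f)
    mf <- find_match(id, mask_files)
    if (is.na(mf))
      stop(sprintf("sample '%s': no vessel mask found", id))
    image <- read_image_rgb(f)
    vm <- read_mask(mf)
    if (!identical(dim(vm), dim(image)[1:2]))
      stop(sprintf("sample '%s': mask size %dx%d mismatches image %dx%d",
                   id, nrow(vm), ncol(vm), dim(image)[1L], dim(image)[2L]))
    ff <- find_match(id, fov_files)
    fov <- if (is.na(ff)) generate_fov_mask(image) else read_mask(ff)
    if (!identical(dim(fov), dim(image)[1:2]))
      stop(sprintf("sample '%s': FoV mask geometry mismatch", id))
    samples[[length(samples) + 1L]] <-
      fundus_sample(image, vm, fov, id, role = role)
  }
  samples
}

#' Load a fundus dataset
#'
#' Reads images, vessel masks and (when present) FoV masks from one of the
#' supported directory layouts; missing FoV masks are estimated with
#' [generate_fov_mask()]. Images are normalised to `[0, 1]` and masks
#' binarised at mid-intensity.
#'
#' Layouts:
#' * `generic`: `images/`, `masks/`, optional `fov/`, files paired by stem.
#' * `drive`: `training/` and `test/` subtrees, each with `images/`,
#'   `1st_manual/`, `mask/`; the subtree sets the sample role.
#' * `chase_db1`: flat directory, masks named `<id>_1stHO.*`; the first 20
#'   ids (sorted) are tagged train, the rest test.
#' * `stare`: `images/` plus one of `labels-ah/`, `labels/`, `masks/`;
#'   no fixed split (use [make_folds()] with the `"stare"` scheme).
#'
#' @param root dataset root directory.
#' @param layout one of `"generic"`, `"drive"`, `"chase_db1"`, `"stare"`.
#' @return list of `fundus_sample` objects.
#' @export
load_dataset <- function(root, layout = c("generic", "drive", "chase_db1",
                                          "stare")) {
  layout <- match.arg(layout)
  if (!dir.exists(root)) stop(sprintf("dataset root '%s' does not exist", root))
  samples <- switch(layout,
    generic = load_pairs(list_images(file.path(root, "images")),
                         list_images(file.path(root, "masks")),
                         list_images(file.path(root, "fov")),
                         role = NA_character_),
    drive = c(load_pairs(list_images(file.path(root, "training", "images")),
                         list_images(file.path(root, "training", "1st_manual")),
                         list_images(file.path(root, "training", "mask")),
                         role = "train"),
              load_pairs(list_images(file.path(root, "test", "images")),
                         list_images(file.path(root, "test", "1st_manual")),
                         list_images(file.path(root, "test", "mask")),
                         role = "test")),
    chase_db1 = {
      fs <- list_images(root)
      masks <- fs[grepl("_(1st|2nd)HO", basename(fs))]
      imgs <- sort(setdiff(fs, masks))
      s <- load_pairs(imgs, fs[grepl("_1stHO", basename(fs))],
                      character(0), role = NA_character_)
      for (i in seq_along(s)) s[[i]]$role <- if (i <= 20L) "train" else "test"
      s
    },
    stare = {
      lab_dir <- Filter(dir.exists,
                        file.path(root, c("labels-ah", "labels", "masks")))
      if (length(lab_dir) == 0L)
        stop("stare layout: no label directory (labels-ah/, labels/ or masks/)")
      load_pairs(list_images(file.path(root, "images")),
                 list_images(lab_dir[[1L]]), character(0),
                 role = NA_character_)
    })
  if (length(samples) == 0L)
    stop(sprintf("no samples found under '%s' for layout '%s'", root, layout))
  samples
}

#' Estimate a field-of-view mask by colour thresholding
#'
#' Thresholds the red channel (the channel with the strongest
#' fundus/background contrast) at a fraction of its maximum, applies
#' morphological closing and hole filling, and keeps the largest connected
#' component.
#'
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param threshold fraction of the red-channel maximum (default 0.1); 0
#'   yields a full-frame mask.
#' @param brush_size odd diameter of the closing brush (default 5).
#' @return `H x W` 0/1 matrix.
#' @export
generate_fov_mask <- function(image, threshold = 0.1, brush_size = 5L) {
  red <- image[, , 1L]
  if (threshold <= 0) return(matrix(1L, nrow(red), ncol(red)))
  mx <- max(red)
  if (mx == 0) {
    warning("image is entirely dark; returning an empty FoV mask")
    return(matrix(0L, nrow(red), ncol(red)))
  }
  m <- EBImage::Image(t(red >= threshold * mx) * 1)
  m <- EBImage::closing(m, EBImage::makeBrush(brush_size, shape = "disc"))
  m <- EBImage::fillHull(m)
  lab <- EBImage::imageData(EBImage::bwlabel(m))
  if (max(lab) == 0) {
    warning("no foreground after thresholding; returning an empty FoV mask")
    return(matrix(0L, nrow(red), ncol(red)))
  }
  counts <- tabulate(lab[lab > 0])
  binarize_mask(t(lab == which.max(counts)))
}

#' Resize a sample
#'
#' The image is resized bilinearly; masks use nearest-neighbour resampling
#' and are re-binarised so labels stay crisp.
#'
#' @param sample a `fundus_sample`.
#' @param target `(H, W)` integer vector.
#' @return a resized `fundus_sample`.
#' @export
resize_sample <- function(sample, target) {
  H <- as.integer(target[1L]); W <- as.integer(target[2L])
  if (H < 1L || W < 1L) stop("target size must be positive")
  eb <- EBImage::Image(aperm(sample$image, c(2L, 1L, 3L)), colormode = "Color")
  img <- aperm(EBImage::imageData(EBImage::resize(eb, w = W, h = H)),
               c(2L, 1L, 3L))
  rs_mask <- function(m) {
    r <- EBImage::resize(EBImage::Image(t(m * 1)), w = W, h = H,
                         filter = "none")
    binarize_mask(t(EBImage::imageData(r)))
  }
  fundus_sample(pmin(pmax(img, 0), 1), rs_mask(sample$vessel_mask),
                rs_mask(sample$fov_mask), sample$id, sample$role)
}

# --- augmentation ------------------------------------------------------------

#' Augmentation configuration
#'
#' Ranges for the photometric jitter (brightness/contrast/saturation) and
#' the shared geometric transform (rotation, flips, shift, zoom). Set a
#' range to 0 (or a flip probability to 0) to disable that component.
#'
#' @param brightness,contrast,saturation symmetric jitter half-ranges
#'   (default 0.2 each).
#' @param rotation rotation range in degrees: a scalar `r` for the
#'   symmetric range `(-r, r)` (default 15), or a `(lo, hi)` pair — a
#'   degenerate pair such as `c(90, 90)` forces a fixed angle.
#' @param flip_h,flip_v flip probabilities (default 0.5 horizontal, 0
#'   vertical).
#' @param shift max absolute shift as a fraction of the image size
#'   (default 0.1).
#' @param zoom `(lo, hi)` scale range (default `c(0.9, 1.1)`).
#' @return object of class `augmentation_config`.
#' @export
augmentation_config <- function(brightness = 0.2, contrast = 0.2,
                                saturation = 0.2, rotation = 15,
                                flip_h = 0.5, flip_v = 0, shift = 0.1,
                                zoom = c(0.9, 1.1)) {
  if (zoom[1L] > zoom[2L]) stop("zoom range must be (lo, hi) with lo <= hi")
  if (length(rotation) == 1L) rotation <- c(-rotation, rotation)
  if (rotation[1L] > rotation[2L]) stop("rotation range must be (lo, hi)")
  structure(list(brightness = brightness, contrast = contrast,
                 saturation = saturation, rotation = rotation,
                 flip_h = flip_h, flip_v = flip_v, shift = shift,
                 zoom = zoom),
            class = "augmentation_config")
}

# Inverse-mapped resampling at source coordinates (sy, sx); out-of-range
# pixels become 0. method "bilinear" or "nearest".
resample_at <- function(arr, sy, sx, method) {
  H <- nrow(arr); W <- ncol(arr)
  inside <- sy >= 1 & sy <= H & sx >= 1 & sx <= W
  if (method == "nearest") {
    iy <- pmin(pmax(round(sy), 1), H)
    ix <- pmin(pmax(round(sx), 1), W)
    out <- matrix(arr[cbind(as.vector(iy), as.vector(ix))], H, W)
  } else {
    y0 <- pmin(pmax(floor(sy), 1), H); y1 <- pmin(y0 + 1, H)
    x0 <- pmin(pmax(floor(sx), 1), W); x1 <- pmin(x0 + 1, W)
    ty <- pmin(pmax(sy - y0, 0), 1); tx <- pmin(pmax(sx - x0, 0), 1)
    g <- function(iy, ix) matrix(arr[cbind(as.vector(iy), as.vector(ix))], H, W)
    out <- (1 - ty) * ((1 - tx) * g(y0, x0) + tx * g(y0, x1)) +
      ty * ((1 - tx) * g(y1, x0) + tx * g(y1, x1))
  }
  out * inside
}

#' Augment a sample
#'
#' Applies one shared geometric transform (rotation about the centre, zoom,
#' shift, flips) to the image and both masks — bilinear resampling for the
#' image, nearest-neighbour for the masks — followed by photometric jitter
#' on the image only. Draws from the R session RNG; seed for reproducibility.
#'
#' @param sample a `fundus_sample`.
#' @param config an [augmentation_config()].
#' @return an augmented `fundus_sample`.
#' @export
augment_sample <- function(sample, config = augmentation_config()) {
  H <- nrow(sample$vessel_mask); W <- ncol(sample$vessel_mask)
  angle <- runif(1, config$rotation[1L], config$rotation[2L]) * pi / 180
  zoom <- runif(1, config$zoom[1L], config$zoom[2L])
  dy <- runif(1, -config$shift, config$shift) * H
  dx <- runif(1, -config$shift, config$shift) * W
  fh <- runif(1) < config$flip_h
  fv <- runif(1) < config$flip_v
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  oy <- matrix(seq_len(H), H, W) - cy
  ox <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  # inverse map: undo shift, then rotation/zoom about the centre
  uy <- oy - dy; ux <- ox - dx
  sy <- cy + (cos(-angle) * uy - sin(-angle) * ux) / zoom
  sx <- cx + (sin(-angle) * uy + cos(-angle) * ux) / zoom
  warp <- function(m, method) {
    out <- resample_at(m, sy, sx, method)
    if (fh) out <- out[, W:1, drop = FALSE]
    if (fv) out <- out[H:1, , drop = FALSE]
    out
  }
  img <- array(0, dim(sample$image))
  for (c in 1:3) img[, , c] <- warp(sample$image[, , c], "bilinear")
  vm <- binarize_mask(warp(sample$vessel_mask, "nearest"))
  fm <- binarize_mask(warp(sample$fov_mask, "nearest"))
  # photometric jitter, image only
  br <- runif(1, -config$brightness, config$brightness)
  ct <- 1 + runif(1, -config$contrast, config$contrast)
  st <- 1 + runif(1, -config$saturation, config$saturation)
  mu <- mean(img)
  img <- (img - mu) * ct + mu + br
  gray <- (img[, , 1L] + img[, , 2L] + img[, , 3L]) / 3
  for (c in 1:3) img[, , c] <- gray + (img[, , c] - gray) * st
  fundus_sample(pmin(pmax(img, 0), 1), vm, fm, sample$id, sample$role)
}

# --- patch grids -------------------------------------------------------------

#' Build a patch grid
#'
#' Origins are 0-based top-left corners on a regular stride, row-major, with
#' the final origin on each axis clamped to `size - patch_size` so every
#' pixel is covered.
#'
#' @param H,W image size.
#' @param patch_size square patch side; must not exceed `min(H, W)`.
#' @param stride step between origins, `1 <= stride <= patch_size`.
#' @return object of class `patch_grid` with `origins` (n x 2 matrix of
#'   `(row, col)`), `patch_size`, `stride`.
#' @export
make_patch_grid <- function(H, W, patch_size = 128L, stride = 64L) {
  patch_size <- as.integer(patch_size); stride <- as.integer(stride)
  if (patch_size > H || patch_size > W)
    stop(sprintf("patch_size %d exceeds image size %dx%d", patch_size, H, W))
  if (stride < 1L || stride > patch_size)
    stop("stride must satisfy 1 <= stride <= patch_size")
  axis_origins <- function(n) {
    o <- seq(0L, n - patch_size, by = stride)
    if (o[length(o)] != n - patch_size) o <- c(o, n - patch_size)
    o
  }
  rows <- axis_origins(H); cols <- axis_origins(W)
  origins <- cbind(row = rep(rows, each = length(cols)),
                   col = rep(cols, times = length(rows)))
  structure(list(origins = origins, patch_size = patch_size, stride = stride,
                 H = H, W = W),
            class = "patch_grid")
}

#' Extract patches
#' @param x `H x W` matrix or `H x W x C` array.
#' @param grid a [make_patch_grid()] object.
#' @return list of patches in grid order.
#' @export
extract_patches <- function(x, grid) {
  ps <- grid$patch_size
  lapply(seq_len(nrow(grid$origins)), function(i) {
    r <- grid$origins[i, 1L]; c <- grid$origins[i, 2L]
    if (length(dim(x)) == 3L) x[r + 1:ps, c + 1:ps, , drop = FALSE]
    else x[r + 1:ps, c + 1:ps, drop = FALSE]
  })
}

#' Stitch patch predictions
#'
#' Sums patch maps at their origins and divides by the per-pixel coverage
#' count, so overlapping predictions are averaged. Linear in the patch
#' values.
#'
#' @param maps list of `patch_size x patch_size` matrices in grid order.
#' @param grid the [make_patch_grid()] used for extraction.
#' @param H,W output size.
#' @return `H x W` matrix.
#' @export
stitch_patches <- function(maps, grid, H = grid$H, W = grid$W) {
  ps <- grid$patch_size
  acc <- matrix(0, H, W)
  cnt <- matrix(0, H, W)
  for (i in seq_len(nrow(grid$origins))) {
    r <- grid$origins[i, 1L]; c <- grid$origins[i, 2L]
    acc[r + 1:ps, c + 1:ps] <- acc[r + 1:ps, c + 1:ps] + maps[[i]]
    cnt[r + 1:ps, c + 1:ps] <- cnt[r + 1:ps, c + 1:ps] + 1
  }
  acc / cnt
}

# --- evaluation splits -------------------------------------------------------

#' Build train/test folds
#'
#' Schemes:
#' * `list(type = "fixed", train_ids =, test_ids =)` — one fold as given.
#' * `list(type = "kfold", k =, test_size =)` — ids are shuffled by `seed`
#'   and partitioned into `k` disjoint test sets of `test_size` (the last
#'   possibly smaller); requires `k * test_size >= length(ids)` so the test
#'   sets cover the dataset.
#' * `"stare"` — preset: 10 folds of 18 train / 2 test over 20 ids
#'   (deterministic consecutive pairs on the sorted ids).
#' * `"drive"`, `"chase_db1"` — preset fixed splits on the sorted ids
#'   (20/20 and 20/8 respectively).
#'
#' @param ids character vector of sample identifiers.
#' @param scheme scheme list or preset name.
#' @param seed shuffle seed for `kfold`.
#' @return list of `fold_split` objects (`train_ids`, `test_ids`,
#'   `fold_index`).
#' @export
make_folds <- function(ids, scheme = "stare", seed = 1L) {
  fold <- function(tr, te, i) structure(list(train_ids = tr, test_ids = te,
                                             fold_index = i),
                                        class = "fold_split")
  if (is.character(scheme) && length(scheme) == 1L) {
    scheme <- switch(scheme,
      stare = {
        if (length(ids) != 20L)
          stop("the stare scheme needs exactly 20 ids")
        list(type = "kfold", k = 10L, test_size = 2L, shuffle = FALSE)
      },
      drive = {
        if (length(ids) != 40L) stop("the drive scheme needs exactly 40 ids")
        s <- sort(ids)
        list(type = "fixed", train_ids = s[1:20], test_ids = s[21:40])
      },
      chase_db1 = {
        if (length(ids) != 28L)
          stop("the chase_db1 scheme needs exactly 28 ids")
        s <- sort(ids)
        list(type = "fixed", train_ids = s[1:20], test_ids = s[21:28])
      },
      stop(sprintf("unknown scheme preset '%s'", scheme)))
  }
  if (scheme$type == "fixed") {
    if (length(intersect(scheme$train_ids, scheme$test_ids)) > 0L)
      stop("train and test ids overlap")
    return(list(fold(scheme$train_ids, scheme$test_ids, 1L)))
  }
  if (scheme$type == "kfold") {
    k <- scheme$k; ts <- scheme$test_size
    if (k * ts < length(ids))
      stop(sprintf("k * test_size = %d cannot cover %d ids", k * ts,
                   length(ids)))
    pool <- sort(ids)
    if (!isFALSE(scheme$shuffle)) {
      set.seed(seed)
      pool <- sample(pool)
    }
    folds <- list()
    at <- 0L
    i <- 0L
    while (at < length(pool) && i < k) {
      i <- i + 1L
      te <- pool[(at + 1L):min(at + ts, length(pool))]
      at <- at + length(te)
      folds[[i]] <- fold(setdiff(pool, te), te, i)
    }
    return(folds)
  }
  stop("unknown scheme type")
}
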