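#' Phantom generator parameters
#'
#' Controls the synthetic fundus phantoms: a bright circular field of view
#' on a dark background, branching curvilinear dark "vessels" whose stroke
#' width tapers towards the tips, a smooth background intensity gradient,
#' and additive Gaussian noise — with pixel-exact paired vessel and FoV
#' masks. Class imbalance mirrors real fundus images: the vessel fraction
#' (relative to the FoV area) is constrained to `fraction_range`, well below
#' the background share.
#'
#' @param size `(H, W)` image size (default `c(64, 64)`, desk-scale).
#' @param n_trees number of vessel trees seeded on the FoV boundary.
#' @param branch_prob per-step probability of spawning a side branch.
#' @param width_range `(min, max)` stroke widths in pixels; branches taper.
#' @param fraction_range `(lo, hi)` admissible vessel-pixel fraction of the
#'   FoV (default `c(0.05, 0.15)`).
#' @param gradient_amplitude amplitude of the linear background shading.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param fov_radius_fraction FoV disk radius as a fraction of
#'   `min(H, W) / 2`.
#' @param vessel_contrast how much darker vessels are than the background.
#' @param background_level mean background intensity inside the FoV.
#' @return object of class `phantom_params`.
#' @export
phantom_params <- function(size = c(64L, 64L), n_trees = 2L,
                           branch_prob = 0.04, width_range = c(1.6, 3.2),
                           fraction_range = c(0.05, 0.15),
                           gradient_amplitude = 0.12, noise_sd = 0.05,
                           fov_radius_fraction = 0.92,
                           vessel_contrast = 0.35, background_level = 0.75) {
  if (fraction_range[1L] >= fraction_range[2L])
    stop("fraction_range must satisfy lo < hi")
  if (width_range[1L] < 1) stop("minimum stroke width must be >= 1 pixel")
  structure(list(size = as.integer(size), n_trees = as.integer(n_trees),
                 branch_prob = branch_prob, width_range = width_range,
                 fraction_range = fraction_range,
                 gradient_amplitude = gradient_amplitude,
                 noise_sd = noise_sd,
                 fov_radius_fraction = fov_radius_fraction,
                 vessel_contrast = vessel_contrast,
                 background_level = background_level),
            class = "phantom_params")
}

# Grow one vessel tree as a random walk from an FoV boundary entry point.
# Returns a data.frame of stamped points (y, x, width, depth).
grow_tree <- function(H, W, cy, cx, radius, params) {
  theta0 <- runif(1, 0, 2 * pi)
  start <- c(cy + 0.95 * radius * sin(theta0), cx + 0.95 * radius * cos(theta0))
  dir0 <- atan2(cy - start[1L], cx - start[2L]) + runif(1, -0.4, 0.4)
  w0 <- runif(1, 0.7, 1) * params$width_range[2L]
  queue <- list(list(pos = start, dir = dir0, width = w0, depth = 0L))
  pts <- NULL
  max_steps <- round(2.2 * radius)
  while (length(queue) > 0L) {
    br <- queue[[1L]]
    queue <- queue[-1L]
    pos <- br$pos; dir <- br$dir; w <- br$width
    for (s in seq_len(max_steps)) {
      if (sqrt((pos[1L] - cy)^2 + (pos[2L] - cx)^2) > radius) break
      w_here <- max(w * (1 - 0.5 * s / max_steps), params$width_range[1L])
      pts <- rbind(pts, c(pos[1L], pos[2L], w_here, br$depth))
      dir <- dir + rnorm(1, sd = 0.15)
      pos <- pos + 0.75 * c(sin(dir), cos(dir))
      if (br$depth < 4L && w_here > 1.2 * params$width_range[1L] &&
          runif(1) < params$branch_prob) {
        queue[[length(queue) + 1L]] <-
          list(pos = pos, dir = dir + sample(c(-1, 1), 1L) * runif(1, 0.4, 0.9),
               width = 0.7 * w_here, depth = br$depth + 1L)
      }
      if (w_here <= params$width_range[1L] && s > max_steps / 2) break
    }
  }
  if (is.null(pts)) return(NULL)
  colnames(pts) <- c("y", "x", "width", "depth")
  as.data.frame(pts)
}

# Render stamped points: returns the binary mask and a soft (anti-aliased)
# coverage map used for the image.
render_strokes <- function(pts, H, W, fov) {
  soft <- matrix(0, H, W)
  hard <- matrix(0L, H, W)
  if (is.null(pts) || nrow(pts) == 0L) return(list(mask = hard, soft = soft))
  for (i in seq_len(nrow(pts))) {
    r <- pts$width[i] / 2
    y <- pts$y[i]; x <- pts$x[i]
    y0 <- max(1L, floor(y - r - 1)); y1 <- min(H, ceiling(y + r + 1))
    x0 <- max(1L, floor(x - r - 1)); x1 <- min(W, ceiling(x + r + 1))
    if (y0 > y1 || x0 > x1) next
    yy <- y0:y1; xx <- x0:x1
    d <- sqrt(outer((yy - y)^2, (xx - x)^2, `+`))
    soft[yy, xx] <- pmax(soft[yy, xx], pmin(pmax(r + 0.5 - d, 0), 1))
    hard[yy, xx] <- pmax(hard[yy, xx], (d <= r) * 1L)
  }
  list(mask = hard * fov, soft = soft * fov)
}

#' Generate one synthetic fundus phantom
#'
#' Grows `n_trees` branching random-walk vessel trees from the FoV boundary,
#' renders them (anti-aliased for the image, hard-thresholded for the
#' mask, both clipped to the FoV), and composes the image as background
#' gradient minus vessel contrast plus Gaussian noise, clipped to `[0, 1]`.
#' Resamples (with more trees when under, fewer steps via new draws when
#' over) until the vessel fraction of the FoV lands in `fraction_range`;
#' fails explicitly after 25 attempts. Deterministic in `seed`.
#'
#' @param params a [phantom_params()].
#' @param seed integer seed.
#' @return a `fundus_sample`; attribute `stroke_records` holds the internal
#'   per-point `(width, depth)` records used by the tapering checks.
#' @export
generate_phantom <- function(params = phantom_params(), seed = 1L) {
  set.seed(seed)
  H <- params$size[1L]; W <- params$size[2L]
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  radius <- params$fov_radius_fraction * min(H, W) / 2
  yy <- matrix(seq_len(H), H, W); xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  fov <- ((yy - cy)^2 + (xx - cx)^2 <= radius^2) * 1L
  fov_area <- sum(fov)
  lo <- params$fraction_range[1L]; hi <- params$fraction_range[2L]
  n_trees <- params$n_trees
  for (attempt in seq_len(25L)) {
    pts <- NULL
    for (t in seq_len(n_trees)) pts <- rbind(pts, grow_tree(H, W, cy, cx,
                                                            radius, params))
    rs <- render_strokes(pts, H, W, fov)
    frac <- sum(rs$mask) / fov_area
    if (frac >= lo && frac <= hi) {
      theta <- runif(1, 0, 2 * pi)
      grad <- params$gradient_amplitude *
        ((yy / H - 0.5) * sin(theta) + (xx / W - 0.5) * cos(theta))
      base <- params$background_level + grad -
        params$vessel_contrast * rs$soft +
        matrix(rnorm(H * W, sd = params$noise_sd), H, W)
      gray <- pmin(pmax(base, 0), 1) * fov + 0.02 * (1 - fov)
      img <- array(0, c(H, W, 3L))
      img[, , 1L] <- gray
      img[, , 2L] <- pmin(pmax(gray * 0.85, 0), 1)
      img[, , 3L] <- pmin(pmax(gray * 0.6, 0), 1)
      s <- fundus_sample(img, rs$mask, fov, sprintf("phantom_%06d", seed))
      attr(s, "stroke_records") <- pts[, c("width", "depth")]
      attr(s, "n_trees") <- n_trees
      return(s)
    }
    # adapt the tree count toward the admissible range and redraw
    if (frac < lo) n_trees <- n_trees + 1L
    if (frac > hi) n_trees <- max(1L, n_trees - 1L)
  }
  stop(sprintf(paste0("could not reach a vessel fraction in [%.2f, %.2f] ",
                      "after 25 attempts (last: %.3f); adjust phantom_params"),
               lo, hi, frac))
}

#' Generate a phantom dataset
#'
#' Draws `n` phantoms with per-sample seeds `seed + index` and, when `dir`
#' is given, writes them in the `generic` dataset layout (`images/`,
#' `masks/`, `fov/` as PNG) plus a JSON manifest recording the parameters
#' and seeds.
#'
#' @param n number of samples.
#' @param params a [phantom_params()].
#' @param seed master seed; sample `i` uses `seed + i`.
#' @param dir optional output directory.
#' @return list of `fundus_sample` objects (invisibly when writing).
#' @export
generate_dataset <- function(n, params = phantom_params(), seed = 1L,
                             dir = NULL) {
  if (n < 1L) stop("n must be >= 1")
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    s <- generate_phantom(params, seed = seed + i)
    s$id <- sprintf("phantom_%03d", i)
    samples[[i]] <- s
  }
  if (!is.null(dir)) {
    for (sub in c("images", "masks", "fov"))
      dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
    for (s in samples) {
      write_image_png(s$image, file.path(dir, "images", paste0(s$id, ".png")))
      write_mask_png(s$vessel_mask, file.path(dir, "masks",
                                              paste0(s$id, ".png")))
      write_mask_png(s$fov_mask, file.path(dir, "fov", paste0(s$id, ".png")))
    }
    manifest <- list(n = n, seed = seed,
                     per_sample_seeds = seed + seq_len(n),
                     params = unclass(params))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(samples))
  }
  samples
}
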