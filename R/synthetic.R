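# Procedural fundus-like data.
#
# Emulates the structure of the public vessel datasets: a circular
# field of view on a dark background, a branching vascular tree whose
# strokes taper from ~4-5 px main vessels down to 1 px microvessels, vessels
# darker than the background disc by a controllable contrast, and additive
# Gaussian noise. Each sample is an image / vessel-mask / FOV-mask triple,
# fully deterministic in the configuration seed, so the loader, network,
# training loop and metrics are all testable without downloads.

#' Configuration of the synthetic fundus generator
#'
#' @param size `c(H, W)` in pixels, both >= 32.
#' @param n_trees Number of vascular trees seeded on the FOV boundary.
#' @param branch_prob Probability per step of spawning a child branch.
#' @param width_root Stroke width (px) at the tree root, tapering towards
#'   `width_min` at branch events (defaults emulate main vessels ~4-5 px).
#' @param width_min Minimum stroke width (px, microvessels).
#' @param contrast Vessel darkening factor in (0, 1]: vessel intensity is
#'   `background * (1 - contrast)`.
#' @param noise_sd Standard deviation of additive Gaussian noise
#'   (unit-scaled intensities).
#' @param fov_radius_frac FOV disc radius as a fraction of `min(H, W) / 2`.
#' @param seed Integer RNG seed; all outputs are bit-reproducible in it.
#' @return A `synthetic_config` object.
#' @export
synthetic_config <- function(size = c(256L, 256L), n_trees = 4L,
                             branch_prob = 0.03, width_root = 4,
                             width_min = 1, contrast = 0.5, noise_sd = 0.05,
                             fov_radius_frac = 0.95, seed = 42L) {
  stopifnot(length(size) == 2L, all(size >= 32L), width_min <= width_root,
            branch_prob >= 0, branch_prob <= 1, contrast > 0, contrast <= 1,
            noise_sd >= 0, fov_radius_frac > 0, fov_radius_frac <= 1)
  structure(list(size = as.integer(size), n_trees = as.integer(n_trees),
                 branch_prob = branch_prob, width_root = width_root,
                 width_min = width_min, contrast = contrast,
                 noise_sd = noise_sd, fov_radius_frac = fov_radius_frac,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

fov_disc <- function(cfg) {
  H <- cfg$size[1]; W <- cfg$size[2]
  r <- cfg$fov_radius_frac * min(H, W) / 2
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  ((yy - cy)^2 + (xx - cx)^2 <= r^2) * 1L
}

stamp_disc <- function(mask, y, x, radius) {
  H <- nrow(mask); W <- ncol(mask)
  r <- max(0L, as.integer(ceiling(radius - 0.5)))
  y0 <- max(1L, floor(y - r)); y1 <- min(H, ceiling(y + r))
  x0 <- max(1L, floor(x - r)); x1 <- min(W, ceiling(x + r))
  for (xi in x0:x1) {
    dy2 <- radius^2 - (xi - x)^2
    if (dy2 < 0) next
    dy <- sqrt(dy2)
    ya <- max(y0, ceiling(y - dy)); yb <- min(y1, floor(y + dy))
    if (ya <= yb) mask[ya:yb, xi] <- 1L
  }
  mask
}

#' Generate a binary vessel-tree mask
#'
#' Random branching walks are seeded on the FOV boundary heading inward and
#' advance with smooth random turning; the stroke width tapers from
#' `width_root` towards `width_min` at branch events, and strokes are
#' rasterized as discs along the path. The result is clipped to the FOV.
#'
#' @param cfg A [synthetic_config()]; `cfg$seed` makes the mask
#'   bit-reproducible (pass `seed = NULL` to use the current RNG state).
#' @return Integer 0/1 matrix `H x W`.
#' @export
generate_vessel_tree <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  H <- cfg$size[1]; W <- cfg$size[2]
  fov <- fov_disc(cfg)
  mask <- matrix(0L, H, W)
  if (cfg$n_trees == 0L) return(mask)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  R <- cfg$fov_radius_frac * min(H, W) / 2
  max_steps <- 40L * (H + W)
  for (tr in seq_len(cfg$n_trees)) {
    a0 <- runif(1, 0, 2 * pi)
    walkers <- list(list(y = cy + R * sin(a0), x = cx + R * cos(a0),
                         dir = a0 + pi + rnorm(1, 0, 0.3),
                         width = cfg$width_root))
    steps <- 0L
    while (length(walkers) > 0 && steps < max_steps) {
      wk <- walkers[[1]]
      walkers <- walkers[-1]
      repeat {
        steps <- steps + 1L
        if (steps >= max_steps) break
        wk$y <- wk$y + sin(wk$dir)
        wk$x <- wk$x + cos(wk$dir)
        iy <- round(wk$y); ix <- round(wk$x)
        if (iy < 1 || iy > H || ix < 1 || ix > W || fov[iy, ix] == 0) break
        mask <- stamp_disc(mask, wk$y, wk$x, wk$width / 2)
        wk$dir <- wk$dir + rnorm(1, 0, 0.12)
        wk$width <- wk$width * 0.9995
        if (runif(1) < cfg$branch_prob && wk$width > cfg$width_min) {
          child_w <- max(cfg$width_min, wk$width * 0.7)
          side <- sample(c(-1, 1), 1)
          walkers[[length(walkers) + 1L]] <-
            list(y = wk$y, x = wk$x, dir = wk$dir + side * runif(1, 0.3, 0.8),
                 width = child_w)
          wk$width <- max(cfg$width_min, wk$width * 0.85)
        }
        if (wk$width < cfg$width_min * 0.999) break
      }
    }
  }
  mask * fov
}

#' Render a vessel mask into a fundus-like photograph
#'
#' A background disc with smooth radial brightness, vessels darkened by
#' `cfg$contrast`, additive Gaussian noise of `cfg$noise_sd`, black outside
#' the FOV. Intensities are quantised to the 8-bit grid so rasters are
#' integer-deterministic.
#'
#' @param mask 0/1 vessel matrix from [generate_vessel_tree()].
#' @param cfg A [synthetic_config()]; rendering noise is reproducible in
#'   `cfg$seed` (offset so it is independent of the tree draw).
#' @return List with `image` (HxWx3 array in \[0,1\]) and `fov` (0/1 matrix).
#' @export
render_fundus <- function(mask, cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed + 1L)
  H <- cfg$size[1]; W <- cfg$size[2]
  stopifnot(identical(dim(mask), c(H, W)))
  fov <- fov_disc(cfg)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  R <- cfg$fov_radius_frac * min(H, W) / 2
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  rad2 <- ((yy - cy)^2 + (xx - cx)^2) / R^2
  bg <- 0.55 + 0.35 * (1 - pmin(rad2, 1))          # brighter centre
  g <- bg * ifelse(mask == 1, 1 - cfg$contrast, 1)
  chans <- list(r = pmin(1, g * 1.2), g = g, b = g * 0.5)
  img <- array(0, c(H, W, 3L))
  for (i in 1:3) {
    ch <- chans[[i]]
    if (cfg$noise_sd > 0) ch <- ch + rnorm(H * W, 0, cfg$noise_sd)
    img[, , i] <- pmin(1, pmax(0, ch)) * fov
  }
  img <- round(img * 255) / 255
  list(image = img, fov = fov)
}

#' Generate a synthetic dataset in memory
#'
#' @param n Number of samples; ids are `synth_0000`, `synth_0001`, ...
#'   Records are deterministic in `(n, cfg$seed)` and split 1:1 (first half
#'   train).
#' @param cfg A [synthetic_config()]; each sample uses a seed derived from
#'   `cfg$seed` and its index.
#' @return List of sample records as in [load_dataset()].
#' @export
make_dataset <- function(n, cfg = synthetic_config()) {
  stopifnot(n >= 0)
  records <- vector("list", n)
  n_train <- n %/% 2L
  for (i in seq_len(n)) {
    ci <- cfg
    ci$seed <- cfg$seed + 7919L * i
    mask <- generate_vessel_tree(ci)
    rf <- render_fundus(mask, ci)
    records[[i]] <- list(id = sprintf("synth_%04d", i - 1L),
                         image = rf$image, vessel_mask = mask,
                         fov_mask = rf$fov,
                         split = if (i <= n_train) "train" else "test")
  }
  records
}

#' Write a synthetic dataset in the DRIVE-style directory layout
#'
#' Emits `images/`, `1st_manual/` and `mask/` PNG files under `dir`, so the
#' generated data flows through exactly the same [load_dataset()] path as
#' real data.
#'
#' @param dir Output directory (created if needed).
#' @param n Number of samples.
#' @param cfg A [synthetic_config()].
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(dir, n, cfg = synthetic_config()) {
  for (sub in c("images", "1st_manual", "mask"))
    dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
  for (rec in make_dataset(n, cfg)) {
    write_raster(rec$image, file.path(dir, "images", paste0(rec$id, ".png")))
    write_raster(rec$vessel_mask + 0, file.path(dir, "1st_manual", paste0(rec$id, ".png")))
    write_raster(rec$fov_mask + 0, file.path(dir, "mask", paste0(rec$id, ".png")))
  }
  invisible(dir)
}
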