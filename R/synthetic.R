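# Seeded generator of cell-like binary segmentation fixtures with spatially
# heterogeneous difficulty.  Blobs (radially perturbed ellipses) are placed
# at random; a fixed fraction of the cells of a reference patch grid is
# designated "hard": blobs centred there get rough boundaries, and pixels
# there are rendered with lower foreground/background contrast and stronger
# texture noise.  The mask is the exact rasterized blob union, so
# image-degrading difficulty never corrupts the labels.  Everything is fully
# determined by (seed, index).

#' Synthetic dataset configuration
#'
#' Defaults emulate nucleus-like microscopy crops at desk scale: 96 x 96
#' images over a 4 x 4 reference grid (24 x 24 patches), a target foreground
#' fraction of 0.18 (inside the 6.6-31.8% range typical of binary
#' segmentation benchmarks), a quarter of the grid cells hard.
#'
#' @param image_size `c(h, w)`.
#' @param n_objects `c(min, max)` blob count; placement stops early once the
#'   foreground target is reached.
#' @param radius `c(min, max)` blob semi-axis range in pixels.
#' @param hard_region_frac fraction of reference-grid cells rendered hard.
#' @param boundary_roughness `c(easy, hard)` amplitude of the radial
#'   boundary perturbation.
#' @param texture_noise pixel noise standard deviation in easy cells (hard
#'   cells use `noise_hard_mult` times this value).
#' @param contrast `c(easy, hard)` foreground-minus-background intensity per
#'   difficulty class.
#' @param noise_hard_mult noise multiplier for hard cells.
#' @param foreground_target approximate foreground fraction in `(0, 1)`.
#' @param ref_grid_patches number of reference-grid patches (difficulty
#'   granularity).
#' @param seed base seed; combined with the pair index.
#' @export
synthetic_config <- function(image_size = c(96L, 96L),
                             n_objects = c(4L, 14L),
                             radius = c(7, 13),
                             hard_region_frac = 0.25,
                             boundary_roughness = c(easy = 0.08, hard = 0.45),
                             texture_noise = 0.04,
                             contrast = c(easy = 0.35, hard = 0.12),
                             noise_hard_mult = 3,
                             foreground_target = 0.18,
                             ref_grid_patches = 16L,
                             seed = 0L) {
  stopifnot(all(image_size >= 8), n_objects[1] >= 1, n_objects[2] >= n_objects[1],
            radius[1] > 0, radius[2] >= radius[1],
            hard_region_frac >= 0, hard_region_frac <= 1,
            length(boundary_roughness) == 2L, length(contrast) == 2L,
            texture_noise >= 0, noise_hard_mult >= 0,
            foreground_target > 0, foreground_target < 1)
  structure(list(
    image_size = as.integer(image_size), n_objects = as.integer(n_objects),
    radius = radius, hard_region_frac = hard_region_frac,
    boundary_roughness = boundary_roughness, texture_noise = texture_noise,
    contrast = contrast, noise_hard_mult = noise_hard_mult,
    foreground_target = foreground_target,
    ref_grid_patches = as.integer(ref_grid_patches), seed = as.integer(seed)
  ), class = "synthetic_config")
}

# per-pair seed, kept below 2^31
pair_seed <- function(cfg, index) {
  as.integer((as.numeric(cfg$seed) * 100003 + as.numeric(index) * 7919) %% 2147483647)
}

#' Generate one synthetic image/mask pair
#'
#' @param cfg a [synthetic_config()].
#' @param index pair index (>= 1); `(cfg$seed, index)` fully determines the
#'   output.
#' @return list with `image` (`H x W x 1` array in `[0, 1]`), `mask`
#'   (`H x W` binary matrix), `hard_cells` (`rows x cols` logical matrix of
#'   the reference grid), and `grid` (the reference [make_grid()]).
#' @export
generate_pair <- function(cfg, index = 1L) {
  stopifnot(inherits(cfg, "synthetic_config"), index >= 1)
  h <- cfg$image_size[1]; w <- cfg$image_size[2]
  if (h < 1 || w < 1) stop("degenerate image size")
  grid <- make_grid(h, w, cfg$ref_grid_patches)
  with_local_seed(pair_seed(cfg, index), function() {
    n_cells <- grid$grid_rows * grid$grid_cols
    n_hard <- round(cfg$hard_region_frac * n_cells)
    hard_cells <- matrix(FALSE, grid$grid_rows, grid$grid_cols)
    if (n_hard > 0) hard_cells[sample.int(n_cells, n_hard)] <- TRUE

    # pixel coordinate planes (row y, col x) and per-pixel cell difficulty
    ys <- matrix(seq_len(h), h, w)
    xs <- matrix(seq_len(w), h, w, byrow = TRUE)
    cell_r <- (ys - 1L) %/% grid$patch_h + 1L
    cell_c <- (xs - 1L) %/% grid$patch_w + 1L
    hard_px <- hard_cells[cbind(as.vector(cell_r), as.vector(cell_c))]
    dim(hard_px) <- c(h, w)

    mask <- matrix(0, h, w)
    n_target <- sample(cfg$n_objects[1]:cfg$n_objects[2], 1L)
    placed <- 0L
    while (placed < cfg$n_objects[2]) {
      if (placed >= n_target &&
          mean(mask) >= cfg$foreground_target) break
      cy <- stats::runif(1, cfg$radius[1], h - cfg$radius[1])
      cx <- stats::runif(1, cfg$radius[1], w - cfg$radius[1])
      ci <- min(grid$grid_rows, (floor(cy) - 1) %/% grid$patch_h + 1)
      cj <- min(grid$grid_cols, (floor(cx) - 1) %/% grid$patch_w + 1)
      amp <- if (hard_cells[ci, cj]) cfg$boundary_roughness[[2]] else cfg$boundary_roughness[[1]]
      rx <- stats::runif(1, cfg$radius[1], cfg$radius[2])
      ry <- stats::runif(1, cfg$radius[1], cfg$radius[2])
      rot <- stats::runif(1, 0, pi)
      kmax <- 5L
      coef <- stats::rnorm(kmax - 1L) / (2:kmax)
      phase <- stats::runif(kmax - 1L, 0, 2 * pi)
      dy <- (ys - cy); dx <- (xs - cx)
      u <- cos(rot) * dx + sin(rot) * dy
      v <- -sin(rot) * dx + cos(rot) * dy
      rho <- sqrt((u / rx)^2 + (v / ry)^2)
      phi <- atan2(v / ry, u / rx)
      pert <- matrix(0, h, w)
      for (k in 2:kmax) {
        pert <- pert + coef[k - 1L] * sin(k * phi + phase[k - 1L])
      }
      boundary <- pmax(1 + amp * pert, 0.2)
      mask[rho <= boundary] <- 1
      placed <- placed + 1L
      if (mean(mask) >= cfg$foreground_target && placed >= cfg$n_objects[1]) break
    }

    contrast <- ifelse(hard_px, cfg$contrast[[2]], cfg$contrast[[1]])
    noise_sd <- cfg$texture_noise * ifelse(hard_px, cfg$noise_hard_mult, 1)
    img <- 0.35 + mask * contrast +
      matrix(stats::rnorm(h * w), h, w) * noise_sd
    img <- pmin(pmax(img, 0), 1)
    dim(img) <- c(h, w, 1L)
    list(image = img, mask = mask, hard_cells = hard_cells, grid = grid)
  })
}

#' Generate an in-memory synthetic dataset
#'
#' @param cfg a [synthetic_config()].
#' @param n number of pairs; indices `first_index, ..., first_index + n - 1`.
#' @param first_index starting pair index.
#' @return a list of [generate_pair()] results.
#' @export
generate_dataset <- function(cfg, n, first_index = 1L) {
  lapply(seq_len(n) + first_index - 1L, function(i) generate_pair(cfg, i))
}

#' Write a synthetic dataset with a train/test manifest to disk
#'
#' Writes `img_####.pgm` / `mask_####.pgm` pairs plus `manifest.csv`
#' (columns `image,mask,split`) and the generator configuration as JSON.
#' The default 70-30 split convention applies when only a total is given.
#' Output is byte-for-byte reproducible for a fixed configuration.
#'
#' @param cfg a [synthetic_config()].
#' @param n_train,n_test pair counts per split.
#' @param out_dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
generate_manifest <- function(cfg, n_train, n_test, out_dir) {
  stopifnot(n_train >= 0, n_test >= 0)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop(sprintf("cannot create directory '%s'", out_dir))
  n <- n_train + n_test
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    pair <- generate_pair(cfg, i)
    img_path <- file.path(out_dir, sprintf("img_%04d.pgm", i))
    mask_path <- file.path(out_dir, sprintf("mask_%04d.pgm", i))
    write_pnm(img_path, pair$image, maxval = 255L)
    write_mask(mask_path, pair$mask)
    rows[[i]] <- data.frame(
      image = img_path, mask = mask_path,
      split = if (i <= n_train) "train" else "test"
    )
  }
  manifest <- do.call(rbind, rows)
  manifest_path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE, quote = FALSE)
  cfg_out <- cfg
  class(cfg_out) <- NULL
  jsonlite::write_json(cfg_out, file.path(out_dir, "synthetic_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest_path)
}
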