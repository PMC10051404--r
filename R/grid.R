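# Patch-grid geometry.  A patch grid partitions an H x W image into
# grid_rows x grid_cols contiguous, non-overlapping rectangles.  Patch
# indices are 0-based (i = row, j = column) and rectangles are half-open:
# patch (i, j) covers pixel rows [i*patch_h, (i+1)*patch_h) and columns
# [j*patch_w, (j+1)*patch_w), row-major.  This convention is fixed across
# the whole package.

check_mask <- function(m) {
  if (!all(m %in% c(0, 1))) stop("mask must contain only values 0 and 1")
  invisible(m)
}

check_probs <- function(p) {
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  invisible(p)
}

#' Construct a patch grid
#'
#' Chooses the factorization `grid_rows * grid_cols == num_patches` whose
#' patch aspect ratio (width/height) is closest, in log-ratio distance, to the
#' image's aspect ratio, among factorizations that divide the image evenly.
#' For a perfect square patch count on a square image this yields the
#' `sqrt(P) x sqrt(P)` lattice (e.g. 16 patches on 768 x 768 -> 4 x 4 patches
#' of 192 x 192).  When two factorizations are equidistant the one with more
#' grid rows wins, so e.g. 128 patches on 768 x 768 tile as 16 x 8
#' (patch 48 x 96); such non-square grids break the "both stages share one
#' input shape" property and a warning is emitted when they are used in the
#' two-stage pipeline.
#'
#' @param image_h,image_w image size in pixels.
#' @param num_patches total number of patches (>= 1).
#' @return an object of class `patch_grid` with fields `grid_rows`,
#'   `grid_cols`, `image_h`, `image_w`, `patch_h`, `patch_w`.
#' @export
make_grid <- function(image_h, image_w, num_patches) {
  stopifnot(image_h >= 1, image_w >= 1, num_patches >= 1)
  num_patches <- as.integer(num_patches)
  divs <- which(num_patches %% seq_len(num_patches) == 0L)
  cand <- data.frame(rows = divs, cols = num_patches %/% divs)
  cand <- cand[image_h %% cand$rows == 0L & image_w %% cand$cols == 0L, , drop = FALSE]
  if (nrow(cand) == 0L) {
    stop(sprintf(
      "no factorization of %d patches divides a %d x %d image evenly",
      num_patches, image_h, image_w
    ))
  }
  patch_aspect <- (image_w / cand$cols) / (image_h / cand$rows)
  dist <- abs(log(patch_aspect) - log(image_w / image_h))
  # ties resolve toward more grid rows
  best <- cand[order(dist, -cand$rows), , drop = FALSE][1, ]
  g <- structure(list(
    grid_rows = as.integer(best$rows), grid_cols = as.integer(best$cols),
    image_h = as.integer(image_h), image_w = as.integer(image_w),
    patch_h = as.integer(image_h / best$rows),
    patch_w = as.integer(image_w / best$cols)
  ), class = "patch_grid")
  stopifnot(
    g$grid_rows * g$grid_cols == num_patches,
    g$grid_rows * g$patch_h == g$image_h,
    g$grid_cols * g$patch_w == g$image_w
  )
  g
}

#' @export
print.patch_grid <- function(x, ...) {
  cat(sprintf(
    "patch_grid: %d x %d patches of %d x %d px over a %d x %d image\n",
    x$grid_rows, x$grid_cols, x$patch_h, x$patch_w, x$image_h, x$image_w
  ))
  invisible(x)
}

check_idx <- function(grid, idx) {
  stopifnot(length(idx) == 2L)
  i <- idx[[1]]; j <- idx[[2]]
  if (i < 0 || i >= grid$grid_rows || j < 0 || j >= grid$grid_cols) {
    stop(sprintf(
      "patch index (%d, %d) outside %d x %d grid",
      i, j, grid$grid_rows, grid$grid_cols
    ))
  }
  c(as.integer(i), as.integer(j))
}

check_grid_dims <- function(x, grid) {
  d <- dim(x)
  if (d[1] != grid$image_h || d[2] != grid$image_w) {
    stop(sprintf(
      "input is %d x %d but grid expects %d x %d",
      d[1], d[2], grid$image_h, grid$image_w
    ))
  }
}

#' Crop one patch out of an image or probability map
#'
#' @param x an `H x W` matrix or `H x W x C` array matching the grid's image
#'   size.
#' @param grid a [make_grid()] object.
#' @param idx 0-based patch index `c(i, j)` (row, column).
#' @return the `patch_h x patch_w (x C)` sub-tensor, as a copy.
#' @export
crop_patch <- function(x, grid, idx) {
  idx <- check_idx(grid, idx)
  check_grid_dims(x, grid)
  rows <- (idx[1] * grid$patch_h + 1):((idx[1] + 1) * grid$patch_h)
  cols <- (idx[2] * grid$patch_w + 1):((idx[2] + 1) * grid$patch_w)
  if (length(dim(x)) == 3L) x[rows, cols, , drop = FALSE] else x[rows, cols, drop = FALSE]
}

#' Write a refined patch back into a probability map
#'
#' Returns a copy of `x` equal to `patch` inside the `idx` rectangle and
#' bit-exactly equal to `x` everywhere else.
#'
#' @inheritParams crop_patch
#' @param patch a `patch_h x patch_w` tensor of the same kind as `x`.
#' @export
write_patch <- function(x, grid, idx, patch) {
  idx <- check_idx(grid, idx)
  check_grid_dims(x, grid)
  pd <- dim(patch)
  if (pd[1] != grid$patch_h || pd[2] != grid$patch_w) {
    stop(sprintf(
      "patch is %d x %d but grid expects %d x %d",
      pd[1], pd[2], grid$patch_h, grid$patch_w
    ))
  }
  rows <- (idx[1] * grid$patch_h + 1):((idx[1] + 1) * grid$patch_h)
  cols <- (idx[2] * grid$patch_w + 1):((idx[2] + 1) * grid$patch_w)
  if (length(dim(x)) == 3L) x[rows, cols, ] <- patch else x[rows, cols] <- patch
  x
}

#' All patch indices of a grid in row-major order
#'
#' @param grid a [make_grid()] object.
#' @return a two-column integer matrix of 0-based `(i, j)` pairs.
#' @export
grid_indices <- function(grid) {
  cbind(
    i = rep(0:(grid$grid_rows - 1L), each = grid$grid_cols),
    j = rep(0:(grid$grid_cols - 1L), times = grid$grid_rows)
  )
}
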