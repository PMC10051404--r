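# Two-stage inference: coarse pass on the downscaled image, per-patch
# uncertainty scoring, threshold selection, full-resolution refinement of
# the selected patches, and write-back into the coarse map.  Coarse
# probabilities inside refined patches are *replaced* by the refinement
# output (not blended).

#' Run the two-stage coarse-to-fine pipeline on one image
#'
#' Stage 1 (`m1`) segments the image downscaled to its input size and the
#' result is upscaled back to full resolution.  Per-patch mean uncertainty
#' is computed on that coarse map, patches scoring at least
#' `cfg$threshold * u_max` are re-segmented at full resolution by `m2`, and
#' their crops replace the coarse probabilities.  With `context = TRUE`,
#' the patch-aligned crop of Stage 1's penultimate activation (computed once
#' per image) is resized and added elementwise to Stage 2's penultimate
#' layer.
#'
#' @param m1,m2 [build_model()] objects; `m1$input_size` must equal the patch
#'   size for square grids (same-input-shape property), `m2$input_size` must
#'   equal the patch size.
#' @param x `H x W x C` image matching the grid.
#' @param grid a [make_grid()] object.
#' @param cfg a [selection_config()]; only `threshold` and `variant` are
#'   used at inference.
#' @param context enable cross-stage context fusion.
#' @return an object of class `two_stage_result`: list with `prob_map`
#'   (final `H x W` probabilities), `coarse_map` (upscaled Stage-1-only
#'   map), `refined` (0-based index matrix of refined patches), and
#'   `scores` (the [patch_scores()]).
#' @export
run_two_stage <- function(m1, m2, x, grid, cfg, context = FALSE) {
  stopifnot(inherits(m1, "seg_model"), inherits(m2, "seg_model"),
            inherits(grid, "patch_grid"), inherits(cfg, "selection_config"))
  d <- dim(x)
  if (length(d) == 2L) { dim(x) <- c(d, 1L); d <- dim(x) }
  check_grid_dims(x, grid)
  if (m2$input_size[1] != grid$patch_h || m2$input_size[2] != grid$patch_w) {
    stop(sprintf(
      "Stage-2 model input %d x %d does not match patch size %d x %d",
      m2$input_size[1], m2$input_size[2], grid$patch_h, grid$patch_w
    ))
  }
  square <- grid$grid_rows == grid$grid_cols && grid$image_h == grid$image_w
  if (square) {
    # same-input-shape property: Stage 1 sees the image downscaled to one
    # patch's size
    if (any(m1$input_size != c(grid$patch_h, grid$patch_w))) {
      stop(sprintf(
        "Stage-1 model input %d x %d does not match patch size %d x %d",
        m1$input_size[1], m1$input_size[2], grid$patch_h, grid$patch_w
      ))
    }
  } else {
    warning("non-square grid: the two stages do not share one input shape")
  }
  if (context && penultimate_channels(m1) != penultimate_channels(m2)) {
    stop("penultimate channel mismatch between stages (different architectures?)")
  }

  xs <- downscale(x, m1$input_size[1], m1$input_size[2])
  s1 <- predict_probs(m1, xs)
  coarse <- upscale(s1$probs, grid$image_h, grid$image_w)
  scores <- patch_scores(coarse, grid, cfg$variant)
  refined <- select_patches(scores, cfg$threshold)

  prob_map <- coarse
  if (nrow(refined) > 0L) {
    for (r in seq_len(nrow(refined))) {
      idx <- refined[r, ]
      ctx <- if (context) {
        context_features(s1$penultimate, grid, idx,
                         target_shape = stage2_penultimate_shape(m2))
      } else NULL
      patch_pred <- predict_probs(m2, crop_patch(x, grid, idx),
                                  penultimate_add = ctx)
      prob_map <- write_patch(prob_map, grid, idx, patch_pred$probs)
    }
  }
  structure(list(prob_map = prob_map, coarse_map = coarse, refined = refined,
                 scores = scores),
            class = "two_stage_result")
}

# spatial size of m's penultimate activation at its recorded input size
stage2_penultimate_shape <- function(m) {
  dims <- list()
  for (node in m$graph) {
    d <- switch(node$op,
      input = m$input_size,
      conv = c(conv_out_dim(dims[[node$input]][1], node$k, node$stride, node$dilation),
               conv_out_dim(dims[[node$input]][2], node$k, node$stride, node$dilation)),
      maxpool = c(conv_out_dim(dims[[node$input]][1], node$k, node$stride),
                  conv_out_dim(dims[[node$input]][2], node$k, node$stride)),
      upsample = {
        if (!is.null(node$to)) {
          if (identical(node$to, "input")) m$input_size else dims[[node$to]]
        } else dims[[node$input[1]]] * node$scale
      },
      globalpool = c(1L, 1L),
      dims[[node$input[1]]]
    )
    dims[[node$name]] <- d
    if (node$name == m$penultimate) return(d)
  }
  stop("penultimate node not found")
}

#' Patch-aligned crop of the Stage-1 penultimate activation
#'
#' Crops the sub-region of the (low-resolution) Stage-1 penultimate feature
#' map that spatially corresponds to patch `(i, j)` using proportional
#' coordinates with half-open floor rounding — rows
#' `[floor(i*H'/rows), floor((i+1)*H'/rows))` — then bilinearly resizes it to
#' `target_shape` for elementwise addition to Stage 2's penultimate layer.
#'
#' @param m1_penultimate `H' x W' x C` activation from Stage 1's coarse pass.
#' @param grid the patch grid.
#' @param idx 0-based `c(i, j)`.
#' @param target_shape `c(h, w)` of Stage 2's penultimate activation.
#' @return an `h x w x C` activation tensor.
#' @export
context_features <- function(m1_penultimate, grid, idx, target_shape) {
  idx <- check_idx(grid, idx)
  d <- dim(m1_penultimate)
  stopifnot(length(d) == 3L)
  r0 <- floor(idx[1] * d[1] / grid$grid_rows)
  r1 <- floor((idx[1] + 1) * d[1] / grid$grid_rows)
  c0 <- floor(idx[2] * d[2] / grid$grid_cols)
  c1 <- floor((idx[2] + 1) * d[2] / grid$grid_cols)
  if (r1 <= r0 || c1 <= c0) {
    stop("patch grid finer than the penultimate feature map")
  }
  sub <- m1_penultimate[(r0 + 1):r1, (c0 + 1):c1, , drop = FALSE]
  resize_bilinear(sub, target_shape[1], target_shape[2])
}

#' Dice coefficient between two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; defined as 1 when both masks are
#' empty.
#'
#' @param pred,truth `H x W` binary masks.
#' @return a value in `[0, 1]`.
#' @export
dice <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth))) stop("mask shapes differ")
  check_mask(pred); check_mask(truth)
  denom <- sum(pred) + sum(truth)
  if (denom == 0) return(1)
  2 * sum(pred * truth) / denom
}

#' Evaluate the pipeline over a dataset manifest
#'
#' Runs the two-stage pipeline (or, with `mode = "baseline"`, a single model
#' on the full image) over the manifest's test split, reporting per-image
#' and mean Dice (probabilities thresholded at 0.5), the fraction of patches
#' refined, and an analytic cost estimate in multiply-accumulates:
#' Stage-1 MACs at its input size plus (number of refined patches) x
#' Stage-2 MACs per patch.  Unreadable or mismatched files are collected as
#' per-file errors and the run continues.
#'
#' @param m1 Stage-1 model (or the single model in baseline mode).
#' @param m2 Stage-2 model; ignored in baseline mode.
#' @param manifest a manifest data.frame ([load_manifest()]) or a list of
#'   in-memory `list(image =, mask =)` pairs.
#' @param grid a [make_grid()] object.
#' @param cfg a [selection_config()].
#' @param context enable context fusion.
#' @param mode `"two_stage"` or `"baseline"`.
#' @param split which manifest split to evaluate (ignored for in-memory
#'   pairs).
#' @return an `eval_report` list: `per_image` data.frame, `mean_dice`,
#'   `frac_refined`, `total_macs`, `mode`, `errors`.
#' @export
evaluate_pipeline <- function(m1, m2 = NULL, manifest, grid, cfg,
                              context = FALSE,
                              mode = c("two_stage", "baseline"),
                              split = "test") {
  mode <- match.arg(mode)
  pairs <- manifest_pairs(manifest, split)
  n_patches <- grid$grid_rows * grid$grid_cols
  errors <- character()
  rows <- list()
  for (nm in names(pairs)) {
    res <- tryCatch({
      pair <- pairs[[nm]]()
      truth <- pair$mask
      if (mode == "baseline") {
        pr <- predict_probs(m1, pair$image)
        list(dice = dice((pr$probs > 0.5) * 1, truth), refined = NA_real_,
             macs = count_flops(m1, dim(pair$image)[1:2]))
      } else {
        ts <- run_two_stage(m1, m2, pair$image, grid, cfg, context = context)
        list(dice = dice((ts$prob_map > 0.5) * 1, truth),
             refined = nrow(ts$refined) / n_patches,
             macs = count_flops(m1, m1$input_size) +
               nrow(ts$refined) * count_flops(m2, c(grid$patch_h, grid$patch_w)))
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors <- c(errors, sprintf("%s: %s", nm, conditionMessage(res)))
    } else {
      rows[[nm]] <- data.frame(id = nm, dice = res$dice,
                               frac_refined = res$refined, macs = res$macs)
    }
  }
  per_image <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(), dice = numeric(), frac_refined = numeric(),
               macs = numeric())
  rownames(per_image) <- NULL
  structure(list(
    mode = mode,
    per_image = per_image,
    mean_dice = mean(per_image$dice),
    frac_refined = if (mode == "baseline") NA_real_ else mean(per_image$frac_refined),
    total_macs = sum(per_image$macs),
    n_images = nrow(per_image),
    errors = errors
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "eval_report (%s): %d images, mean Dice %.4f, frac refined %s, total MACs %.3g\n",
    x$mode, x$n_images, x$mean_dice,
    if (is.na(x$frac_refined)) "-" else sprintf("%.2f", x$frac_refined),
    x$total_macs
  ))
  if (length(x$errors)) cat("errors:\n", paste(" -", x$errors, collapse = "\n"), "\n")
  invisible(x)
}

# normalize a manifest (data.frame of paths or list of pairs) into a named
# list of thunks returning list(image, mask)
manifest_pairs <- function(manifest, split = NULL) {
  if (is.data.frame(manifest)) {
    rows <- if (!is.null(split)) manifest[manifest$split == split, , drop = FALSE] else manifest
    out <- lapply(seq_len(nrow(rows)), function(k) {
      img <- rows$image[k]; msk <- rows$mask[k]
      function() {
        x <- read_image(img)
        y <- read_mask(msk)
        if (!all(dim(x)[1:2] == dim(y))) {
          stop(sprintf("image/mask size mismatch: %s vs %s", img, msk))
        }
        list(image = x, mask = y)
      }
    })
    names(out) <- basename(rows$image)
    out
  } else if (is.list(manifest)) {
    out <- lapply(manifest, function(p) function() p)
    if (is.null(names(manifest)) || any(names(manifest) == "")) {
      names(out) <- sprintf("pair_%03d", seq_along(out))
    }
    out
  } else {
    stop("manifest must be a data.frame of paths or a list of image/mask pairs")
  }
}
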