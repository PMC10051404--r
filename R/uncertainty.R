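# Pixel uncertainty, per-patch scores, and the selection function.
#
# Two uncertainty variants are supported.  "full_entropy" (the default) is
# the binary Shannon entropy H(p) = -p log2 p - (1-p) log2 (1-p), maximal
# (= 1) at p = 0.5 and symmetric about it.  "paper" is the one-sided
# surprisal u(p) = -p log2 p, which peaks at p = 1/e ~ 0.368 with maximum
# log2(e)/e ~ 0.531 and is *not* symmetric -- it rates confident-foreground
# pixels (p near 1) certain but confident-background pixels (p near 0)
# mildly uncertain.  Because the one-sided form contradicts the usual
# reading that uncertainty is largest at p = 0.5, full binary entropy is
# the default; the one-sided form is kept as an explicit variant.
#
# Selection thresholds are interpreted on a [0,1]-normalized scale (raw
# patch scores divided by the variant's maximum), so threshold 1 selects
# only saturated patches and threshold 0 selects everything, under either
# variant.

uncertainty_variants <- c("full_entropy", "paper")

#' Maximum attainable pixel uncertainty of a variant
#'
#' `full_entropy` attains 1 at p = 0.5; `paper` attains `log2(e)/e`
#' (about 0.5307) at p = 1/e.
#'
#' @param variant `"full_entropy"` or `"paper"`.
#' @export
uncertainty_max <- function(variant = c("full_entropy", "paper")) {
  variant <- match.arg(variant)
  if (variant == "full_entropy") 1 else log2(exp(1)) / exp(1)
}

#' Per-pixel prediction uncertainty
#'
#' Vectorized over `p`, with the convention `0 * log 0 = 0` so both variants
#' are 0 at p = 0 and p = 1.
#'
#' @param p foreground probabilities in `[0, 1]`.
#' @param variant uncertainty variant, see [uncertainty_max()].
#' @return nonnegative uncertainties, same shape as `p`.
#' @export
pixel_uncertainty <- function(p, variant = c("full_entropy", "paper")) {
  variant <- match.arg(variant)
  check_probs(p)
  plog <- function(q) ifelse(q > 0, q * log2(q), 0)
  u <- if (variant == "paper") -plog(p) else -plog(p) - plog(1 - p)
  if (!is.null(dim(p))) dim(u) <- dim(p)
  u
}

#' Per-patch uncertainty scores
#'
#' The score of patch (i, j) is the mean pixel uncertainty over its crop of
#' the full-resolution coarse probability map.
#'
#' @param p_hat an `H x W` probability map matching `grid`'s image size.
#' @param grid a [make_grid()] object.
#' @param variant uncertainty variant.
#' @return an object of class `patch_scores`: list with `scores`
#'   (`grid_rows x grid_cols` matrix), `grid`, and `variant`.
#' @export
patch_scores <- function(p_hat, grid, variant = c("full_entropy", "paper")) {
  variant <- match.arg(variant)
  check_grid_dims(p_hat, grid)
  u <- pixel_uncertainty(p_hat, variant)
  # block means: average u over each patch_h x patch_w cell
  rfac <- rep(seq_len(grid$grid_rows), each = grid$patch_h)
  cfac <- rep(seq_len(grid$grid_cols), each = grid$patch_w)
  sums <- rowsum(t(rowsum(u, rfac)), cfac)  # grid_cols x grid_rows
  scores <- t(sums) / (grid$patch_h * grid$patch_w)
  structure(
    list(scores = unname(scores), grid = grid, variant = variant),
    class = "patch_scores"
  )
}

#' @export
print.patch_scores <- function(x, ...) {
  cat(sprintf(
    "patch_scores (%s variant, u_max = %.4f):\n", x$variant,
    uncertainty_max(x$variant)
  ))
  print(round(x$scores, 4))
  invisible(x)
}

#' Threshold-based patch selection (inference-time g)
#'
#' Selects patches whose score is at least `threshold * u_max(variant)`,
#' i.e. the threshold lives on a [0,1]-normalized scale: 0 selects all
#' patches, 1 selects only patches saturated at the variant's maximum.
#' The comparison is `>=`.
#'
#' @param scores a [patch_scores()] object.
#' @param threshold normalized threshold in `[0, 1]`.
#' @return 0-based `(i, j)` index matrix (possibly 0 rows), row-major order.
#' @export
select_patches <- function(scores, threshold) {
  stopifnot(inherits(scores, "patch_scores"), threshold >= 0, threshold <= 1)
  cut <- threshold * uncertainty_max(scores$variant)
  idx <- grid_indices(scores$grid)
  keep <- as.vector(t(scores$scores)) >= cut  # row-major flatten
  idx[keep, , drop = FALSE]
}

#' Selection configuration
#'
#' Bundles the training-time sampling strategy, the inference-time threshold,
#' the uncertainty variant, and the RNG seed that governs sampling.
#'
#' @param strategy `"random"`, `"weighted"` or `"highest"`.
#' @param threshold normalized selection threshold in `[0, 1]` (typical
#'   operating point 0.25; 0.5 is the conventional default).
#' @param variant uncertainty variant.
#' @param seed integer seed for all sampling randomness.
#' @export
selection_config <- function(strategy = c("weighted", "random", "highest"),
                             threshold = 0.25,
                             variant = c("full_entropy", "paper"),
                             seed = 0L) {
  strategy <- match.arg(strategy)
  variant <- match.arg(variant)
  stopifnot(threshold >= 0, threshold <= 1)
  structure(
    list(strategy = strategy, threshold = threshold, variant = variant,
         seed = as.integer(seed)),
    class = "selection_config"
  )
}

#' Sample one training patch (training-time g)
#'
#' Draws a single patch index according to the configured strategy:
#' `random` is uniform over all patches; `weighted` draws patch (i, j) with
#' probability `score[i,j] / sum(scores)` (uniform when all scores are 0);
#' `highest` deterministically returns the arg-max score, ties broken by the
#' smallest row-major index.  Randomness comes from R's current RNG stream,
#' so results are reproducible under `set.seed()`.
#'
#' @param scores a [patch_scores()] object.
#' @param cfg a [selection_config()].
#' @return a 0-based integer vector `c(i, j)`.
#' @export
sample_training_patch <- function(scores, cfg) {
  stopifnot(inherits(scores, "patch_scores"), inherits(cfg, "selection_config"))
  s <- as.vector(t(scores$scores))  # row-major
  n <- length(s)
  stopifnot(n >= 1)
  k <- switch(cfg$strategy,
    random = sample.int(n, 1L),
    weighted = {
      if (sum(s) <= 0) sample.int(n, 1L) else sample.int(n, 1L, prob = s / sum(s))
    },
    highest = which.max(s),  # which.max returns the first (row-major) maximum
    stop(sprintf("unknown strategy '%s'", cfg$strategy))
  )
  idx <- grid_indices(scores$grid)
  idx[k, ]
}
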