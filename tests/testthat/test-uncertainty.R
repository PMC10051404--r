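# pixel uncertainty, patch scores, selection and sampling

test_that("pixel_uncertainty endpoints and maxima", {
  for (v in c("paper", "full_entropy")) {
    expect_equal(pixel_uncertainty(0, v), 0)
    expect_equal(pixel_uncertainty(1, v), 0)
  }
  expect_equal(pixel_uncertainty(0.5, "paper"), 0.5)
  expect_equal(pixel_uncertainty(0.5, "full_entropy"), 1)
  expect_error(pixel_uncertainty(1.2), "\\[0, 1\\]")

  # dense grid-search oracle: the one-sided variant peaks at 1/e
  grid_p <- seq(0, 1, by = 1e-5)
  u <- pixel_uncertainty(grid_p, "paper")
  expect_equal(grid_p[which.max(u)], 1 / exp(1), tolerance = 1e-4)
  expect_equal(max(u), log2(exp(1)) / exp(1), tolerance = 1e-8)
  expect_equal(max(u), uncertainty_max("paper"), tolerance = 1e-8)
})

test_that("entropy symmetry holds for full_entropy only", {
  p <- seq(0.01, 0.99, by = 0.01)
  expect_equal(pixel_uncertainty(p, "full_entropy"),
               pixel_uncertainty(1 - p, "full_entropy"))
  asym <- setdiff(p, c(0.5))
  expect_true(all(abs(pixel_uncertainty(asym, "paper") -
                        pixel_uncertainty(1 - asym, "paper")) > 1e-12))
})

test_that("patch_scores equals the brute-force per-pixel oracle", {
  expect_equal(
    patch_scores(matrix(0, 8, 8), make_grid(8, 8, 4))$scores,
    matrix(0, 2, 2)
  )
  # hand oracle: [[1,1],[0.5,0.5]] under one patch, paper variant
  ps <- patch_scores(matrix(c(1, 0.5, 1, 0.5), 2, 2), make_grid(2, 2, 1), "paper")
  expect_equal(ps$scores[1, 1], 0.25)

  # brute-force double loop on random 64x64 maps with 4 and 16 patches
  for (np in c(4, 16)) {
    for (v in c("paper", "full_entropy")) {
      p_hat <- rand_probs(64, 64, seed = np)
      g <- make_grid(64, 64, np)
      got <- patch_scores(p_hat, g, v)$scores
      want <- matrix(0, g$grid_rows, g$grid_cols)
      for (i in 0:(g$grid_rows - 1)) for (j in 0:(g$grid_cols - 1)) {
        acc <- 0
        for (r in (i * g$patch_h + 1):((i + 1) * g$patch_h)) {
          for (cc in (j * g$patch_w + 1):((j + 1) * g$patch_w)) {
            acc <- acc + pixel_uncertainty(p_hat[r, cc], v)
          }
        }
        want[i + 1, j + 1] <- acc / (g$patch_h * g$patch_w)
      }
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("select_patches thresholds on the normalized scale", {
  g <- make_grid(6, 6, 9)
  p_hat <- rand_probs(6, 6, seed = 9)
  sc <- patch_scores(p_hat, g)
  expect_identical(nrow(select_patches(sc, 0)), 9L)        # >=0 selects all
  stopifnot(all(sc$scores < uncertainty_max(sc$variant)))
  expect_identical(nrow(select_patches(sc, 1)), 0L)        # nothing saturated

  # direct enumeration: normalized scores {0.1, 0.3, 0.6}, threshold 0.25
  sc3 <- structure(list(
    scores = matrix(c(0.1, 0.3, 0.6) * uncertainty_max("full_entropy"), 1, 3),
    grid = make_grid(1, 3, 3), variant = "full_entropy"
  ), class = "patch_scores")
  sel <- select_patches(sc3, 0.25)
  expect_identical(sel[, "j"], c(1L, 2L))

  # monotonicity: tau1 <= tau2 => selection(tau2) subset of selection(tau1)
  taus <- c(0, 0.25, 0.5, 0.75, 1)
  for (s in 1:5) {
    sc_r <- patch_scores(rand_probs(8, 8, seed = 100 + s), make_grid(8, 8, 16))
    sets <- lapply(taus, function(t) {
      m <- select_patches(sc_r, t)
      paste(m[, 1], m[, 2])
    })
    for (k in 2:length(sets)) expect_true(all(sets[[k]] %in% sets[[k - 1]]))
  }
})

test_that("sampling strategies follow their contracts", {
  g <- make_grid(1, 3, 3)
  mk <- function(s) structure(list(scores = matrix(s, 1, 3), grid = g,
                                   variant = "full_entropy"),
                              class = "patch_scores")
  # degenerate weighted: all mass on patch 3
  set.seed(1)
  cfgw <- selection_config("weighted", seed = 1)
  for (k in 1:20) expect_identical(sample_training_patch(mk(c(0, 0, 1)), cfgw),
                                   c(i = 0L, j = 2L))
  # weighted with zero scores falls back to uniform (all patches reachable)
  set.seed(2)
  drawn <- replicate(60, sample_training_patch(mk(c(0, 0, 0)), cfgw)[2])
  expect_setequal(unique(drawn), 0:2)
  # highest: argmax with row-major tie-break
  cfgh <- selection_config("highest", seed = 1)
  expect_identical(sample_training_patch(mk(c(0.9, 0.9, 0.2)), cfgh),
                   c(i = 0L, j = 0L))
  # determinism: same seed => same sequence
  seq_draw <- function() {
    set.seed(42)
    replicate(25, sample_training_patch(mk(c(0.2, 0.5, 0.3)), cfgw)[2])
  }
  expect_identical(seq_draw(), seq_draw())
  # weighted probabilities are normalized scores: binomial 3-sigma check
  set.seed(3)
  n <- 10000
  hits <- sum(replicate(n, sample_training_patch(mk(c(1, 3, 0)), cfgw)[2]) == 1)
  p <- 0.75
  expect_lt(abs(hits / n - p), 3 * sqrt(p * (1 - p) / n))
})
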