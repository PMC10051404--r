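# grid geometry: factorization rule, crop/write-back, interpolation

test_that("make_grid picks the aspect-closest factorization", {
  g16 <- make_grid(768, 768, 16)
  expect_identical(c(g16$grid_rows, g16$grid_cols), c(4L, 4L))
  expect_identical(c(g16$patch_h, g16$patch_w), c(192L, 192L))

  g1 <- make_grid(768, 768, 1)
  expect_identical(c(g1$grid_rows, g1$grid_cols, g1$patch_h, g1$patch_w),
                   c(1L, 1L, 768L, 768L))

  # enumeration oracle for 128 patches: all factor pairs dividing 768,
  # patch aspect closest to 1, ties toward more rows
  pairs <- do.call(rbind, lapply(1:128, function(r) {
    if (128 %% r == 0) c(r, 128 / r) else NULL
  }))
  ok <- pairs[768 %% pairs[, 1] == 0 & 768 %% pairs[, 2] == 0, , drop = FALSE]
  aspect <- abs(log((768 / ok[, 2]) / (768 / ok[, 1])))
  best <- ok[order(aspect, -ok[, 1]), , drop = FALSE][1, ]
  g128 <- make_grid(768, 768, 128)
  expect_identical(c(g128$grid_rows, g128$grid_cols), as.integer(best))
  expect_identical(c(g128$grid_rows, g128$grid_cols), c(16L, 8L))
  expect_identical(c(g128$patch_h, g128$patch_w), c(48L, 96L))
})

test_that("make_grid errors when no factorization divides the image", {
  expect_error(make_grid(97, 97, 16), "no factorization")
  expect_error(make_grid(100, 100, 7), "no factorization")
})

test_that("crop_patch returns the half-open rectangle", {
  x <- matrix(1:16, 4, 4)
  g <- make_grid(4, 4, 4)
  expect_identical(crop_patch(x, g, c(0, 0)), x[1:2, 1:2])
  expect_identical(crop_patch(x, g, c(1, 1)), x[3:4, 3:4])
  # arithmetic from the 4x4-on-768 example: idx (0,1) covers rows [0,192),
  # cols [192,384)
  g768 <- make_grid(768, 768, 16)
  xr <- rand_probs(768, 768, seed = 5)
  expect_identical(crop_patch(xr, g768, c(0, 1)), xr[1:192, 193:384])
  expect_error(crop_patch(x, g, c(2, 0)), "outside")
  expect_error(crop_patch(matrix(0, 5, 4), g, c(0, 0)), "grid expects")
})

test_that("write_patch is local, exact, and inverts decomposition", {
  g <- make_grid(8, 8, 4)
  x <- rand_probs(8, 8, seed = 2)
  patch <- rand_probs(4, 4, seed = 3)
  out <- write_patch(x, g, c(0, 0), patch)
  expect_identical(out[1:4, 1:4], patch)        # roundtrip read-back
  expect_identical(out[5:8, ], x[5:8, ])        # half-open boundary: row patch_h unchanged
  expect_identical(out[1:4, 5:8], x[1:4, 5:8])
  expect_error(write_patch(x, g, c(0, 0), matrix(0, 3, 4)), "patch is")

  # reassembling all crops reproduces the source bit-exact (tiling partition)
  for (gg in list(make_grid(12, 18, 6), make_grid(16, 16, 16))) {
    src <- rand_probs(gg$image_h, gg$image_w, seed = 4)
    rebuilt <- matrix(0, gg$image_h, gg$image_w)
    idx <- grid_indices(gg)
    px <- list()
    for (r in seq_len(nrow(idx))) px[[r]] <- crop_patch(src, gg, idx[r, ])
    expect_identical(sort(unlist(px)), sort(as.vector(src)))  # pixel multiset
    for (r in seq_len(nrow(idx))) rebuilt <- write_patch(rebuilt, gg, idx[r, ], px[[r]])
    expect_identical(rebuilt, src)
  }
})

test_that("bilinear resize preserves constants and range; masks stay binary", {
  const <- matrix(0.7, 13, 9)
  for (sz in list(c(5, 5), c(26, 18), c(13, 9), c(1, 1))) {
    out <- resize_bilinear(const, sz[1], sz[2])
    expect_equal(max(abs(out - 0.7)), 0)
  }
  x <- rand_probs(20, 20, seed = 6)
  out <- resize_bilinear(x, 37, 11)
  expect_gte(min(out), min(x))
  expect_lte(max(out), max(x))

  m <- matrix(rbinom(400, 1, 0.3), 20, 20)
  for (sz in list(c(7, 31), c(40, 40), c(3, 3))) {
    rm_ <- resize_mask(m, sz[1], sz[2])
    expect_true(all(rm_ %in% c(0, 1)))
  }
  expect_error(resize_mask(matrix(0.5, 4, 4), 2, 2), "only values 0 and 1")

  # pipeline geometry: 768 downscaled by the 16-patch factor is one patch
  g <- make_grid(768, 768, 16)
  img <- array(rand_probs(768, 768, seed = 7), c(768, 768, 1))
  small <- downscale(img, g$patch_h, g$patch_w)
  expect_identical(dim(small)[1:2], c(192L, 192L))
})
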