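# focal loss, augmentation, Adam training loops, cross-stage transfer

test_that("focal loss: reductions, hand value, brute-force oracle", {
  set.seed(1)
  p <- matrix(runif(64, 0.05, 0.95), 8, 8)
  y <- matrix(rbinom(64, 1, 0.4), 8, 8)
  # gamma = 0, alpha = 1 reduces to mean binary cross-entropy
  bce <- -mean(y * log(p) + (1 - y) * log(1 - p))
  expect_equal(focal_loss(p, y, gamma = 0, alpha = 1), bce, tolerance = 1e-12)
  # p_t = 1 everywhere -> 0 (up to the 1e-7 clamp)
  expect_lt(focal_loss(matrix(1, 4, 4), matrix(1, 4, 4)), 1e-10)
  # single pixel p = 0.5, y = 1, gamma = 2: (1-0.5)^2 * (-ln 0.5)
  expect_equal(focal_loss(matrix(0.5), matrix(1)), 0.25 * log(2),
               tolerance = 1e-12)
  # brute-force per-pixel evaluation, weighted case
  for (gam in c(0, 1, 2)) {
    for (al in c(1, 0.25)) {
      acc <- 0
      for (k in seq_along(p)) {
        pt <- if (y[k] == 1) p[k] else 1 - p[k]
        at <- if (al < 1) (if (y[k] == 1) al else 1 - al) else 1
        acc <- acc - at * (1 - pt)^gam * log(pt)
      }
      expect_equal(focal_loss(p, y, gam, al), acc / length(p),
                   tolerance = 1e-12)
    }
  }
})

test_that("focal loss gradient matches finite differences", {
  set.seed(2)
  m <- build_model("tiny", c(8, 8), in_channels = 1, seed = 3)
  x <- array(runif(64), c(8, 8, 1))
  y <- matrix(rbinom(64, 1, 0.4), 8, 8)
  cfg <- train_config(epochs = 1)
  st <- patchrefine:::train_step_grads(m, x, y, cfg)
  eps <- 1e-6
  for (nm in c("c1", "c3", "head")) {
    idx <- sample(length(m$params[[nm]]$wmat), 2)
    for (i in idx) {
      mp <- m; mp$params[[nm]]$wmat[i] <- mp$params[[nm]]$wmat[i] + eps
      mm <- m; mm$params[[nm]]$wmat[i] <- mm$params[[nm]]$wmat[i] - eps
      g_num <- (patchrefine:::train_step_grads(mp, x, y, cfg)$loss -
                patchrefine:::train_step_grads(mm, x, y, cfg)$loss) / (2 * eps)
      expect_equal(st$grads[[nm]]$wmat[i], g_num, tolerance = 1e-5)
    }
  }
})

test_that("augmentation: identity config, involution, translation trace", {
  set.seed(3)
  x <- array(runif(100 * 100), c(100, 100, 1))
  y <- matrix(rbinom(1e4, 1, 0.3), 100, 100)
  idcfg <- augment_config(0, 0, 0, 0)
  out <- augment_pair(x, y, idcfg)
  expect_identical(out$image, x)
  expect_identical(out$mask, y)

  # forced double flip returns the original
  flip_cfg <- augment_config(1, 0, 0, 0)
  once <- augment_pair(x, y, flip_cfg)
  twice <- augment_pair(once$image, once$mask, flip_cfg)
  expect_identical(twice$image, x)
  expect_identical(twice$mask, y)

  # a single bright pixel moves by at most 10 px under 10% translation
  xb <- array(0, c(100, 100, 1)); xb[50, 50, 1] <- 1
  yb <- matrix(0, 100, 100); yb[50, 50] <- 1
  tr_cfg <- augment_config(0, 0, 0, 0.1)
  for (k in 1:10) {
    tr <- augment_pair(xb, yb, tr_cfg)
    expect_identical(dim(tr$mask), c(100L, 100L))
    pos <- which(tr$mask == 1, arr.ind = TRUE)
    expect_gte(nrow(pos), 1)
    expect_true(all(abs(pos[, 1] - 50) <= 10 + 1))
    expect_true(all(abs(pos[, 2] - 50) <= 10 + 1))
  }

  # range/binarity preservation under the full default augmentation
  for (k in 1:5) {
    out <- augment_pair(x, y, augment_config())
    expect_true(all(out$image >= 0 & out$image <= 1))
    expect_true(all(out$mask %in% c(0, 1)))
  }
})

test_that("train_stage1: loss decreases, zero lr is a no-op, bookkeeping", {
  grid <- desk_grid()
  pairs <- synth_pairs(12, seed = 5)
  # training-progress property over 3 seeds
  for (seed in 1:3) {
    m <- build_model("tiny", c(24, 24), in_channels = 1, seed = seed)
    m <- train_stage1(m, pairs, grid, desk_train_config(seed, epochs = 6))
    hist <- m$history$stage1_loss
    expect_length(hist, 6)
    expect_lt(hist[6], hist[1])
  }
  m0 <- build_model("tiny", c(24, 24), in_channels = 1, seed = 1)
  m0t <- train_stage1(m0, pairs, grid,
                      train_config(learning_rate = 0, epochs = 2,
                                   image_size = c(96, 96), seed = 1))
  expect_identical(m0t$params, m0$params)
  expect_error(train_stage1(m0, list(), grid, desk_train_config(1)),
               "empty")
})

test_that("init_stage2_from_stage1 is a deep copy with equal weights", {
  m1 <- build_model("tiny", c(24, 24), in_channels = 1, seed = 4)
  m2 <- init_stage2_from_stage1(m1)
  # exhaustive parameter comparison
  expect_identical(m2$params, m1$params)
  set.seed(8)
  x <- array(runif(24 * 24), c(24, 24, 1))
  expect_identical(predict_probs(m2, x)$probs, predict_probs(m1, x)$probs)
  # mutating m2 leaves m1 untouched
  before <- m1$params$c1$wmat
  m2$params$c1$wmat[] <- 0
  expect_identical(m1$params$c1$wmat, before)
})

test_that("train_stage2: frozen stage 1, deterministic highest sampling", {
  grid <- desk_grid()
  pairs <- synth_pairs(6, seed = 9)
  m1 <- build_model("tiny", c(24, 24), in_channels = 1, seed = 2)
  m1_params_before <- m1$params
  sel <- selection_config("highest", seed = 3)
  cfg <- train_config(learning_rate = 1e-3, epochs = 3,
                      image_size = c(96, 96),
                      augment = augment_config(0, 0, 0, 0), seed = 3)
  m2 <- train_stage2(m1, init_stage2_from_stage1(m1), pairs, grid, sel, cfg)
  expect_identical(m1$params, m1_params_before)        # frozen contract
  expect_length(m2$history$stage2_loss, 3)
  # highest + frozen scores + augmentation off: the same patches every epoch,
  # so exactly (epochs) draws land on (n_images) distinct cells
  hist <- m2$history$patch_histogram
  expect_identical(sum(hist), 3L * 6L)
  expect_true(all(hist %% 3L == 0L))  # each image hits one fixed cell per epoch
  expect_error(
    train_stage2(m1, init_stage2_from_stage1(m1), pairs, grid,
                 structure(list(strategy = "best", threshold = 0.5,
                                variant = "full_entropy", seed = 1L),
                           class = "selection_config"), cfg),
    "unknown strategy"
  )
})

test_that("training is reproducible from seed and config", {
  grid <- desk_grid()
  pairs <- synth_pairs(5, seed = 12)
  go <- function() {
    m <- build_model("tiny", c(24, 24), in_channels = 1, seed = 6)
    train_stage1(m, pairs, grid, desk_train_config(6, epochs = 2))
  }
  a <- go(); b <- go()
  expect_identical(a$params, b$params)
  expect_identical(a$history$stage1_loss, b$history$stage1_loss)
})
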