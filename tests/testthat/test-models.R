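# segmentation model contract, parameter and MAC accounting

test_that("forward contract: shaped, finite, deterministic, seeded init", {
  m <- build_model("tiny", c(64, 64), seed = 1)
  set.seed(7)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  pr <- predict_probs(m, x)
  expect_identical(dim(pr$probs), c(64L, 64L))
  expect_true(all(is.finite(pr$probs)))
  expect_true(all(pr$probs > 0 & pr$probs < 1))
  expect_lte(dim(pr$penultimate)[1], 64L)
  expect_identical(predict_probs(m, x)$probs, pr$probs)   # eval determinism

  m_b <- build_model("tiny", c(64, 64), seed = 1)
  expect_identical(m$params, m_b$params)                  # seeded init
  m_c <- build_model("tiny", c(64, 64), seed = 2)
  expect_false(identical(m$params, m_c$params))

  expect_error(build_model("vgg", c(64, 64)), "valid choices")
  expect_error(predict_probs(m, array(0, c(32, 32, 3))), "does not match")
})

test_that("heavy architectures honor the forward contract at small size", {
  set.seed(8)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  for (arch in c("fcn", "deeplabv3", "unet", "segnet")) {
    m <- build_model(arch, c(64, 64), seed = 1)
    pr <- predict_probs(m, x)
    expect_identical(dim(pr$probs), c(64L, 64L))
    expect_true(all(is.finite(pr$probs)))
  }
})

test_that("predict_probs matches the elementwise logistic oracle", {
  m <- build_model("tiny", c(16, 16), in_channels = 1, seed = 3)
  # zero final layer -> logits 0 -> probability exactly 0.5
  m0 <- m
  m0$params$head$wmat[] <- 0
  m0$params$head$b[] <- 0
  x <- array(runif(256), c(16, 16, 1))
  expect_equal(predict_probs(m0, x)$probs, matrix(0.5, 16, 16))
  # general logits: elementwise 1/(1+exp(-z)) and monotonicity
  pr <- predict_probs(m, x)
  expect_equal(pr$probs, 1 / (1 + exp(-pr$logits)), tolerance = 1e-15)
  z <- sort(as.vector(pr$logits))
  expect_true(all(diff(1 / (1 + exp(-z))) >= 0))
})

test_that("parameter counts: hand oracle, encoder, invariance, freezing", {
  # single 3x3 convolution 3 -> 4 with bias: 3*4*9 + 4 = 112
  g <- list(list(name = "in", op = "input", input = character()),
            patchrefine:::conv_node("c", "in", 3L, 3L, 4L))
  m1conv <- structure(list(architecture_id = "tiny", encoder = "tiny",
                           input_size = c(8L, 8L), in_channels = 3L, graph = g,
                           penultimate = "c", output = "c", params = NULL,
                           frozen = FALSE), class = "seg_model")
  expect_identical(attr(count_params(m1conv), "total"), 112L)

  # fully convolutional: identical counts at different input sizes
  d1 <- build_model("deeplabv3", c(768, 768), weights = FALSE)
  d2 <- build_model("deeplabv3", c(192, 192), weights = FALSE)
  expect_identical(attr(count_params(d1), "total"), attr(count_params(d2), "total"))

  # freezing zeroes the trainable count but not the total
  mt <- build_model("tiny", c(24, 24), weights = FALSE)
  total <- attr(count_params(mt), "total")
  mt$frozen <- TRUE
  expect_identical(as.integer(count_params(mt)), 0L)
  expect_identical(attr(count_params(mt), "total"), total)
})

test_that("weight shapes transfer across same-architecture builds", {
  a <- build_model("tiny", c(24, 24), seed = 1)
  b <- build_model("tiny", c(24, 24), seed = 99)
  expect_identical(names(a$params), names(b$params))
  for (nm in names(a$params)) {
    for (fld in names(a$params[[nm]])) {
      expect_identical(dim(a$params[[nm]][[fld]]), dim(b$params[[nm]][[fld]]))
      expect_identical(length(a$params[[nm]][[fld]]), length(b$params[[nm]][[fld]]))
    }
  }
})

test_that("MAC counts: hand oracle and stage parity", {
  # 3x3 conv, 1 -> 1 channel, 8x8, stride 1, same padding: 9 * 64 MACs
  g <- list(list(name = "in", op = "input", input = character()),
            patchrefine:::conv_node("c", "in", 3L, 1L, 1L))
  m <- structure(list(architecture_id = "tiny", encoder = "tiny",
                      input_size = c(8L, 8L), in_channels = 1L, graph = g,
                      penultimate = "c", output = "c", params = NULL,
                      frozen = FALSE), class = "seg_model")
  expect_identical(count_flops(m, c(8, 8)), 576)

  # Stage-1 input (image/f) and Stage-2 input (one patch) cost the same for
  # square grids
  mt <- build_model("tiny", c(192, 192), weights = FALSE)
  g16 <- make_grid(768, 768, 16)
  expect_identical(count_flops(mt, c(192, 192)),
                   count_flops(mt, c(g16$patch_h, g16$patch_w)))
})

test_that("op table covers the architectures", {
  tab <- op_count_table(c("tiny", "segnet"), sizes = c(48L, 96L))
  expect_identical(tab$architecture, c("tiny", "segnet"))
  expect_true(all(tab$params > 0))
  expect_true(all(tab$macs_96x96 > tab$macs_48x48))
})
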