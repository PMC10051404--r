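# Shared fixtures.  All data is generated in code; heavyweight artifacts
# (trained model replicates used by the acceptance ablations) are memoized
# in `fixture_env` so several tests can share one computation.

fixture_env <- new.env(parent = emptyenv())

memo <- function(key, fn) {
  if (is.null(fixture_env[[key]])) fixture_env[[key]] <- fn()
  fixture_env[[key]]
}

# deterministic random probability map
rand_probs <- function(h, w, seed = 1) {
  set.seed(seed)
  matrix(runif(h * w), h, w)
}

# small in-memory synthetic dataset (list of image/mask pairs)
synth_pairs <- function(n, seed = 0, first_index = 1) {
  cfg <- synthetic_config(seed = seed)
  lapply(generate_dataset(cfg, n, first_index = first_index),
         function(p) list(image = p$image, mask = p$mask))
}

# desk-scale training configuration: the tiny architecture trained from
# scratch uses a larger Adam step (1e-3) than the reference recipe's 1e-4
# (which targets ImageNet-pretrained ResNet-50 backbones) and per-image
# updates (batch 1), since a 20-image dataset otherwise yields too few
# optimizer steps to converge
desk_train_config <- function(seed, epochs = 20) {
  train_config(learning_rate = 1e-3, epochs = epochs, batch_size = 1,
               image_size = c(96, 96), seed = seed)
}

desk_grid <- function() make_grid(96, 96, 16)

# one full desk-scale replicate: Stage 1, then Stage 2 under three
# configurations (full-featured / no fine-tune / no context), evaluated at
# thresholds 0 and 1 on a held-out split.  Used by the acceptance ablation
# criteria and reused by training-property tests.
train_replicate <- function(seed, n_train = 20, n_test = 8) {
  memo(sprintf("replicate_%d", seed), function() {
    grid <- desk_grid()
    train <- synth_pairs(n_train, seed = seed)
    test <- synth_pairs(n_test, seed = seed, first_index = n_train + 1)
    tc <- desk_train_config(seed)
    m1 <- build_model("tiny", c(24, 24), in_channels = 1, seed = seed)
    m1 <- train_stage1(m1, train, grid, tc)
    sel <- selection_config("weighted", threshold = 0.25, seed = seed)
    m2_full <- train_stage2(m1, init_stage2_from_stage1(m1), train, grid, sel,
                            tc, context = TRUE)
    m2_noft <- train_stage2(
      m1, build_model("tiny", c(24, 24), in_channels = 1, seed = seed + 1000L),
      train, grid, sel, tc, context = TRUE
    )
    m2_noctx <- train_stage2(m1, init_stage2_from_stage1(m1), train, grid, sel,
                             tc, context = FALSE)
    ev <- function(m2, context, threshold) {
      evaluate_pipeline(m1, m2, test, grid,
                        selection_config(threshold = threshold),
                        context = context)$mean_dice
    }
    list(
      m1 = m1, m2_full = m2_full, grid = grid, test = test,
      dice_full_t0 = ev(m2_full, TRUE, 0),
      dice_full_t1 = ev(m2_full, TRUE, 1),
      dice_noft_t0 = ev(m2_noft, TRUE, 0),
      dice_noctx_t0 = ev(m2_noctx, FALSE, 0)
    )
  })
}

acceptance_seeds <- 1:10
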