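# Training recipe: focal loss, paired geometric/photometric augmentation,
# Adam, Stage-1 training on downscaled images, and Stage-2 training on one
# uncertainty-sampled full-resolution patch per image per epoch, optionally
# initialized from Stage 1 and fused with its context.

#' Training configuration
#'
#' Defaults follow the standard recipe: Adam with learning rate `1e-4`,
#' 20 epochs, focal loss with `gamma = 2` and no class weighting
#' (`alpha = 1`).  `image_size` defaults to 768 x 768 and is reduced for
#' desk-scale runs.
#'
#' @param learning_rate Adam step size (> 0).
#' @param epochs number of passes over the training split (>= 1).
#' @param batch_size gradients are averaged over this many samples per
#'   optimizer step.
#' @param focal_gamma focusing exponent (>= 0; 0 recovers plain
#'   cross-entropy).
#' @param focal_alpha foreground class weight in `(0, 1]`; 1 means
#'   unweighted.
#' @param image_size `c(h, w)` images are resized to before the pipeline's
#'   own downscaling.
#' @param augment an [augment_config()].
#' @param seed seed governing all training randomness.
#' @export
train_config <- function(learning_rate = 1e-4, epochs = 20L, batch_size = 4L,
                         focal_gamma = 2, focal_alpha = 1,
                         image_size = c(768L, 768L),
                         augment = augment_config(), seed = 0L) {
  stopifnot(learning_rate >= 0, epochs >= 1, batch_size >= 1,
            focal_gamma >= 0, focal_alpha > 0, focal_alpha <= 1)
  structure(list(
    learning_rate = learning_rate, epochs = as.integer(epochs),
    batch_size = as.integer(batch_size), focal_gamma = focal_gamma,
    focal_alpha = focal_alpha, image_size = as.integer(image_size),
    augment = augment, seed = as.integer(seed)
  ), class = "train_config")
}

#' Augmentation configuration
#'
#' Horizontal flip, brightness/contrast jitter by a factor drawn uniformly
#' from `[1 - j, 1 + j]`, and a random translation of up to
#' `translate_frac` of the image size realized as an upscale followed by a
#' crop.  Geometric transforms are applied identically to image and mask;
#' photometric jitter touches only the image.  Setting every field to 0
#' makes the augmentation the identity.
#'
#' @param hflip_prob probability of a horizontal flip.
#' @param jitter_brightness,jitter_contrast jitter amplitudes in `[0, 1]`.
#' @param translate_frac translation amplitude in `[0, 1]`.
#' @export
augment_config <- function(hflip_prob = 0.5, jitter_brightness = 0.1,
                           jitter_contrast = 0.1, translate_frac = 0.1) {
  vals <- c(hflip_prob, jitter_brightness, jitter_contrast, translate_frac)
  stopifnot(all(vals >= 0), all(vals <= 1))
  structure(list(
    hflip_prob = hflip_prob, jitter_brightness = jitter_brightness,
    jitter_contrast = jitter_contrast, translate_frac = translate_frac
  ), class = "augment_config")
}

#' Focal loss
#'
#' Mean over pixels of `-alpha_t (1 - p_t)^gamma log(p_t)` with
#' `p_t = p` where `y = 1` and `1 - p` where `y = 0`, and
#' `alpha_t = alpha` / `1 - alpha` respectively when `alpha < 1` (1 when
#' unweighted).  The log is natural.  Probabilities are clamped to
#' `[1e-7, 1 - 1e-7]` so exact 0/1 inputs stay finite.
#'
#' @param p predicted foreground probabilities (any shape).
#' @param y binary ground truth, same shape.
#' @param gamma focusing exponent.
#' @param alpha foreground weight in `(0, 1]`.
#' @return a nonnegative scalar.
#' @export
focal_loss <- function(p, y, gamma = 2, alpha = 1) {
  if (!all(dim(p) == dim(y)) && length(p) != length(y)) stop("shape mismatch")
  check_mask(y)
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  p_t <- ifelse(y == 1, p, 1 - p)
  a_t <- if (alpha < 1) ifelse(y == 1, alpha, 1 - alpha) else 1
  mean(-a_t * (1 - p_t)^gamma * log(p_t))
}

# gradient of the mean focal loss w.r.t. the logits z (p = sigmoid(z));
# d p_t / d z = s * p (1 - p) with s = +1 for y = 1 and -1 for y = 0
focal_loss_grad_logits <- function(p, y, gamma, alpha) {
  pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  p_t <- ifelse(y == 1, pc, 1 - pc)
  a_t <- if (alpha < 1) ifelse(y == 1, alpha, 1 - alpha) else 1
  dl_dpt <- a_t * (gamma * (1 - p_t)^(gamma - 1) * log(p_t) - (1 - p_t)^gamma / p_t)
  s <- ifelse(y == 1, 1, -1)
  g <- dl_dpt * s * pc * (1 - pc) / length(p)
  dim(g) <- dim(p)
  g
}

#' Paired image/mask augmentation
#'
#' Draws from R's current RNG stream (reproducible under `set.seed()`).
#'
#' @param x `H x W x C` image in `[0, 1]`.
#' @param y `H x W` binary mask.
#' @param cfg an [augment_config()].
#' @return list with transformed `image` and `mask` of unchanged sizes; the
#'   mask stays binary and the image stays in `[0, 1]`.
#' @export
augment_pair <- function(x, y, cfg = augment_config()) {
  stopifnot(inherits(cfg, "augment_config"))
  d <- dim(x)
  if (length(d) == 2L) { dim(x) <- c(d, 1L); d <- dim(x) }
  if (cfg$hflip_prob > 0 && stats::runif(1) < cfg$hflip_prob) {
    x <- x[, d[2]:1, , drop = FALSE]
    y <- y[, d[2]:1, drop = FALSE]
  }
  if (cfg$jitter_brightness > 0) {
    f <- stats::runif(1, 1 - cfg$jitter_brightness, 1 + cfg$jitter_brightness)
    x <- pmin(pmax(x * f, 0), 1)
  }
  if (cfg$jitter_contrast > 0) {
    f <- stats::runif(1, 1 - cfg$jitter_contrast, 1 + cfg$jitter_contrast)
    x <- pmin(pmax((x - mean(x)) * f + mean(x), 0), 1)
  }
  if (cfg$translate_frac > 0) {
    zh <- d[1] + ceiling(cfg$translate_frac * d[1])
    zw <- d[2] + ceiling(cfg$translate_frac * d[2])
    xb <- resize_bilinear(x, zh, zw)
    yb <- resize_mask(y, zh, zw)
    oy <- sample.int(zh - d[1] + 1L, 1L) - 1L
    ox <- sample.int(zw - d[2] + 1L, 1L) - 1L
    x <- xb[(oy + 1):(oy + d[1]), (ox + 1):(ox + d[2]), , drop = FALSE]
    y <- yb[(oy + 1):(oy + d[1]), (ox + 1):(ox + d[2]), drop = FALSE]
  }
  list(image = x, mask = y)
}

## ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  state <- list(t = 0)
  state$m <- lapply(params, function(p) lapply(p, function(v) if (is.null(v)) NULL else v * 0))
  state$v <- state$m
  state
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    for (fld in names(grads[[nm]])) {
      g <- grads[[nm]][[fld]]
      if (is.null(g)) next
      m <- beta1 * state$m[[nm]][[fld]] + (1 - beta1) * g
      v <- beta2 * state$v[[nm]][[fld]] + (1 - beta2) * g^2
      state$m[[nm]][[fld]] <- m
      state$v[[nm]][[fld]] <- v
      params[[nm]][[fld]] <- params[[nm]][[fld]] - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    }
  }
  list(params = params, state = state)
}

# one forward/backward on a single sample; returns loss and param grads
train_step_grads <- function(model, x, y, cfg, penultimate_add = NULL) {
  fwd <- graph_forward(model, x, penultimate_add = penultimate_add, train = TRUE)
  logits <- fwd$out[, , 1L]
  p <- 1 / (1 + exp(-logits))
  loss <- focal_loss(p, y, cfg$focal_gamma, cfg$focal_alpha)
  dlogits <- focal_loss_grad_logits(p, y, cfg$focal_gamma, cfg$focal_alpha)
  d_out <- array(dlogits, dim = c(dim(y), 1L))
  grads <- graph_backward(model, fwd, d_out)
  list(loss = loss, grads = grads)
}

accumulate_grads <- function(acc, grads) {
  if (is.null(acc)) return(grads)
  for (nm in names(grads)) {
    for (fld in names(grads[[nm]])) {
      if (is.null(grads[[nm]][[fld]])) next
      acc[[nm]][[fld]] <- acc[[nm]][[fld]] + grads[[nm]][[fld]]
    }
  }
  acc
}

scale_grads <- function(grads, k) {
  lapply(grads, function(g) lapply(g, function(v) if (is.null(v)) NULL else v * k))
}

#' Train the Stage-1 (coarse) model
#'
#' Each image/mask pair is augmented, downscaled to the model's input size
#' (bilinear for the image, nearest for the mask), and the model is trained
#' with focal loss and Adam.  Deterministic given `cfg$seed`.
#'
#' @param model a trainable [build_model()] object (input size = the
#'   downscaled image size).
#' @param manifest manifest data.frame or list of in-memory pairs
#'   (train split used for data.frames).
#' @param grid patch grid (fixes the downscale factor: the Stage-1 input is
#'   one patch's size for square grids).
#' @param cfg a [train_config()].
#' @return the trained model; per-epoch mean loss in
#'   `model$history$stage1_loss`.
#' @export
train_stage1 <- function(model, manifest, grid, cfg = train_config()) {
  pairs <- load_all_pairs(manifest, "train")
  if (length(pairs) == 0L) stop("empty training manifest")
  with_local_seed(cfg$seed, function() {
    state <- adam_init(model$params)
    losses <- numeric(cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(length(pairs))
      ep_loss <- numeric(length(ord))
      acc <- NULL
      n_acc <- 0L
      for (k in seq_along(ord)) {
        pair <- pairs[[ord[k]]]
        aug <- augment_pair(pair$image, pair$mask, cfg$augment)
        xs <- downscale(aug$image, model$input_size[1], model$input_size[2])
        ys <- resize_mask(aug$mask, model$input_size[1], model$input_size[2])
        st <- train_step_grads(model, xs, ys, cfg)
        ep_loss[k] <- st$loss
        acc <- accumulate_grads(acc, st$grads)
        n_acc <- n_acc + 1L
        if (n_acc == cfg$batch_size || k == length(ord)) {
          upd <- adam_step(model$params, scale_grads(acc, 1 / n_acc), state,
                           cfg$learning_rate)
          model$params <- upd$params
          state <- upd$state
          acc <- NULL; n_acc <- 0L
        }
      }
      losses[ep] <- mean(ep_loss)
    }
    model$history$stage1_loss <- losses
    model
  })
}

#' Initialize the Stage-2 model from trained Stage 1
#'
#' Cross-stage transfer: returns a new model of identical architecture whose
#' every weight equals `m1`'s.  The copy is deep — later Stage-2 training
#' never mutates `m1`.
#'
#' @param m1 a trained [build_model()] object.
#' @return a fresh `seg_model` with identical weights, unfrozen, history
#'   cleared.
#' @export
init_stage2_from_stage1 <- function(m1) {
  stopifnot(inherits(m1, "seg_model"), !is.null(m1$params))
  m2 <- m1
  m2$frozen <- FALSE
  m2$history <- list()
  m2
}

#' Train the Stage-2 (refinement) model
#'
#' Per epoch and per image: augment, run the frozen Stage-1 coarse pass
#' (downscale, predict, upscale), score every patch's uncertainty, sample
#' exactly one patch by the configured strategy, and train `m2` on the
#' full-resolution crop of that patch — optionally with Stage-1 context
#' added at the penultimate layer.  Scores are recomputed on the augmented
#' image each epoch.  `m1` is never modified.
#'
#' @param m1 trained, frozen Stage-1 model.
#' @param m2 Stage-2 model (fresh, or from [init_stage2_from_stage1()]).
#' @param manifest manifest data.frame or list of in-memory pairs.
#' @param grid patch grid; `m2$input_size` must equal the patch size.
#' @param sel a [selection_config()] (its `strategy` governs sampling).
#' @param cfg a [train_config()].
#' @param context enable cross-stage context fusion during training.
#' @return the trained `m2`; per-epoch mean loss in
#'   `m2$history$stage2_loss`, sampled-patch counts in
#'   `m2$history$patch_histogram`.
#' @export
train_stage2 <- function(m1, m2, manifest, grid, sel, cfg = train_config(),
                         context = FALSE) {
  stopifnot(inherits(sel, "selection_config"))
  pairs <- load_all_pairs(manifest, "train")
  if (length(pairs) == 0L) stop("empty training manifest")
  if (m2$input_size[1] != grid$patch_h || m2$input_size[2] != grid$patch_w) {
    stop("Stage-2 model input size must equal the patch size")
  }
  with_local_seed(cfg$seed + sel$seed, function() {
    state <- adam_init(m2$params)
    losses <- numeric(cfg$epochs)
    hist_counts <- matrix(0L, grid$grid_rows, grid$grid_cols)
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(length(pairs))
      ep_loss <- numeric(length(ord))
      acc <- NULL
      n_acc <- 0L
      for (k in seq_along(ord)) {
        pair <- pairs[[ord[k]]]
        aug <- augment_pair(pair$image, pair$mask, cfg$augment)
        xs <- downscale(aug$image, m1$input_size[1], m1$input_size[2])
        s1 <- predict_probs(m1, xs)
        coarse <- upscale(s1$probs, grid$image_h, grid$image_w)
        scores <- patch_scores(coarse, grid, sel$variant)
        idx <- sample_training_patch(scores, sel)
        hist_counts[idx[1] + 1L, idx[2] + 1L] <- hist_counts[idx[1] + 1L, idx[2] + 1L] + 1L
        xp <- crop_patch(aug$image, grid, idx)
        yp <- crop_patch(aug$mask, grid, idx)
        ctx <- if (context) {
          context_features(s1$penultimate, grid, idx,
                           target_shape = stage2_penultimate_shape(m2))
        } else NULL
        st <- train_step_grads(m2, xp, yp, cfg, penultimate_add = ctx)
        ep_loss[k] <- st$loss
        acc <- accumulate_grads(acc, st$grads)
        n_acc <- n_acc + 1L
        if (n_acc == cfg$batch_size || k == length(ord)) {
          upd <- adam_step(m2$params, scale_grads(acc, 1 / n_acc), state,
                           cfg$learning_rate)
          m2$params <- upd$params
          state <- upd$state
          acc <- NULL; n_acc <- 0L
        }
      }
      losses[ep] <- mean(ep_loss)
    }
    m2$history$stage2_loss <- losses
    m2$history$patch_histogram <- hist_counts
    m2
  })
}

# materialize a manifest's pairs in memory
load_all_pairs <- function(manifest, split) {
  thunks <- manifest_pairs(manifest, split)
  lapply(thunks, function(f) {
    p <- f()
    d <- dim(p$image)
    if (length(d) == 2L) dim(p$image) <- c(d, 1L)
    p
  })
}
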