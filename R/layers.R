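# A small computational-graph engine for fully convolutional segmentation
# networks: plain R arrays (H x W x C), im2col convolutions executed as BLAS
# matrix products, separable bilinear resizing, and manual reverse-mode
# differentiation for the ops the trainable architectures use.
#
# A graph is an ordered list of nodes (topological order); each node is a
# list with at least `name`, `op`, and `input` (character vector of upstream
# node names).  Supported ops:
#   input                      network input
#   conv   (k, cin, cout, stride, dilation, bias)
#   bn     (c)                 affine-only channel scale/shift (gamma, beta)
#   relu
#   maxpool(k, stride)         forward-only
#   upsample(scale | to)       bilinear; `to = "input"` resizes to the
#                              network input size, `to = <node>` to that
#                              node's spatial size
#   add                        elementwise sum of inputs (same shape)
#   concat                     channel concatenation            forward-only
#   globalpool                 global average pool to 1 x 1     forward-only

conv_node <- function(name, input, k, cin, cout, stride = 1L, dilation = 1L,
                      bias = TRUE) {
  list(name = name, op = "conv", input = input, k = as.integer(k),
       cin = as.integer(cin), cout = as.integer(cout),
       stride = as.integer(stride), dilation = as.integer(dilation),
       bias = bias)
}
bn_node <- function(name, input, c) list(name = name, op = "bn", input = input, c = as.integer(c))
relu_node <- function(name, input) list(name = name, op = "relu", input = input)
maxpool_node <- function(name, input, k = 3L, stride = 2L) {
  list(name = name, op = "maxpool", input = input, k = as.integer(k), stride = as.integer(stride))
}
upsample_node <- function(name, input, scale = NULL, to = NULL) {
  list(name = name, op = "upsample", input = input, scale = scale, to = to)
}
add_node <- function(name, inputs) list(name = name, op = "add", input = inputs)
concat_node <- function(name, inputs) list(name = name, op = "concat", input = inputs)
globalpool_node <- function(name, input) list(name = name, op = "globalpool", input = input)

# output spatial size of a strided/padded op; pad = dilation * (k %/% 2)
# (torch-style "same" padding for odd k), giving out = ceiling(h / stride)
conv_out_dim <- function(h, k, stride, dilation = 1L) {
  pad <- dilation * (k %/% 2L)
  (h + 2L * pad - dilation * (k - 1L) - 1L) %/% stride + 1L
}

## ---- im2col ----------------------------------------------------------------

engine_cache <- new.env(parent = emptyenv())

# linear indices into the zero-padded input such that
# Xp[idx] has dim (oh*ow) x (k*k*cin), column order (dy, dx, ci) matching
# matrix(W, k*k*cin, cout) for W of dim (k, k, cin, cout)
im2col_indices <- function(h, w, cin, k, stride, dilation) {
  key <- paste("i2c", h, w, cin, k, stride, dilation, sep = ":")
  got <- engine_cache[[key]]
  if (!is.null(got)) return(got)
  pad <- dilation * (k %/% 2L)
  hp <- h + 2L * pad; wp <- w + 2L * pad
  oh <- conv_out_dim(h, k, stride, dilation)
  ow <- conv_out_dim(w, k, stride, dilation)
  oy <- rep(seq_len(oh) - 1L, times = ow) * stride      # output rows, col-major
  ox <- rep(seq_len(ow) - 1L, each = oh) * stride
  dy <- rep(seq_len(k) - 1L, times = k) * dilation      # kernel offsets, dy fastest
  dx <- rep(seq_len(k) - 1L, each = k) * dilation
  base <- outer(oy, dy, `+`) + 1L                        # (oh*ow) x k^2 rows
  basec <- outer(ox, dx, `+`)                            # 0-based cols
  idx_plane <- base + basec * hp                         # (oh*ow) x k^2 within one channel
  idx <- matrix(0L, nrow = oh * ow, ncol = k * k * cin)
  for (ci in seq_len(cin)) {
    idx[, ((ci - 1L) * k * k + 1L):(ci * k * k)] <- idx_plane + (ci - 1L) * hp * wp
  }
  out <- list(idx = idx, pad = pad, oh = oh, ow = ow, hp = hp, wp = wp)
  engine_cache[[key]] <- out
  out
}

pad_input <- function(x, pad, value = 0) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(value, dim = c(d[1] + 2L * pad, d[2] + 2L * pad, d[3]))
  xp[(pad + 1L):(pad + d[1]), (pad + 1L):(pad + d[2]), ] <- x
  xp
}

conv_forward <- function(x, wmat, b, node, cache = FALSE) {
  d <- dim(x)
  ii <- im2col_indices(d[1], d[2], node$cin, node$k, node$stride, node$dilation)
  xp <- pad_input(x, ii$pad)
  xcol <- xp
  dim(xcol) <- NULL
  xcol <- matrix(xcol[ii$idx], nrow = nrow(ii$idx))
  y <- xcol %*% wmat
  if (!is.null(b)) y <- sweep(y, 2L, b, `+`)
  dim(y) <- c(ii$oh, ii$ow, node$cout)
  if (cache) attr(y, "xcol") <- xcol
  y
}

conv_backward <- function(dy, xcol, wmat, node, in_dim) {
  ii <- im2col_indices(in_dim[1], in_dim[2], node$cin, node$k, node$stride, node$dilation)
  dym <- dy
  dim(dym) <- c(nrow(ii$idx), node$cout)
  dw <- crossprod(xcol, dym)                    # (k*k*cin) x cout
  db <- if (node$bias) colSums(dym) else NULL
  dxcol <- tcrossprod(dym, wmat)                # (oh*ow) x (k*k*cin)
  dxp <- numeric(ii$hp * ii$wp * node$cin)
  # for a fixed kernel offset the output->input map is injective, so
  # accumulate column by column
  for (cc in seq_len(ncol(ii$idx))) {
    tgt <- ii$idx[, cc]
    dxp[tgt] <- dxp[tgt] + dxcol[, cc]
  }
  dim(dxp) <- c(ii$hp, ii$wp, node$cin)
  pad <- ii$pad
  dx <- if (pad > 0L) {
    dxp[(pad + 1L):(pad + in_dim[1]), (pad + 1L):(pad + in_dim[2]), , drop = FALSE]
  } else dxp
  list(dx = dx, dw = dw, db = db)
}

maxpool_forward <- function(x, node) {
  d <- dim(x)
  ii <- im2col_indices(d[1], d[2], 1L, node$k, node$stride, 1L)
  out <- array(0, dim = c(ii$oh, ii$ow, d[3]))
  for (ch in seq_len(d[3])) {
    xp <- matrix(-Inf, nrow = ii$hp, ncol = ii$wp)
    xp[(ii$pad + 1L):(ii$pad + d[1]), (ii$pad + 1L):(ii$pad + d[2])] <- x[, , ch]
    xv <- as.vector(xp)
    m <- xv[ii$idx[, 1L]]
    for (cc in 2:ncol(ii$idx)) m <- pmax(m, xv[ii$idx[, cc]])
    out[, , ch] <- m
  }
  out
}

upsample_target <- function(node, acts, input_dim) {
  if (!is.null(node$to)) {
    if (identical(node$to, "input")) return(input_dim[1:2])
    return(dim(acts[[node$to]])[1:2])
  }
  d <- dim(acts[[node$input[1]]])
  c(d[1] * node$scale, d[2] * node$scale)
}

## ---- graph execution -------------------------------------------------------

# forward pass through a model graph.
#   penultimate_add: optional tensor added to the penultimate node's output
#     before it is consumed downstream (cross-stage context fusion).
#   train = TRUE caches per-conv column matrices for backprop.
graph_forward <- function(model, x, penultimate_add = NULL, train = FALSE) {
  acts <- list()
  caches <- if (train) list() else NULL
  input_dim <- dim(x)
  fetch <- function(name) {
    a <- acts[[name]]
    if (!is.null(penultimate_add) && identical(name, model$penultimate)) {
      a <- a + penultimate_add
    }
    a
  }
  for (node in model$graph) {
    y <- switch(node$op,
      input = x,
      conv = {
        p <- model$params[[node$name]]
        xin <- fetch(node$input)
        yy <- conv_forward(xin, p$wmat, p$b, node, cache = train)
        if (train) {
          caches[[node$name]] <- list(xcol = attr(yy, "xcol"), in_dim = dim(xin))
          attr(yy, "xcol") <- NULL
        }
        yy
      },
      bn = {
        p <- model$params[[node$name]]
        xin <- fetch(node$input)
        sweep(sweep(xin, 3L, p$gamma, `*`), 3L, p$beta, `+`)
      },
      relu = pmax(fetch(node$input), 0),
      maxpool = maxpool_forward(fetch(node$input), node),
      upsample = {
        tgt <- upsample_target(node, acts, input_dim)
        resize_apply(fetch(node$input), tgt[1], tgt[2], "bilinear")
      },
      add = Reduce(`+`, lapply(node$input, fetch)),
      concat = {
        parts <- lapply(node$input, fetch)
        d1 <- dim(parts[[1]])
        array(unlist(parts), dim = c(d1[1], d1[2], sum(vapply(parts, function(p) dim(p)[3], 0))))
      },
      globalpool = {
        xin <- fetch(node$input)
        array(apply(xin, 3L, mean), dim = c(1L, 1L, dim(xin)[3]))
      },
      stop(sprintf("unknown op '%s'", node$op))
    )
    dim_ok <- !is.null(dim(y))
    stopifnot(dim_ok)
    acts[[node$name]] <- y
  }
  pen <- acts[[model$penultimate]]
  if (!is.null(penultimate_add)) pen <- pen + penultimate_add
  list(out = acts[[model$output]], penultimate = pen, acts = acts, caches = caches)
}

# reverse-mode pass; d_out is the gradient of the scalar loss w.r.t. the
# output node.  Returns per-node parameter gradients.  Ops without a backward
# rule (maxpool, concat, globalpool) raise an error: they only occur in the
# forward-only heavy backbones.
graph_backward <- function(model, fwd, d_out) {
  grads <- list()
  dacts <- list()
  dacts[[model$output]] <- d_out
  input_dim <- dim(fwd$acts[[model$graph[[1]]$name]])
  for (node in rev(model$graph)) {
    dy <- dacts[[node$name]]
    if (is.null(dy)) next
    bump <- function(name, dx) {
      dacts[[name]] <<- if (is.null(dacts[[name]])) dx else dacts[[name]] + dx
    }
    switch(node$op,
      input = NULL,
      conv = {
        p <- model$params[[node$name]]
        cache <- fwd$caches[[node$name]]
        bk <- conv_backward(dy, cache$xcol, p$wmat, node, cache$in_dim)
        grads[[node$name]] <- list(wmat = bk$dw, b = bk$db)
        bump(node$input, bk$dx)
      },
      bn = {
        p <- model$params[[node$name]]
        xin <- fwd$acts[[node$input]]
        grads[[node$name]] <- list(
          gamma = as.vector(apply(dy * xin, 3L, sum)),
          beta = as.vector(apply(dy, 3L, sum))
        )
        bump(node$input, sweep(dy, 3L, p$gamma, `*`))
      },
      relu = bump(node$input, dy * (fwd$acts[[node$name]] > 0)),
      upsample = {
        src <- fwd$acts[[node$input]]
        d <- dim(src)
        rr <- interp_matrix_cached(d[1], dim(dy)[1], "bilinear")
        rc <- interp_matrix_cached(d[2], dim(dy)[2], "bilinear")
        dx <- array(0, dim = d)
        for (ch in seq_len(d[3])) dx[, , ch] <- crossprod(rr, dy[, , ch]) %*% rc
        bump(node$input, dx)
      },
      add = for (nm in node$input) bump(nm, dy),
      stop(sprintf("op '%s' has no backward rule (forward-only backbone layer)", node$op))
    )
  }
  grads
}
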