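# Concrete segmentation architectures and op accounting.
#
# Every model satisfies one contract: forward(image H x W x C) returns
# 1-channel logits at the input's spatial size plus the penultimate
# activation (the input of the final 1x1 prediction convolution).  The
# "tiny" architecture (~5k parameters) is the trainable desk-scale network
# used throughout the tests; fcn / deeplabv3 / unet / segnet are
# ResNet-50-backed reference designs used for parameter/FLOP accounting and
# forward-contract checks.
#
# FLOPs are counted as multiply-accumulate operations (MACs) of one forward
# pass: k^2 * cin * cout * out_h * out_w per convolution, in * out per dense
# layer; normalization, pooling, resizing and activations are excluded.
# Under this convention the cost of a fully convolutional network scales
# with input area, i.e. doubling each side quadruples the count.

architecture_ids <- c("tiny", "fcn", "deeplabv3", "unet", "segnet")

## ---- graph builders --------------------------------------------------------

tiny_graph <- function(in_channels = 3L, width = 8L) {
  w <- as.integer(width)
  g <- list(
    list(name = "in", op = "input", input = character()),
    conv_node("c1", "in", 3L, in_channels, w), relu_node("r1", "c1"),
    conv_node("c2", "r1", 3L, w, 2L * w, stride = 2L), relu_node("r2", "c2"),
    conv_node("c3", "r2", 3L, 2L * w, 2L * w), relu_node("r3", "c3"),
    upsample_node("up", "r3", to = "input"),
    conv_node("c4", "up", 3L, 2L * w, w), relu_node("r4", "c4"),
    conv_node("head", "r4", 1L, w, 1L)
  )
  list(graph = g, penultimate = "r4", output = "head")
}

# conv -> bn -> relu triple; returns nodes and the output name
cbr <- function(prefix, input, k, cin, cout, stride = 1L, dilation = 1L) {
  list(
    nodes = list(
      conv_node(paste0(prefix, "_c"), input, k, cin, cout, stride, dilation, bias = FALSE),
      bn_node(paste0(prefix, "_bn"), paste0(prefix, "_c"), cout),
      relu_node(paste0(prefix, "_r"), paste0(prefix, "_bn"))
    ),
    out = paste0(prefix, "_r")
  )
}

# ResNet-50 bottleneck stage; returns nodes, output name, and out channels
resnet_stage <- function(prefix, input, inplanes, planes, blocks, stride) {
  nodes <- list()
  outp <- 4L * planes
  src <- input
  for (b in seq_len(blocks)) {
    p <- sprintf("%s_b%d", prefix, b)
    s <- if (b == 1L) stride else 1L
    cin <- if (b == 1L) inplanes else outp
    b1 <- cbr(paste0(p, "_1"), src, 1L, cin, planes)
    b2 <- cbr(paste0(p, "_2"), b1$out, 3L, planes, planes, stride = s)
    nodes <- c(nodes, b1$nodes, b2$nodes,
      list(
        conv_node(paste0(p, "_3c"), b2$out, 1L, planes, outp, bias = FALSE),
        bn_node(paste0(p, "_3bn"), paste0(p, "_3c"), outp)
      ))
    if (b == 1L) {
      nodes <- c(nodes, list(
        conv_node(paste0(p, "_dsc"), src, 1L, cin, outp, stride = s, bias = FALSE),
        bn_node(paste0(p, "_dsbn"), paste0(p, "_dsc"), outp),
        add_node(paste0(p, "_add"), c(paste0(p, "_3bn"), paste0(p, "_dsbn")))
      ))
    } else {
      nodes <- c(nodes, list(add_node(paste0(p, "_add"), c(paste0(p, "_3bn"), src))))
    }
    nodes <- c(nodes, list(relu_node(paste0(p, "_r"), paste0(p, "_add"))))
    src <- paste0(p, "_r")
  }
  list(nodes = nodes, out = src, channels = outp)
}

# ResNet-50 encoder (classification head removed): 23,508,032 parameters.
# Returns the node list plus the names/channels of the skip stages.
resnet50_graph <- function(in_channels = 3L) {
  stem <- cbr("stem", "in", 7L, in_channels, 64L, stride = 2L)
  nodes <- c(list(list(name = "in", op = "input", input = character())),
             stem$nodes,
             list(maxpool_node("pool", stem$out)))
  l1 <- resnet_stage("l1", "pool", 64L, 64L, 3L, 1L)
  l2 <- resnet_stage("l2", l1$out, 256L, 128L, 4L, 2L)
  l3 <- resnet_stage("l3", l2$out, 512L, 256L, 6L, 2L)
  l4 <- resnet_stage("l4", l3$out, 1024L, 512L, 3L, 2L)
  list(
    nodes = c(nodes, l1$nodes, l2$nodes, l3$nodes, l4$nodes),
    skips = list(stem = list(out = stem$out, channels = 64L),
                 l1 = list(out = l1$out, channels = 256L),
                 l2 = list(out = l2$out, channels = 512L),
                 l3 = list(out = l3$out, channels = 1024L),
                 l4 = list(out = l4$out, channels = 2048L))
  )
}

# torchvision-style auxiliary head on the stride-16 stage (included so that
# fcn/deeplabv3 totals land at the reference magnitudes); its output is not
# part of the inference graph contract, so it is attached as a dangling
# branch feeding nothing.
aux_head_nodes <- function(input) {
  h <- cbr("aux", input, 3L, 1024L, 256L)
  c(h$nodes, list(conv_node("aux_head", h$out, 1L, 256L, 1L)))
}

fcn_graph <- function(in_channels = 3L) {
  bb <- resnet50_graph(in_channels)
  h <- cbr("fhead", bb$skips$l4$out, 3L, 2048L, 512L)
  nodes <- c(bb$nodes, h$nodes, list(
    conv_node("fcls", h$out, 1L, 512L, 1L),
    upsample_node("fup", "fcls", to = "input")
  ), aux_head_nodes(bb$skips$l3$out))
  list(graph = nodes, penultimate = h$out, output = "fup")
}

deeplabv3_graph <- function(in_channels = 3L) {
  bb <- resnet50_graph(in_channels)
  x <- bb$skips$l4$out
  a0 <- cbr("aspp0", x, 1L, 2048L, 256L)
  a1 <- cbr("aspp1", x, 3L, 2048L, 256L, dilation = 12L)
  a2 <- cbr("aspp2", x, 3L, 2048L, 256L, dilation = 24L)
  a3 <- cbr("aspp3", x, 3L, 2048L, 256L, dilation = 36L)
  ap <- cbr("asppp", "gp", 1L, 2048L, 256L)
  proj <- cbr("proj", "cat", 1L, 5L * 256L, 256L)
  hd <- cbr("dhead", proj$out, 3L, 256L, 256L)
  nodes <- c(bb$nodes, a0$nodes, a1$nodes, a2$nodes, a3$nodes,
    list(globalpool_node("gp", x)), ap$nodes,
    list(upsample_node("gpup", ap$out, to = a0$out),
         concat_node("cat", c(a0$out, a1$out, a2$out, a3$out, "gpup"))),
    proj$nodes, hd$nodes,
    list(conv_node("dcls", hd$out, 1L, 256L, 1L),
         upsample_node("dup", "dcls", to = "input")),
    aux_head_nodes(bb$skips$l3$out))
  list(graph = nodes, penultimate = hd$out, output = "dup")
}

# U-Net-style decoder over the ResNet-50 encoder: upsample, concatenate the
# matching skip activation, two 3x3 conv-bn-relu blocks per level.
unet_graph <- function(in_channels = 3L) {
  bb <- resnet50_graph(in_channels)
  widths <- c(512L, 256L, 128L, 64L)
  skips <- list(bb$skips$l3, bb$skips$l2, bb$skips$l1, bb$skips$stem)
  nodes <- bb$nodes
  src <- bb$skips$l4$out
  cin <- 2048L
  for (lev in seq_along(widths)) {
    p <- sprintf("dec%d", lev)
    nodes <- c(nodes, list(
      upsample_node(paste0(p, "_up"), src, to = skips[[lev]]$out),
      concat_node(paste0(p, "_cat"), c(paste0(p, "_up"), skips[[lev]]$out))
    ))
    b1 <- cbr(paste0(p, "_1"), paste0(p, "_cat"), 3L, cin + skips[[lev]]$channels, widths[lev])
    b2 <- cbr(paste0(p, "_2"), b1$out, 3L, widths[lev], widths[lev])
    nodes <- c(nodes, b1$nodes, b2$nodes)
    src <- b2$out
    cin <- widths[lev]
  }
  fin <- cbr("ufin", "uup", 3L, 64L, 32L)
  nodes <- c(nodes, list(upsample_node("uup", src, to = "input")), fin$nodes,
             list(conv_node("ucls", fin$out, 1L, 32L, 1L)))
  list(graph = nodes, penultimate = fin$out, output = "ucls")
}

# SegNet-style decoder: successive upsample + conv-bn-relu stages mirroring
# the encoder's downsampling, no skip connections.
segnet_graph <- function(in_channels = 3L) {
  bb <- resnet50_graph(in_channels)
  widths <- c(1024L, 512L, 256L, 128L, 64L)
  nodes <- bb$nodes
  src <- bb$skips$l4$out
  cin <- 2048L
  for (lev in seq_along(widths)) {
    p <- sprintf("sdec%d", lev)
    nodes <- c(nodes, list(upsample_node(paste0(p, "_up"), src, scale = 2L)))
    b <- cbr(paste0(p, "_1"), paste0(p, "_up"), 3L, cin, widths[lev])
    nodes <- c(nodes, b$nodes)
    src <- b$out
    cin <- widths[lev]
  }
  nodes <- c(nodes, list(upsample_node("sup", src, to = "input"),
                         conv_node("scls", "sup", 1L, 64L, 1L)))
  list(graph = nodes, penultimate = "sup", output = "scls")
}

## ---- model construction ----------------------------------------------------

# run fn with a private RNG stream, restoring the caller's state
with_local_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

init_params <- function(graph, seed) {
  with_local_seed(seed, function() {
    params <- list()
    for (node in graph) {
      if (node$op == "conv") {
        fan_in <- node$k^2 * node$cin
        params[[node$name]] <- list(
          wmat = matrix(stats::rnorm(fan_in * node$cout, sd = sqrt(2 / fan_in)),
                        nrow = fan_in, ncol = node$cout),
          b = if (node$bias) numeric(node$cout) else NULL
        )
      } else if (node$op == "bn") {
        params[[node$name]] <- list(gamma = rep(1, node$c), beta = numeric(node$c))
      }
    }
    params
  })
}

#' Build a segmentation model
#'
#' @param architecture_id one of `"tiny"`, `"fcn"`, `"deeplabv3"`, `"unet"`,
#'   `"segnet"`.  All but `tiny` use a ResNet-50 encoder; `tiny` is a ~5k
#'   parameter encoder-decoder intended for desk-scale training and tests.
#' @param input_size `c(h, w)` the model is intended to run at (models are
#'   fully convolutional; the size is recorded for pipeline validation and
#'   default FLOP accounting).
#' @param encoder `"tiny"` or `"resnet50"`; must match the architecture.
#' @param pretrained if `TRUE`, request ImageNet encoder weights.  This needs
#'   a network download and is unavailable offline; an error is raised.
#' @param in_channels input channels (1 or 3).
#' @param seed RNG seed for weight initialization; two builds with the same
#'   seed have identical weights.
#' @param weights if `FALSE`, build a shapes-only model: op accounting works
#'   but `predict_probs()` does not (used for fast parameter/FLOP audits of
#'   the heavy architectures).
#' @return an object of class `seg_model`.
#' @export
build_model <- function(architecture_id, input_size,
                        encoder = c("auto", "tiny", "resnet50"),
                        pretrained = FALSE, in_channels = 3L, seed = 0L,
                        weights = TRUE) {
  if (!architecture_id %in% architecture_ids) {
    stop(sprintf(
      "unknown architecture '%s'; valid choices: %s",
      architecture_id, paste(architecture_ids, collapse = ", ")
    ))
  }
  encoder <- match.arg(encoder)
  expected <- if (architecture_id == "tiny") "tiny" else "resnet50"
  if (encoder == "auto") encoder <- expected
  if (encoder != expected) {
    stop(sprintf(
      "architecture '%s' uses the '%s' encoder; valid encoders: tiny, resnet50",
      architecture_id, expected
    ))
  }
  if (pretrained) {
    stop("pretrained ImageNet encoder weights require a network download and are not bundled")
  }
  stopifnot(length(input_size) == 2L, all(input_size >= 1), in_channels %in% c(1L, 3L))
  spec <- switch(architecture_id,
    tiny = tiny_graph(in_channels),
    fcn = fcn_graph(in_channels),
    deeplabv3 = deeplabv3_graph(in_channels),
    unet = unet_graph(in_channels),
    segnet = segnet_graph(in_channels)
  )
  structure(list(
    architecture_id = architecture_id,
    encoder = encoder,
    input_size = as.integer(input_size),
    in_channels = as.integer(in_channels),
    graph = spec$graph,
    penultimate = spec$penultimate,
    output = spec$output,
    params = if (weights) init_params(spec$graph, seed) else NULL,
    seed = as.integer(seed),
    frozen = FALSE,
    history = list()
  ), class = "seg_model")
}

#' @export
print.seg_model <- function(x, ...) {
  pc <- count_params(x)
  cat(sprintf(
    "seg_model '%s' (%s encoder), input %d x %d x %d, %s params (%s trainable)%s\n",
    x$architecture_id, x$encoder, x$input_size[1], x$input_size[2], x$in_channels,
    format(attr(pc, "total"), big.mark = ","), format(as.integer(pc), big.mark = ","),
    if (is.null(x$params)) " [shapes only]" else ""
  ))
  invisible(x)
}

#' Forward pass producing a probability map
#'
#' Applies the model to an image and returns the per-pixel foreground
#' probability (logistic transform of the logits) together with the
#' penultimate activation used for cross-stage context fusion.
#'
#' @param m a [build_model()] object with weights.
#' @param x an `H x W x C` image array matching `m$input_size` and
#'   `m$in_channels`, values in `[0, 1]`.
#' @param penultimate_add optional activation added elementwise to the
#'   penultimate layer before the prediction head (context fusion).
#' @return list with `probs` (`H x W` matrix in (0,1)) and `penultimate`.
#' @export
predict_probs <- function(m, x, penultimate_add = NULL) {
  stopifnot(inherits(m, "seg_model"))
  if (is.null(m$params)) stop("model was built with weights = FALSE")
  d <- dim(x)
  if (length(d) == 2L) { dim(x) <- c(d, 1L); d <- dim(x) }
  if (d[1] != m$input_size[1] || d[2] != m$input_size[2] || d[3] != m$in_channels) {
    stop(sprintf(
      "input %d x %d x %d does not match model input %d x %d x %d",
      d[1], d[2], d[3], m$input_size[1], m$input_size[2], m$in_channels
    ))
  }
  if (!is.null(penultimate_add)) {
    pch <- penultimate_channels(m)
    if (dim(penultimate_add)[3] != pch) {
      stop(sprintf(
        "context has %d channels but the penultimate layer has %d (architecture mismatch)",
        dim(penultimate_add)[3], pch
      ))
    }
  }
  fwd <- graph_forward(m, x, penultimate_add = penultimate_add)
  logits <- fwd$out[, , 1L]
  list(probs = 1 / (1 + exp(-logits)), penultimate = fwd$penultimate,
       logits = logits)
}

# channel count of the penultimate activation, derived from the graph
penultimate_channels <- function(m) {
  ch <- m$in_channels
  chans <- list()
  for (node in m$graph) {
    ch <- switch(node$op,
      input = m$in_channels,
      conv = node$cout,
      bn = node$c,
      relu = chans[[node$input]],
      maxpool = chans[[node$input]],
      upsample = chans[[node$input[1]]],
      add = chans[[node$input[1]]],
      concat = sum(unlist(chans[node$input])),
      globalpool = chans[[node$input]]
    )
    chans[[node$name]] <- ch
  }
  chans[[m$penultimate]]
}

## ---- op accounting ---------------------------------------------------------

node_param_count <- function(node) {
  switch(node$op,
    conv = node$k^2 * node$cin * node$cout + if (node$bias) node$cout else 0L,
    bn = 2L * node$c,
    0L
  )
}

#' Count model parameters
#'
#' Counts are derived analytically from the layer shapes, so they work for
#' shapes-only models too.  The return value is the *trainable* count (0 for
#' a frozen model); the architecture's total is attached as attribute
#' `"total"`, which freezing does not change.
#'
#' @param m a [build_model()] object.
#' @return integer trainable-parameter count with attribute `total`.
#' @export
count_params <- function(m) {
  stopifnot(inherits(m, "seg_model"))
  total <- sum(vapply(m$graph, node_param_count, numeric(1)))
  structure(as.integer(if (isTRUE(m$frozen)) 0L else total), total = as.integer(total))
}

#' Parameter count of a model's encoder backbone
#'
#' For the ResNet-50-backed architectures this is the classification-free
#' ResNet-50 encoder (23,508,032 parameters); for `tiny` it is the
#' downsampling half of the network.
#'
#' @param m a [build_model()] object.
#' @return integer parameter count of the encoder layers.
#' @export
count_encoder_params <- function(m) {
  stopifnot(inherits(m, "seg_model"))
  pref <- if (m$encoder == "resnet50") "^(stem_|pool$|l[1-4]_)" else "^(c1|c2|c3|r1|r2|r3)$"
  keep <- vapply(m$graph, function(n) grepl(pref, n$name), logical(1))
  as.integer(sum(vapply(m$graph[keep], node_param_count, numeric(1))))
}

#' Count forward-pass multiply-accumulate operations
#'
#' Walks the graph symbolically at the given input size and sums
#' `k^2 * cin * cout * out_h * out_w` per convolution (dilation does not
#' change the count; normalization, pooling, resizing and activations are
#' excluded).  For fully convolutional architectures the count scales with
#' input area: doubling each side quadruples it.
#'
#' @param m a [build_model()] object (weights not required).
#' @param input_size `c(h, w)`; defaults to the model's recorded input size.
#' @return total MAC count (numeric; may exceed integer range).
#' @export
count_flops <- function(m, input_size = NULL) {
  stopifnot(inherits(m, "seg_model"))
  if (is.null(input_size)) input_size <- m$input_size
  dims <- list()
  flops <- 0
  for (node in m$graph) {
    d <- switch(node$op,
      input = c(input_size[1], input_size[2]),
      conv = {
        din <- dims[[node$input]]
        dout <- c(conv_out_dim(din[1], node$k, node$stride, node$dilation),
                  conv_out_dim(din[2], node$k, node$stride, node$dilation))
        flops <- flops + node$k^2 * node$cin * node$cout * dout[1] * dout[2]
        dout
      },
      maxpool = {
        din <- dims[[node$input]]
        c(conv_out_dim(din[1], node$k, node$stride),
          conv_out_dim(din[2], node$k, node$stride))
      },
      upsample = {
        if (!is.null(node$to)) {
          if (identical(node$to, "input")) c(input_size[1], input_size[2]) else dims[[node$to]]
        } else {
          dims[[node$input[1]]] * node$scale
        }
      },
      globalpool = c(1, 1),
      dims[[node$input[1]]]
    )
    dims[[node$name]] <- d
  }
  flops
}

#' Parameter/FLOP table across architectures
#'
#' Convenience audit table: one row per architecture, with the parameter
#' count and MACs at each requested square input size.
#'
#' @param archs architecture ids.
#' @param sizes vector of square input side lengths.
#' @param in_channels input channels.
#' @return a data.frame.
#' @export
op_count_table <- function(archs = architecture_ids,
                           sizes = c(96L, 192L, 384L, 768L),
                           in_channels = 3L) {
  rows <- lapply(archs, function(a) {
    m <- build_model(a, c(sizes[1], sizes[1]), in_channels = in_channels,
                     weights = FALSE)
    fl <- vapply(sizes, function(s) count_flops(m, c(s, s)), numeric(1))
    names(fl) <- sprintf("macs_%dx%d", sizes, sizes)
    c(list(architecture = a, params = attr(count_params(m), "total")), as.list(fl))
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}
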