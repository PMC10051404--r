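# Separable image resizing.  Bilinear interpolation follows the
# "pixel-area / align-corners-false" convention: destination pixel centre d
# maps to source coordinate (d + 0.5) * (in/out) - 0.5, clamped to the valid
# range.  Because every interpolation row sums to 1, constants (and therefore
# the [0,1] range of probability maps) are preserved exactly.

#' Row/column interpolation matrix for bilinear resizing
#'
#' Builds the `out_n` x `in_n` matrix `R` such that `R %*% v` bilinearly
#' resamples a length-`in_n` signal to length `out_n` under the
#' pixel-area (align-corners-false) convention.  Rows sum to 1, so constant
#' signals are mapped to themselves.
#'
#' @param in_n,out_n input and output lengths (>= 1).
#' @return a dense `out_n` x `in_n` numeric matrix.
#' @keywords internal
interp_matrix <- function(in_n, out_n) {
  stopifnot(in_n >= 1, out_n >= 1)
  scale <- in_n / out_n
  src <- (seq_len(out_n) - 0.5) * scale - 0.5
  src <- pmin(pmax(src, 0), in_n - 1)
  lo <- floor(src)
  w_hi <- src - lo
  hi <- pmin(lo + 1, in_n - 1)
  m <- matrix(0, nrow = out_n, ncol = in_n)
  idx <- seq_len(out_n)
  m[cbind(idx, lo + 1)] <- m[cbind(idx, lo + 1)] + (1 - w_hi)
  m[cbind(idx, hi + 1)] <- m[cbind(idx, hi + 1)] + w_hi
  m
}

# nearest-neighbour selection matrix (one 1 per row); used for masks so that
# label sets are closed under resizing
nearest_matrix <- function(in_n, out_n) {
  stopifnot(in_n >= 1, out_n >= 1)
  scale <- in_n / out_n
  src <- floor((seq_len(out_n) - 0.5) * scale)
  src <- pmin(pmax(src, 0), in_n - 1)
  m <- matrix(0, nrow = out_n, ncol = in_n)
  m[cbind(seq_len(out_n), src + 1)] <- 1
  m
}

resize_cache <- new.env(parent = emptyenv())

interp_matrix_cached <- function(in_n, out_n, kind = "bilinear") {
  key <- paste(kind, in_n, out_n, sep = ":")
  m <- resize_cache[[key]]
  if (is.null(m)) {
    m <- if (kind == "bilinear") interp_matrix(in_n, out_n) else nearest_matrix(in_n, out_n)
    resize_cache[[key]] <- m
  }
  m
}

# apply separable resize Y = Rr X Rc' channel-wise; x is H x W or H x W x C
resize_apply <- function(x, out_h, out_w, kind) {
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(2L, 3L))) {
    stop("expected an H x W matrix or H x W x C array")
  }
  rr <- interp_matrix_cached(d[1], out_h, kind)
  rc <- interp_matrix_cached(d[2], out_w, kind)
  if (length(d) == 2L) {
    return(rr %*% x %*% t(rc))
  }
  out <- array(0, dim = c(out_h, out_w, d[3]))
  for (ch in seq_len(d[3])) out[, , ch] <- rr %*% x[, , ch] %*% t(rc)
  out
}

#' Bilinear resize of an image or probability map
#'
#' @param x an `H x W` matrix (probability map) or `H x W x C` array (image),
#'   values in `[0, 1]`.
#' @param out_h,out_w target size (>= 1).
#' @return the resized matrix/array; values stay within the input's range.
#' @export
resize_bilinear <- function(x, out_h, out_w) {
  stopifnot(out_h >= 1, out_w >= 1)
  resize_apply(x, out_h, out_w, "bilinear")
}

#' @rdname resize_bilinear
#' @export
downscale <- function(x, out_h, out_w) resize_bilinear(x, out_h, out_w)

#' @rdname resize_bilinear
#' @export
upscale <- function(x, out_h, out_w) resize_bilinear(x, out_h, out_w)

#' Nearest-neighbour resize of a binary mask
#'
#' Labels are copied, never blended, so the output contains only values that
#' occur in the input (in particular `{0, 1}` masks stay binary).
#'
#' @param m an `H x W` matrix with values in `{0, 1}`.
#' @inheritParams resize_bilinear
#' @export
resize_mask <- function(m, out_h, out_w) {
  stopifnot(out_h >= 1, out_w >= 1)
  check_mask(m)
  resize_apply(m, out_h, out_w, "nearest")
}
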