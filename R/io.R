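# Image and manifest I/O.
#
# Images, masks and probability maps are stored as netpbm PNM files — a
# standard raster format readable by scikit-image, Pillow, ImageMagick and
# netpbm itself — because no PNG codec is guaranteed in the target R stack.
# Greyscale data use PGM (binary P5; ASCII P2 is also read), RGB images use
# PPM (binary P6 / ASCII P3).  Images and masks are 8-bit; probability maps
# are 16-bit big-endian PGM with value = round(p * 65535), preserving the
# resolution that thresholding near the uncertainty maximum needs.

#' Read a PNM (PGM/PPM) file
#'
#' @param path file path.
#' @return numeric array `H x W x C` with values in `[0, 1]` (C = 1 for PGM,
#'   3 for PPM); attribute `maxval` records the stored bit depth.
#' @export
read_pnm <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L, useBytes = TRUE)
  if (!magic %in% c("P2", "P3", "P5", "P6")) {
    stop(sprintf("'%s' is not a supported PNM file (magic '%s')", path, magic))
  }
  ascii <- magic %in% c("P2", "P3")
  channels <- if (magic %in% c("P3", "P6")) 3L else 1L
  # header tokens: width, height, maxval; '#' comments allowed
  tokens <- integer(0)
  buf <- character(0)
  while (length(tokens) < 3L) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L || ch == "") stop(sprintf("truncated PNM header in '%s'", path))
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0L || ch %in% c("\n", "")) break
      }
      ch <- " "
    }
    if (grepl("[0-9]", ch)) {
      buf <- c(buf, ch)
    } else if (length(buf)) {
      tokens <- c(tokens, as.integer(paste(buf, collapse = "")))
      buf <- character(0)
    }
  }
  w <- tokens[1]; h <- tokens[2]; maxval <- tokens[3]
  n <- h * w * channels
  vals <- if (ascii) {
    scan(con, what = integer(), n = n, quiet = TRUE)
  } else if (maxval < 256L) {
    as.integer(readBin(con, "raw", n = n))
  } else {
    readBin(con, "integer", n = n, size = 2L, signed = FALSE, endian = "big")
  }
  if (length(vals) != n) stop(sprintf("truncated pixel data in '%s'", path))
  # PNM stores row-major (rows of the image in file order)
  arr <- array(0, dim = c(h, w, channels))
  for (ch_i in seq_len(channels)) {
    plane <- vals[seq(ch_i, n, by = channels)]
    arr[, , ch_i] <- matrix(plane, nrow = h, ncol = w, byrow = TRUE)
  }
  structure(arr / maxval, maxval = maxval)
}

#' Write a PNM (PGM/PPM) file
#'
#' @param path output path.
#' @param x `H x W` matrix or `H x W x C` array (C = 1 or 3) with values in
#'   `[0, 1]`.
#' @param maxval 255 for 8-bit or 65535 for 16-bit (16-bit only for
#'   greyscale).
#' @export
write_pnm <- function(path, x, maxval = 255L) {
  d <- dim(x)
  if (length(d) == 2L) { dim(x) <- c(d, 1L); d <- dim(x) }
  stopifnot(length(d) == 3L, d[3] %in% c(1L, 3L), maxval %in% c(255L, 65535L))
  if (d[3] == 3L && maxval != 255L) stop("16-bit output is greyscale-only")
  # interleave channels, row-major
  flat <- numeric(d[1] * d[2] * d[3])
  for (ch_i in seq_len(d[3])) {
    flat[seq(ch_i, length(flat), by = d[3])] <- as.vector(t(x[, , ch_i]))
  }
  flat <- as.integer(round(pmin(pmax(flat, 0), 1) * maxval))
  magic <- if (d[3] == 3L) "P6" else "P5"
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("%s\n%d %d\n%d\n", magic, d[2], d[1], maxval), con,
            eos = NULL, useBytes = TRUE)
  if (maxval < 256L) {
    writeBin(as.raw(flat), con)
  } else {
    # big-endian 16-bit; writeBin has no unsigned 16-bit type, split bytes
    hi <- flat %/% 256L
    lo <- flat %% 256L
    bytes <- as.raw(as.vector(rbind(hi, lo)))
    writeBin(bytes, con)
  }
  invisible(path)
}

#' Read an image as an `H x W x C` array in `[0, 1]`
#' @param path a PGM/PPM file.
#' @export
read_image <- function(path) {
  x <- read_pnm(path)
  attr(x, "maxval") <- NULL
  x
}

#' Read a binary mask (any nonzero value becomes 1)
#' @param path a PGM file.
#' @return `H x W` matrix with values in `{0, 1}`.
#' @export
read_mask <- function(path) {
  x <- read_pnm(path)
  if (dim(x)[3] != 1L) stop(sprintf("mask '%s' must be greyscale", path))
  (x[, , 1L] != 0) * 1
}

#' Write a binary mask as an 8-bit PGM with values {0, 255}
#' @param path output path.
#' @param m `H x W` binary matrix.
#' @export
write_mask <- function(path, m) {
  check_mask(m)
  write_pnm(path, m, maxval = 255L)
}

#' Write a probability map as 16-bit greyscale PGM
#'
#' Stored value is `round(p * 65535)`; reading back recovers each
#' probability to within `1/65535`.
#'
#' @param path output path.
#' @param p `H x W` probability matrix.
#' @export
write_prob <- function(path, p) {
  check_probs(p)
  write_pnm(path, p, maxval = 65535L)
}

#' Read a probability map written by [write_prob()]
#' @param path a 16-bit PGM file.
#' @export
read_prob <- function(path) {
  x <- read_pnm(path)
  if (dim(x)[3] != 1L) stop(sprintf("probability map '%s' must be greyscale", path))
  unname(x[, , 1L])
}

#' Load and validate a dataset manifest
#'
#' A manifest is a CSV with header `image,mask,split`; `split` must be
#' `train` or `test`, paths must be nonempty and image paths unique.
#'
#' @param path CSV path.
#' @return a data.frame with columns `image`, `mask`, `split`.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("manifest not found: '%s'", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image", "mask", "split")
  if (!all(need %in% names(df))) {
    stop(sprintf("manifest '%s' must have columns image,mask,split", path))
  }
  bad_split <- which(!df$split %in% c("train", "test"))
  if (length(bad_split)) {
    stop(sprintf("manifest '%s': invalid split '%s' at line %d",
                 path, df$split[bad_split[1]], bad_split[1] + 1L))
  }
  bad_path <- which(!nzchar(df$image) | !nzchar(df$mask))
  if (length(bad_path)) {
    stop(sprintf("manifest '%s': empty path at line %d", path, bad_path[1] + 1L))
  }
  if (anyDuplicated(df$image)) {
    stop(sprintf("manifest '%s': duplicate image path '%s'",
                 path, df$image[duplicated(df$image)][1]))
  }
  message(sprintf("manifest '%s': %d train, %d test", path,
                  sum(df$split == "train"), sum(df$split == "test")))
  df[, need]
}

#' Save / load a fully resolved run configuration
#'
#' A run configuration is a plain named list (training, selection, grid and
#' path settings) serialized as human-readable JSON; `load_run_config()`
#' of a saved file reproduces the list exactly (round-trip identity), so
#' every run can record the configuration it resolved to.
#'
#' @param cfg a named list of scalar-or-vector settings.
#' @param path JSON path.
#' @export
save_run_config <- function(cfg, path) {
  stopifnot(is.list(cfg))
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config not found: '%s'", path))
  jsonlite::read_json(path, simplifyVector = TRUE)
}
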