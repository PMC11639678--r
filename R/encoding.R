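#' Read an IDX-format file (images or labels)
#'
#' Parses the big-endian IDX binary layout used by the MNIST family:
#' a 4-byte magic number (`0x00 0x00 0x08 <ndim>`), `ndim` big-endian
#' 32-bit dimension sizes and a uint8 payload. A 3-dimensional file is
#' interpreted as a stack of grayscale images and returned as a pixel
#' matrix normalized to \[0, 1\] (raw value / 255, one column per image);
#' a 1-dimensional file is interpreted as integer class labels.
#'
#' @param path path to an IDX file.
#' @return For image files, a numeric matrix `[n_pixels x n_images]` with a
#'   `dim_sizes` attribute holding `c(n, rows, cols)`; for label files, an
#'   integer vector.
#' @seealso [read_idx_dataset()], [write_idx()]
#' @export
read_idx <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 4L)
  if (length(magic) < 4L)
    stop("malformed IDX file: truncated magic number at byte offset 0")
  if (magic[1] != as.raw(0) || magic[2] != as.raw(0))
    stop("malformed IDX file: bad magic number at byte offset 0 (expected 0x0000 prefix)")
  if (magic[3] != as.raw(0x08))
    stop("malformed IDX file: unsupported data type code at byte offset 2 (only uint8/0x08)")
  ndim <- as.integer(magic[4])
  if (!ndim %in% c(1L, 3L))
    stop("malformed IDX file: dimension count ", ndim,
         " at byte offset 3 (expected 1 for labels or 3 for images)")
  dims <- readBin(con, "integer", n = ndim, size = 4L, endian = "big")
  if (length(dims) < ndim || any(dims < 0))
    stop("malformed IDX file: truncated or invalid dimension sizes at byte offset 4")
  n_vals <- prod(dims)
  payload <- readBin(con, "integer", n = n_vals, size = 1L, signed = FALSE)
  if (length(payload) < n_vals)
    stop("malformed IDX file: truncated payload at byte offset ",
         4L + 4L * ndim + length(payload),
         " (expected ", n_vals, " bytes, got ", length(payload), ")")
  if (ndim == 1L) return(as.integer(payload))
  px <- matrix(payload / 255, nrow = dims[2] * dims[3], ncol = dims[1])
  attr(px, "dim_sizes") <- dims
  px
}

#' Read a paired image/label IDX file set as a dataset
#'
#' @param image_path,label_path paths to the IDX image and label files.
#' @return A `csdp_dataset`: list with `pixels` (`[n_pixels x n]`, values in
#'   \[0, 1\]), integer `labels` (0-based), `side` (image side length for
#'   square images, else `NA`) and `n_classes`.
#' @export
read_idx_dataset <- function(image_path, label_path) {
  px <- read_idx(image_path)
  if (is.null(attr(px, "dim_sizes")))
    stop("image_path does not point to a 3-dimensional IDX image file")
  labels <- read_idx(label_path)
  if (is.matrix(labels))
    stop("label_path does not point to a 1-dimensional IDX label file")
  if (length(labels) != ncol(px))
    stop("image/label count mismatch: ", ncol(px), " images vs ",
         length(labels), " labels")
  d <- attr(px, "dim_sizes")
  new_dataset(unclass_matrix(px), labels,
              side = if (d[2] == d[3]) d[2] else NA_integer_)
}

unclass_matrix <- function(px) { attr(px, "dim_sizes") <- NULL; px }

new_dataset <- function(pixels, labels, side = NA_integer_) {
  structure(list(pixels = pixels, labels = labels,
                 side = as.integer(side),
                 n_classes = if (is.null(labels)) NA_integer_
                             else length(unique(labels))),
            class = "csdp_dataset")
}

#' @export
print.csdp_dataset <- function(x, ...) {
  cat("<csdp_dataset> ", ncol(x$pixels), " patterns of ", nrow(x$pixels),
      " pixels", if (!is.na(x$side)) paste0(" (", x$side, "x", x$side, ")"),
      if (!is.null(x$labels)) paste0(", ", x$n_classes, " classes"),
      "\n", sep = "")
  invisible(x)
}

#' Write images or labels to an IDX-format file
#'
#' Inverse of [read_idx()]: pixel matrices (values in \[0, 1\]) are scaled
#' by 255, rounded and stored as a 3-dimensional uint8 file; integer label
#' vectors are stored as a 1-dimensional uint8 file.
#'
#' @param x pixel matrix `[n_pixels x n]` (with square images of side
#'   `side`) or an integer label vector.
#' @param path output path.
#' @param side image side length; required for pixel matrices.
#' @return `path`, invisibly.
#' @export
write_idx <- function(x, path, side = NULL) {
  con <- file(path, "wb")
  on.exit(close(con))
  if (is.matrix(x)) {
    if (is.null(side)) side <- as.integer(round(sqrt(nrow(x))))
    if (side * side != nrow(x))
      stop("pixel rows (", nrow(x), ") do not form ", side, "x", side, " images")
    writeBin(as.raw(c(0, 0, 0x08, 3)), con)
    writeBin(as.integer(c(ncol(x), side, side)), con, size = 4L, endian = "big")
    writeBin(as.raw(pmin(255L, pmax(0L, as.integer(round(x * 255))))), con)
  } else {
    writeBin(as.raw(c(0, 0, 0x08, 1)), con)
    writeBin(as.integer(length(x)), con, size = 4L, endian = "big")
    writeBin(as.raw(as.integer(x)), con)
  }
  invisible(path)
}

#' Encode intensities as Bernoulli spike trains
#'
#' Each pixel intensity in \[0, 1\] is treated as an independent Bernoulli
#' spike probability at every step of the stimulus window.
#'
#' @param pixels numeric vector or matrix `[n_pixels x n_patterns]` with
#'   values in \[0, 1\].
#' @param T_steps number of time steps (positive integer).
#' @param seed RNG seed for the stream; encoding is bit-reproducible given
#'   the seed.
#' @return Binary array `[n_pixels, n_patterns, T_steps]`.
#' @examples
#' s <- encode_bernoulli(c(0, 1, 0.5), T_steps = 4, seed = 1)
#' s[1, 1, ]  # all zero
#' @export
encode_bernoulli <- function(pixels, T_steps, seed) {
  if (T_steps <= 0) stop("T_steps must be a positive integer")
  if (!is.matrix(pixels)) pixels <- matrix(pixels, ncol = 1L)
  if (any(pixels < 0 | pixels > 1)) stop("pixel values must lie in [0, 1]")
  set.seed(as.integer(seed))
  u <- array(stats::runif(length(pixels) * T_steps),
             dim = c(nrow(pixels), ncol(pixels), T_steps))
  s <- array(0, dim = dim(u))
  s[u < as.vector(pixels)] <- 1  # pixels recycles over the time dimension
  s
}

#' One-hot label spikes (clamped)
#'
#' Labels are encoded deterministically as a constant one-hot spike vector:
#' the class channel is clamped to 1 at every time step, so a single
#' `[C x n]` matrix represents the whole window.
#'
#' @param labels integer vector of 0-based class indices.
#' @param n_classes class count `C`.
#' @return Binary matrix `[C x n]`.
#' @export
encode_labels <- function(labels, n_classes) {
  if (any(labels < 0 | labels >= n_classes))
    stop("labels must lie in 0..C-1")
  y <- matrix(0, n_classes, length(labels))
  y[cbind(labels + 1L, seq_along(labels))] <- 1
  y
}

#' Assemble a spike batch for one stimulus window
#'
#' @param pixels `[n_pixels x B]` intensities in \[0, 1\].
#' @param labels 0-based labels, or `NULL`.
#' @param y_type binary vector of length B (1 = positive sample, 0 =
#'   negative); defaults to all-positive.
#' @param config a [csdp_config()].
#' @param seed RNG seed for the Bernoulli encoding.
#' @return A `csdp_spike_batch`: list with binary `sensory`
#'   `[J0, B, T_steps]`, `class_spikes` (`[C x B]` clamped one-hot, `NULL`
#'   when no labels are supplied) and `y_type`.
#' @export
make_spike_batch <- function(pixels, labels, config, y_type = NULL, seed = 1L) {
  if (!is.matrix(pixels)) pixels <- matrix(pixels, ncol = 1L)
  if (nrow(pixels) != config$layer_sizes[1])
    stop("pixels have ", nrow(pixels), " rows but the input layer expects ",
         config$layer_sizes[1])
  B <- ncol(pixels)
  if (is.null(y_type)) y_type <- rep(1, B)
  structure(list(
    sensory = encode_bernoulli(pixels, stimulus_steps(config), seed),
    class_spikes = if (is.null(labels)) NULL
                   else encode_labels(labels, config$n_classes),
    y_type = as.numeric(y_type)
  ), class = "csdp_spike_batch")
}

# Procedural binary glyphs: visually distinct strokes/blobs for each class,
# defined for any side >= 4. Classes beyond the 10 base glyphs reuse them
# with a circular shift.
glyph_template <- function(class_idx, side) {
  g <- matrix(0, side, side)
  mid <- (side + 1) / 2
  th <- max(1L, side %/% 6)            # stroke half-thickness
  band <- function(center) pmax(1L, floor(center - th + 1)):pmin(side, ceiling(center + th - 1))
  base <- class_idx %% 10L
  shift <- class_idx %/% 10L
  switch(as.character(base),
    "0" = { g[band(mid), ] <- 1 },                       # horizontal bar
    "1" = { g[, band(mid)] <- 1 },                       # vertical bar
    "2" = { for (i in 1:side) g[i, max(1, i - th + 1):min(side, i + th - 1)] <- 1 },  # diagonal
    "3" = { g[band(mid), ] <- 1; g[, band(mid)] <- 1 },  # cross
    "4" = { g[c(1:th, (side - th + 1):side), ] <- 1      # box outline
            g[, c(1:th, (side - th + 1):side)] <- 1 },
    "5" = { d <- outer(1:side, 1:side, function(r, c) (r - mid)^2 + (c - mid)^2)
            g[d <= (side / 3)^2] <- 1 },                 # filled disc
    "6" = { for (i in 1:side) {
              g[i, max(1, i - th + 1):min(side, i + th - 1)] <- 1
              j <- side - i + 1
              g[i, max(1, j - th + 1):min(side, j + th - 1)] <- 1
            } },                                         # X
    "7" = { g[1:(2 * th), ] <- 1; g[, band(mid)] <- 1 }, # T
    "8" = { g[, 1:(2 * th)] <- 1; g[(side - 2 * th + 1):side, ] <- 1 },  # L
    "9" = { blk <- max(2L, side %/% 4)
            g[] <- outer(1:side, 1:side,
                         function(r, c) (((r - 1) %/% blk) + ((c - 1) %/% blk)) %% 2) }  # checker
  )
  if (shift > 0) {
    k <- (shift * th) %% side
    g <- g[c((k + 1):side, seq_len(k)), , drop = FALSE]
  }
  g
}

#' Generate a synthetic class-templated image dataset
#'
#' A desk-scale stand-in for MNIST-style data with the same statistical
#' shape as [read_idx_dataset()] output: each class has a distinct binary
#' glyph template (bars, crosses, discs, ...) and each sample is the
#' template with every pixel flipped independently with probability
#' `noise`. Deterministic given `seed`.
#'
#' @param n_classes number of classes (>= 2).
#' @param n_per_class samples per class.
#' @param side image side length (>= 4).
#' @param noise per-pixel flip probability in \[0, 1).
#' @param seed RNG seed.
#' @return A `csdp_dataset` with a `templates` attribute
#'   (`[side^2 x n_classes]` binary matrix).
#' @examples
#' ds <- make_synthetic_dataset(2, 10, side = 12, noise = 0.05, seed = 1)
#' dim(ds$pixels)
#' @export
make_synthetic_dataset <- function(n_classes, n_per_class, side = 12,
                                   noise = 0.05, seed = 1L) {
  if (n_classes < 2) stop("n_classes must be >= 2")
  if (side < 4) stop("side must be >= 4")
  if (noise < 0 || noise >= 1) stop("noise must lie in [0, 1)")
  templates <- vapply(seq_len(n_classes) - 1L,
                      function(k) as.vector(glyph_template(k, side)),
                      numeric(side * side))
  set.seed(as.integer(seed))
  n <- n_classes * n_per_class
  labels <- rep(seq_len(n_classes) - 1L, each = n_per_class)
  pixels <- templates[, labels + 1L, drop = FALSE]
  flips <- matrix(stats::runif(length(pixels)) < noise, nrow(pixels), n)
  pixels[flips] <- 1 - pixels[flips]
  ds <- new_dataset(pixels, labels, side = side)
  attr(ds, "templates") <- templates
  ds
}
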