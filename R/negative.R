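# On-the-fly synthesis of negative (out-of-distribution) samples: wrong
# labels for the supervised variant, rotated convex mixtures of batch
# partners for the unsupervised variant. Exactly one negative is created
# per positive sample and appended to the batch with y_type = 0.

#' Negative labels for supervised contrastive training
#'
#' For each sample with true class `c`, draws an incorrect class `q`
#' uniformly from the remaining `C - 1` classes; the paired image is an
#' unchanged copy of the original.
#'
#' @param labels 0-based true class indices.
#' @param n_classes class count `C` (>= 2).
#' @param seed RNG seed.
#' @return Integer vector of 0-based incorrect classes, `q != c` always.
#' @export
negative_labels <- function(labels, n_classes, seed = 1L) {
  if (n_classes < 2) stop("need n_classes >= 2 to sample an incorrect class")
  set.seed(as.integer(seed))
  # uniform over {0..C-1} \ {c}: draw in 0..C-2 and skip past the true class
  q <- floor(stats::runif(length(labels)) * (n_classes - 1L))
  as.integer(ifelse(q >= labels, q + 1L, q))
}

#' Rotate a square image about its center (bilinear, zero fill)
#'
#' Inverse-mapped rotation: each output pixel samples the input at the
#' back-rotated location with bilinear interpolation, zero outside the
#' support. The rotation semantics live behind this single function so an
#' alternative resampler can be swapped in.
#'
#' @param img `side x side` numeric matrix.
#' @param angle rotation angle in radians (counterclockwise in matrix
#'   row/column coordinates).
#' @return Rotated matrix of the same shape.
#' @export
rotate_bilinear <- function(img, angle) {
  side <- nrow(img)
  stopifnot(ncol(img) == side)
  ctr <- (side + 1) / 2
  co <- cos(angle); si <- sin(angle)
  g <- expand.grid(r = seq_len(side), c = seq_len(side))
  # inverse map: where does output pixel (r, c) come from?
  sr <- co * (g$r - ctr) + si * (g$c - ctr) + ctr
  sc <- -si * (g$r - ctr) + co * (g$c - ctr) + ctr
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  at <- function(r, c) {
    ok <- r >= 1 & r <= side & c >= 1 & c <= side
    v <- numeric(length(r))
    v[ok] <- img[cbind(r[ok], c[ok])]
    v
  }
  v <- (1 - fr) * (1 - fc) * at(r0, c0) +
       (1 - fr) * fc       * at(r0, c0 + 1) +
       fr       * (1 - fc) * at(r0 + 1, c0) +
       fr       * fc       * at(r0 + 1, c0 + 1)
  matrix(v, side, side)
}

#' Negative patterns by rotated convex mixture (unsupervised variant)
#'
#' For each pattern `x_i`, picks a distinct partner `x_j` from the batch,
#' rotates it by an angle drawn uniformly from `angle_range`, and mixes:
#' `x_neg_i = eta * x_i + (1 - eta) * rotate(x_j)`, clipped to \[0, 1\].
#'
#' @param pixels `[side^2 x B]` pattern matrix, `B >= 2`.
#' @param side image side length.
#' @param eta mixing weight in (0, 1) on the original pattern.
#' @param angle_range interval (radians) the rotation is drawn from.
#' @param seed RNG seed.
#' @return `[side^2 x B]` matrix of negative patterns.
#' @export
negative_mixtures <- function(pixels, side, eta = 0.55,
                              angle_range = c(pi / 4, 7 * pi / 4),
                              seed = 1L) {
  B <- ncol(pixels)
  if (B < 2) stop("need a batch of >= 2 patterns to pick a distinct partner")
  if (eta <= 0 || eta > 1) stop("eta must lie in (0, 1]")
  set.seed(as.integer(seed))
  # partner j != i, uniform over the rest of the batch
  j <- floor(stats::runif(B) * (B - 1L)) + 1L
  j <- ifelse(j >= seq_len(B), j + 1L, j)
  angles <- stats::runif(B, angle_range[1], angle_range[2])
  neg <- vapply(seq_len(B), function(i) {
    r <- rotate_bilinear(matrix(pixels[, j[i]], side, side), angles[i])
    pmin(pmax(eta * pixels[, i] + (1 - eta) * as.vector(r), 0), 1)
  }, numeric(nrow(pixels)))
  matrix(neg, nrow(pixels), B)
}

#' Append one negative sample per positive to a batch
#'
#' Supervised mode keeps the images and swaps in incorrect labels;
#' unsupervised mode replaces the images by rotated convex mixtures and
#' carries no labels. The returned batch has twice the width, `y_type = 1`
#' for the first half and 0 for the second.
#'
#' @param pixels `[n_pixels x B]` positive patterns.
#' @param labels 0-based labels (required in supervised mode).
#' @param config a [csdp_config()].
#' @param side image side (unsupervised mode).
#' @param eta mixing weight (unsupervised mode).
#' @param seed RNG seed.
#' @return List with doubled `pixels`, `labels` (or `NULL`) and `y_type`.
#' @export
append_negatives <- function(pixels, labels, config, side = NULL,
                             eta = 0.55, seed = 1L) {
  B <- ncol(pixels)
  if (config$supervised) {
    if (is.null(labels)) stop("supervised negatives need the true labels")
    neg_lab <- negative_labels(labels, config$n_classes, seed = seed)
    list(pixels = cbind(pixels, pixels),
         labels = c(labels, neg_lab),
         y_type = rep(c(1, 0), each = B))
  } else {
    if (is.null(side)) side <- as.integer(round(sqrt(nrow(pixels))))
    neg_px <- negative_mixtures(pixels, side, eta = eta, seed = seed)
    # labels are duplicated only to keep column alignment; in unsupervised
    # mode they never drive the network and heads train on positive columns
    list(pixels = cbind(pixels, neg_px),
         labels = if (!is.null(labels)) c(labels, labels),
         y_type = rep(c(1, 0), each = B))
  }
}
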