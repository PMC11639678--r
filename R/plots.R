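# Figure and export helpers: training-curve plot, original/reconstruction
# grids, and plain-text PGM export of image grids.

#' Plot training goodness curves
#'
#' Mean goodness probability of positive and negative samples per epoch:
#' a healthy contrastive run drives the curves apart.
#'
#' @param model a trained `csdp_model`.
#' @param ... passed to [graphics::matplot()].
#' @return The metrics data frame, invisibly.
#' @export
plot_metrics <- function(model, ...) {
  m <- model$metrics
  if (is.null(m)) stop("model has no training metrics")
  graphics::matplot(m$epoch, cbind(m$pos_goodness, m$neg_goodness),
                    type = "b", pch = c(16, 1), lty = 1,
                    col = c("forestgreen", "firebrick"),
                    xlab = "epoch", ylab = "mean goodness probability", ...)
  graphics::legend("right", legend = c("positive", "negative"),
                   col = c("forestgreen", "firebrick"), pch = c(16, 1))
  invisible(m)
}

#' Plot originals and reconstructions side by side
#'
#' Draws an image grid with columns alternating between original patterns
#' and the model's reconstructions.
#'
#' @param originals,reconstructions `[side^2 x n]` pixel matrices.
#' @param side image side length.
#' @return Invisibly, `NULL`.
#' @export
plot_reconstructions <- function(originals, reconstructions, side) {
  n <- ncol(originals)
  op <- graphics::par(mfrow = c(1, 2 * n), mar = c(0.2, 0.2, 1, 0.2))
  on.exit(graphics::par(op))
  for (i in seq_len(n)) {
    for (px in list(originals[, i], reconstructions[, i])) {
      img <- matrix(px, side, side)
      graphics::image(t(img[side:1, ]), col = grDevices::gray.colors(64, 0, 1),
                      axes = FALSE, zlim = c(0, 1))
    }
  }
  invisible(NULL)
}

#' Export an image grid as a plain-text PGM file
#'
#' Writes the patterns as one horizontal strip in the ASCII "P2" portable
#' graymap format (viewable by most image tools, diff-able as text).
#' Useful for original/reconstruction strips.
#'
#' @param pixels `[side^2 x n]` pixel matrix in \[0, 1\]; columns become
#'   tiles left to right.
#' @param side image side length.
#' @param path output path.
#' @param gap blank pixels between tiles.
#' @return `path`, invisibly.
#' @export
write_pgm_grid <- function(pixels, side, path, gap = 1L) {
  n <- ncol(pixels)
  w <- n * side + (n - 1L) * gap
  canvas <- matrix(0, side, w)
  for (i in seq_len(n)) {
    c0 <- (i - 1L) * (side + gap)
    canvas[, (c0 + 1L):(c0 + side)] <- matrix(pixels[, i], side, side)
  }
  vals <- round(canvas * 255)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(w, side), "255"), con)
  utils::write.table(vals, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
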