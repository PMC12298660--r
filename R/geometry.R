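# Elliptical ROI mask and grid-block enumeration.
#
# The capture protocol centres the cut of beef inside a black elliptical
# mask; only the ellipse interior is analysed.  A pixel (x, y) counts as
# inside when its centre (x + 0.5, y + 0.5) satisfies the ellipse
# inequality (boundary inclusive).  With this convention the standard
# 960 x 720 mask at 75% scale contains exactly 55 complete 64 x 64 blocks
# and 36 complete 80 x 80 blocks.

#' Construct an elliptical region-of-interest mask
#'
#' The ellipse is centred in the frame and spans `scale_fraction` of each
#' image dimension, e.g. the default 960 x 720 capture at 0.75 gives a
#' 720-pixel major axis and 540-pixel minor axis centred at (480, 360).
#'
#' @param width,height Image dimensions in pixels.
#' @param scale_fraction Fraction of each dimension spanned by the
#'   ellipse, in (0, 1]. The robustness study uses 0.60 / 0.75 / 0.90 for
#'   the small / medium / large masks.
#' @return An object of class `ellipse_mask`.
#' @export
#' @examples
#' ellipse_mask(960, 720, 0.75)
ellipse_mask <- function(width = 960, height = 720, scale_fraction = 0.75) {
  if (!is.numeric(width) || !is.numeric(height) || width <= 0 || height <= 0) {
    abort("width and height must be positive")
  }
  if (scale_fraction <= 0 || scale_fraction > 1) {
    abort("scale_fraction must be in (0, 1]")
  }
  structure(
    list(width = as.numeric(width), height = as.numeric(height),
         center_x = width / 2, center_y = height / 2,
         semi_axis_x = scale_fraction * width / 2,
         semi_axis_y = scale_fraction * height / 2,
         scale_fraction = scale_fraction),
    class = "ellipse_mask")
}

#' @export
print.ellipse_mask <- function(x, ...) {
  cat(sprintf("<ellipse_mask %gx%g, centre (%g, %g), semi-axes (%g, %g)>\n",
              x$width, x$height, x$center_x, x$center_y,
              x$semi_axis_x, x$semi_axis_y))
  invisible(x)
}

#' Pixel-centre inside test for an ellipse mask
#'
#' @param mask An [ellipse_mask()].
#' @param x,y 0-based pixel coordinates (vectorised).
#' @return Logical vector, `TRUE` where the pixel centre lies inside or on
#'   the ellipse.
#' @export
ellipse_inside <- function(mask, x, y) {
  ((x + 0.5 - mask$center_x) / mask$semi_axis_x)^2 +
    ((y + 0.5 - mask$center_y) / mask$semi_axis_y)^2 <= 1
}

#' Logical raster of an ellipse mask
#'
#' @param mask An [ellipse_mask()].
#' @return Logical matrix `height x width`; `TRUE` inside the ellipse.
#' @export
mask_raster <- function(mask) {
  x <- rep(0:(mask$width - 1), times = mask$height)
  y <- rep(0:(mask$height - 1), each = mask$width)
  matrix(ellipse_inside(mask, x, y), nrow = mask$height, byrow = TRUE)
}

#' Rasterised area of an ellipse mask
#'
#' Number of pixels whose centres fall inside the ellipse (close to, but
#' not exactly, `pi * a * b`).
#'
#' @param mask An [ellipse_mask()].
#' @return Integer pixel count.
#' @export
mask_area <- function(mask) sum(mask_raster(mask))

#' Black out everything outside the region of interest
#'
#' @param image Array `c(H, W, 3)`, 0-255, matching the mask dimensions.
#' @param mask An [ellipse_mask()].
#' @return The masked image; pixels outside the ellipse are (0, 0, 0).
#' @export
apply_mask <- function(image, mask) {
  d <- dim(image)
  if (d[1] != mask$height || d[2] != mask$width) {
    abort(sprintf("image is %dx%d but mask expects %gx%g",
                  d[2], d[1], mask$width, mask$height))
  }
  keep <- mask_raster(mask)
  out <- image
  for (ch in 1:3) out[, , ch][!keep] <- 0
  out
}

#' Enumerate the grid blocks fully contained in the ROI
#'
#' The grid is anchored at the image origin (0, 0) and blocks are
#' half-open windows `[x, x + size) x [y, y + size)`; residual margins
#' that do not fit a whole block are discarded. A block qualifies when all
#' of its pixels are inside the ellipse; because the ellipse is convex it
#' suffices to test the four corner pixels. Blocks are listed row-major,
#' top-left to bottom-right.
#'
#' @param mask An [ellipse_mask()].
#' @param block_size Side of the square blocks, pixels.
#' @return A tibble with columns `block_id`, `x`, `y`, `size`.
#' @export
#' @examples
#' nrow(valid_blocks(ellipse_mask(960, 720, 0.75), 80))  # 36
#' nrow(valid_blocks(ellipse_mask(960, 720, 0.75), 64))  # 55
valid_blocks <- function(mask, block_size) {
  if (!is.numeric(block_size) || block_size <= 0) {
    abort("block_size must be positive")
  }
  if (block_size > min(mask$width, mask$height)) {
    abort("block_size exceeds image dimensions")
  }
  bx <- seq(0, mask$width - block_size, by = block_size)
  by <- seq(0, mask$height - block_size, by = block_size)
  grid <- tidyr::expand_grid(y = by, x = bx)   # row-major
  s <- block_size
  ok <- ellipse_inside(mask, grid$x,         grid$y) &
        ellipse_inside(mask, grid$x + s - 1, grid$y) &
        ellipse_inside(mask, grid$x,         grid$y + s - 1) &
        ellipse_inside(mask, grid$x + s - 1, grid$y + s - 1)
  out <- grid[ok, c("x", "y")]
  tibble(block_id = seq_len(nrow(out)), x = out$x, y = out$y, size = s)
}

# Extract one block as an array c(size, size, 3); x, y 0-based origin.
block_pixels <- function(image, x, y, size) {
  image[(y + 1):(y + size), (x + 1):(x + size), , drop = FALSE]
}

#' Export a block grid as CSV
#'
#' @param blocks Tibble from [valid_blocks()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_block_grid <- function(blocks, path) {
  write.csv(blocks, path, row.names = FALSE)
  invisible(path)
}
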