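# Images are plain numeric arrays dim c(height, width, 3) holding 8-bit
# intensities 0..255.  Pixel coordinates are 0-based: x rightward (column),
# y downward (row), so pixel (x, y) lives at img[y + 1, x + 1, ].  The
# continuous coordinate of a pixel centre is (x + 0.5, y + 0.5).

#' Read an 8-bit RGB image
#'
#' Reads a PNG or JPEG file into the array representation used by the
#' package (`height x width x 3`, intensities 0-255). Grayscale files are
#' replicated across the three channels; an alpha channel, if present, is
#' dropped.
#'
#' @param path Path to a PNG or JPEG file.
#' @return Numeric array `c(H, W, 3)` with values in 0..255.
#' @export
read_beef_image <- function(path) {
  if (!file.exists(path)) abort(paste0("image file not found: ", path))
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)          # [x, y, c] in [0, 1]
  if (length(dim(dat)) == 2L) dat <- array(dat, c(dim(dat), 1L))
  dat <- aperm(dat, c(2, 1, 3))           # -> [y, x, c]
  nc <- dim(dat)[3]
  if (nc == 1L) dat <- dat[, , c(1, 1, 1), drop = FALSE]
  if (nc >= 4L) dat <- dat[, , 1:3, drop = FALSE]
  if (dim(dat)[3] == 2L) dat <- dat[, , c(1, 1, 1), drop = FALSE]
  round(255 * pmin(pmax(dat, 0), 1))
}

#' Write an image to PNG
#'
#' @param image Array `c(H, W, 3)` (0-255) or a single-channel matrix
#'   (e.g. a fat ground-truth mask, written as 0/255).
#' @param path Output path; format follows the file extension (PNG
#'   recommended).
#' @return `path`, invisibly.
#' @export
write_beef_image <- function(image, path) {
  if (is.logical(image)) image <- 255 * image
  dat <- image / 255
  if (length(dim(dat)) == 3L) dat <- aperm(dat, c(2, 1, 3)) else dat <- t(dat)
  EBImage::writeImage(EBImage::Image(pmin(pmax(dat, 0), 1),
                                     colormode = if (length(dim(dat)) == 3L) "Color" else "Grayscale"),
                      path)
  invisible(path)
}

# Bilinear sampling of a single-channel matrix at continuous pixel
# coordinates (integer coordinates address pixels exactly).  Out-of-bounds
# samples return `fill`.  Shared by circular LBP sampling, resizing and the
# perspective tilt warp.
sample_bilinear <- function(mat, x, y, fill = 0) {
  h <- nrow(mat); w <- ncol(mat)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0;   fy <- y - y0
  gv <- function(xi, yi) {
    inb <- xi >= 0 & xi <= w - 1 & yi >= 0 & yi <= h - 1
    out <- rep(fill, length(xi))
    out[inb] <- mat[xi[inb] * h + yi[inb] + 1]   # column-major linear index
    out
  }
  v00 <- gv(x0, y0); v10 <- gv(x0 + 1, y0)
  v01 <- gv(x0, y0 + 1); v11 <- gv(x0 + 1, y0 + 1)
  (1 - fy) * ((1 - fx) * v00 + fx * v10) + fy * ((1 - fx) * v01 + fx * v11)
}

#' Resize an image with bilinear interpolation
#'
#' The pipeline operates at a fixed working resolution of 960 x 720;
#' captures at other resolutions are resampled before masking.
#'
#' @param image Array `c(H, W, 3)`, 0-255.
#' @param width,height Target size in pixels (default 960 x 720).
#' @return Resized array, rounded back to 0-255.
#' @export
resize_image <- function(image, width = 960, height = 720) {
  d <- dim(image)
  if (d[1] == height && d[2] == width) return(image)
  # centre-aligned mapping of output pixel centres onto the input grid,
  # clamped at the borders (edge replication)
  xs <- pmin(pmax((seq_len(width) - 0.5) * d[2] / width - 0.5, 0), d[2] - 1)
  ys <- pmin(pmax((seq_len(height) - 0.5) * d[1] / height - 0.5, 0), d[1] - 1)
  xg <- rep(xs, times = height)
  yg <- rep(ys, each = width)
  out <- array(0, c(height, width, 3))
  for (ch in 1:3) {
    v <- sample_bilinear(image[, , ch], xg, yg)
    out[, , ch] <- matrix(v, nrow = height, byrow = TRUE)
  }
  round(pmin(pmax(out, 0), 255))
}

#' Convert an RGB block to grayscale
#'
#' Uses the Rec. 601 luma weights `0.299 R + 0.587 G + 0.114 B`, rounded
#' and clamped to 0-255.
#'
#' @param block Array `c(h, w, 3)` of 8-bit intensities.
#' @return Integer-valued matrix `h x w`.
#' @export
#' @examples
#' px <- array(c(100, 150, 200), c(1, 1, 3))
#' to_grayscale(px)  # 141
to_grayscale <- function(block) {
  if (length(dim(block)) != 3L || dim(block)[3] != 3L) {
    abort("to_grayscale() expects an RGB array c(h, w, 3)")
  }
  if (any(dim(block)[1:2] == 0L)) abort("empty block")
  g <- 0.299 * block[, , 1] + 0.587 * block[, , 2] + 0.114 * block[, , 3]
  matrix(pmin(pmax(round(g), 0), 255), nrow = dim(block)[1])
}

clip255 <- function(x) pmin(pmax(x, 0), 255)
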