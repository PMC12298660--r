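# Per-block colour statistics.  Every colour space is expressed on a
# common 0-255 scale so the downstream min-max scaler sees comparable
# ranges: HSV hue (0-360 deg) is multiplied by 255/360 and S, V by 255;
# L* is multiplied by 255/100 and a*, b* are shifted from [-128, 127] by
# +128 (sRGB primaries, D65 white).

COLORSPACES <- c("rgb", "hsv", "lab")

#' Convert an RGB block to another colour space on a 0-255 scale
#'
#' @param block Array `c(h, w, 3)` of 8-bit RGB intensities.
#' @param colorspace One of `"rgb"`, `"hsv"`, `"lab"`.
#' @return Array `c(h, w, 3)` with every channel on a 0-255 scale.
#' @export
#' @examples
#' px <- array(c(255, 0, 0), c(1, 1, 3))
#' convert_colorspace(px, "hsv")  # H = 0, S = 255, V = 255
convert_colorspace <- function(block, colorspace = COLORSPACES) {
  colorspace <- match.arg(tolower(colorspace), COLORSPACES)
  d <- dim(block)
  if (length(d) != 3L || d[3] != 3L) abort("block must be an array c(h, w, 3)")
  if (any(d[1:2] == 0L)) abort("empty block")
  if (colorspace == "rgb") return(block * 1)
  n <- d[1] * d[2]
  rgb <- cbind(as.vector(block[, , 1]), as.vector(block[, , 2]),
               as.vector(block[, , 3]))
  if (colorspace == "hsv") {
    hsv <- grDevices::rgb2hsv(t(rgb), maxColorValue = 255)  # each in [0, 1]
    out <- cbind(hsv[1, ] * 255, hsv[2, ] * 255, hsv[3, ] * 255)
  } else {
    lab <- grDevices::convertColor(rgb / 255, from = "sRGB", to = "Lab")
    out <- cbind(lab[, 1] * 255 / 100, lab[, 2] + 128, lab[, 3] + 128)
  }
  array(clip255(out), d)
}

#' Per-block colour statistics
#'
#' Population mean and population (divide-by-N) standard deviation of each
#' channel over all block pixels, after conversion to the requested colour
#' space. Returned as a one-row tibble so per-image results stack with
#' `dplyr::bind_rows()`.
#'
#' @inheritParams convert_colorspace
#' @return A one-row tibble: `colorspace`, `mu_1..mu_3`, `sd_1..sd_3`.
#' @export
#' @examples
#' blk <- array(128, c(4, 4, 3))
#' color_stats(blk, "rgb")
color_stats <- function(block, colorspace = COLORSPACES) {
  colorspace <- match.arg(tolower(colorspace), COLORSPACES)
  conv <- convert_colorspace(block, colorspace)
  n <- prod(dim(conv)[1:2])
  mu <- vapply(1:3, function(ch) mean(conv[, , ch]), numeric(1))
  sg <- vapply(1:3, function(ch) {
    v <- conv[, , ch]
    sqrt(sum((v - mean(v))^2) / n)
  }, numeric(1))
  tibble(colorspace = colorspace,
         mu_1 = mu[1], mu_2 = mu[2], mu_3 = mu[3],
         sd_1 = sg[1], sd_2 = sg[2], sd_3 = sg[3])
}

# Flat named vector (mu_1..sd_3) for feature assembly.
color_stats_vector <- function(block, colorspace) {
  st <- color_stats(block, colorspace)
  v <- unlist(st[1, c("mu_1", "mu_2", "mu_3", "sd_1", "sd_2", "sd_3")])
  names(v) <- paste0(colorspace, "_", c("mu_1", "mu_2", "mu_3",
                                        "sd_1", "sd_2", "sd_3"))
  v
}
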