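# Per-block feature assembly and [0, 1] min-max scaling.
#
# A block feature vector is the 59-bin uniform-LBP histogram followed by
# six colour statistics (mu_1, mu_2, mu_3, sd_1, sd_2, sd_3) per colour
# space, in the fixed order RGB, HSV, L*a*b*.  The supported combinations
# and their lengths (P = 8): lbp_rgb / lbp_hsv / lbp_lab -> 65,
# lbp_rgb_hsv -> 71, lbp_rgb_hsv_lab -> 77.

FEATURE_COMBINATIONS <- list(
  lbp_rgb         = "rgb",
  lbp_hsv         = "hsv",
  lbp_lab         = "lab",
  lbp_rgb_hsv     = c("rgb", "hsv"),
  lbp_rgb_hsv_lab = c("rgb", "hsv", "lab")
)

#' Colour spaces used by a feature combination
#'
#' @param combination One of `"lbp_rgb"`, `"lbp_hsv"`, `"lbp_lab"`,
#'   `"lbp_rgb_hsv"`, `"lbp_rgb_hsv_lab"`.
#' @return Character vector of colour-space names in assembly order.
#' @export
combination_colorspaces <- function(combination = names(FEATURE_COMBINATIONS)) {
  combination <- match.arg(tolower(combination), names(FEATURE_COMBINATIONS))
  FEATURE_COMBINATIONS[[combination]]
}

#' Expected feature-vector length for a combination
#'
#' @inheritParams combination_colorspaces
#' @param P LBP sampling points (length depends on the histogram size).
#' @return Integer length: 59 + 6 per colour space for P = 8.
#' @export
#' @examples
#' feature_length("lbp_rgb")          # 65
#' feature_length("lbp_rgb_hsv_lab")  # 77
feature_length <- function(combination, P = 8) {
  lbp_n_bins(P) + 6L * length(combination_colorspaces(combination))
}

#' Assemble one block feature vector
#'
#' @param hist Histogram from [lbp_histogram()].
#' @param stats A list of one-row tibbles from [color_stats()], one per
#'   colour space of the combination, in order RGB, HSV, LAB.
#' @inheritParams combination_colorspaces
#' @return Named numeric vector of length [feature_length()].
#' @export
assemble_features <- function(hist, stats, combination = "lbp_rgb") {
  combination <- match.arg(tolower(combination), names(FEATURE_COMBINATIONS))
  spaces <- FEATURE_COMBINATIONS[[combination]]
  if (inherits(stats, "data.frame")) stats <- list(stats)
  got <- vapply(stats, function(s) s$colorspace[1], character(1))
  if (!identical(got, spaces)) {
    abort(sprintf("combination %s needs colour stats for [%s], got [%s]",
                  combination, paste(spaces, collapse = ", "),
                  paste(got, collapse = ", ")))
  }
  cols <- c("mu_1", "mu_2", "mu_3", "sd_1", "sd_2", "sd_3")
  colour <- unlist(lapply(stats, function(s) {
    v <- unlist(s[1, cols])
    names(v) <- paste0(s$colorspace[1], "_", cols)
    v
  }))
  c(hist[seq_along(hist)], colour)
}

#' Fit a min-max feature scaler on training vectors
#'
#' Records the per-dimension minimum and maximum over the training set
#' only; the fitted scaler is then frozen for validation and test data to
#' avoid leakage.
#'
#' @param x Numeric matrix (rows = blocks) or a data frame of feature
#'   columns; at least two rows.
#' @return An object of class `marble_scaler`.
#' @export
fit_scaler <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) abort("need at least two training vectors")
  structure(
    list(mins = apply(x, 2, min), maxs = apply(x, 2, max),
         dims = ncol(x), names = colnames(x)),
    class = "marble_scaler")
}

#' Scale feature vectors to [0, 1]
#'
#' Applies `(v - min) / (max - min)` per dimension with the bounds learned
#' by [fit_scaler()], clipping out-of-range values to \[0, 1\]. Degenerate
#' (constant) training dimensions map to 0.
#'
#' @param scaler A `marble_scaler`.
#' @param x Matrix or data frame of feature rows, or a single numeric
#'   vector.
#' @return Scaled numeric matrix (or vector, matching the input shape).
#' @export
apply_scaler <- function(scaler, x) {
  vec <- is.null(dim(x))
  x <- if (vec) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(x) != scaler$dims) {
    abort(sprintf("scaler expects %d dimensions, got %d", scaler$dims, ncol(x)))
  }
  rng <- scaler$maxs - scaler$mins
  out <- sweep(x, 2, scaler$mins, "-")
  nz <- rng > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2, rng[nz], "/")
  out[, !nz] <- 0
  out <- pmin(pmax(out, 0), 1)
  if (vec) drop(out) else out
}

#' @export
print.marble_scaler <- function(x, ...) {
  cat(sprintf("<marble_scaler: %d dimensions, %d degenerate>\n",
              x$dims, sum(x$maxs == x$mins)))
  invisible(x)
}

#' @rdname fit_scaler
#' @param x A `marble_scaler`.
#' @param ... Unused.
#' @export
tidy.marble_scaler <- function(x, ...) {
  tibble(dimension = x$names %||% paste0("V", seq_len(x$dims)),
         min = unname(x$mins), max = unname(x$maxs))
}

#' Serialise / restore a fitted scaler as JSON
#'
#' @param scaler A `marble_scaler`.
#' @param path JSON file path.
#' @return `write_scaler()` returns `path` invisibly; `read_scaler()`
#'   returns the restored `marble_scaler`.
#' @export
write_scaler <- function(scaler, path) {
  jsonlite::write_json(
    list(dims = scaler$dims, names = scaler$names,
         mins = unname(scaler$mins), maxs = unname(scaler$maxs)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scaler
#' @export
read_scaler <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(mins = setNames(j$mins, j$names),
                 maxs = setNames(j$maxs, j$names),
                 dims = j$dims, names = j$names),
            class = "marble_scaler")
}

#' Feature vectors for every valid block of one image
#'
#' Runs the full per-block feature extraction (grayscale, uniform LBP
#' histogram, colour statistics for the combination's colour spaces) over
#' the valid grid blocks of a masked image.
#'
#' @param image Array `c(H, W, 3)`, 0-255 (masking is not required: only
#'   blocks fully inside the ROI are touched).
#' @param blocks Tibble from [valid_blocks()].
#' @inheritParams combination_colorspaces
#' @param P,R LBP configuration (default LBP(8, 1)).
#' @return Tibble: `block_id`, `x`, `y`, then one column per feature.
#' @export
block_features <- function(image, blocks, combination = "lbp_rgb",
                           P = 8, R = 1) {
  combination <- match.arg(tolower(combination), names(FEATURE_COMBINATIONS))
  spaces <- FEATURE_COMBINATIONS[[combination]]
  gray <- to_grayscale(image)
  rows <- purrr::pmap(blocks, function(block_id, x, y, size) {
    blk <- block_pixels(image, x, y, size)
    g <- gray[(y + 1):(y + size), (x + 1):(x + size)]
    hist <- lbp_histogram(g, P = P, R = R)
    colour <- unlist(lapply(spaces, function(cs) color_stats_vector(blk, cs)))
    c(hist[seq_along(hist)], colour)
  })
  feats <- do.call(rbind, rows)
  dplyr::bind_cols(blocks[, c("block_id", "x", "y")], as_tibble(feats))
}

# Columns of a feature tibble that hold feature values.
feature_columns <- function(df) {
  setdiff(names(df), c("image_id", "class", "split", "block_id", "x", "y",
                       ".pred"))
}
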