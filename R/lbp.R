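# Uniform local binary patterns.
#
# At every interior pixel the P neighbours on a circle of radius R are
# thresholded against the centre (bit k = 1 when neighbour k >= centre,
# weighted 2^k), giving a code in [0, 2^P - 1].  Codes whose circular bit
# string has at most two 0<->1 transitions are "uniform"; for P = 8 there
# are 58 of them and all remaining codes share one bin, yielding the
# 59-bin histogram used as the block texture feature.
#
# Neighbour k sits at angle 2*pi*k/P counterclockwise from the +x axis.
# For the unit-radius 8-point operator the sampling positions are snapped
# to the surrounding 3x3 pixel ring (the operator's classical definition);
# radius-2 configurations sample the exact circle with bilinear
# interpolation.

lbp_offsets <- function(P, R) {
  k <- 0:(P - 1)
  ang <- 2 * pi * k / P
  dx <- R * cos(ang)
  dy <- -R * sin(ang)           # y grows downward; angles measured CCW
  if (P == 8 && R == 1) {       # 3x3 ring
    dx <- round(dx); dy <- round(dy)
  }
  # remove floating fuzz at axis-aligned samples
  dx <- ifelse(abs(dx - round(dx)) < 1e-9, round(dx), dx)
  dy <- ifelse(abs(dy - round(dy)) < 1e-9, round(dy), dy)
  list(dx = dx, dy = dy)
}

check_lbp_config <- function(P, R) {
  if (!(P %in% c(8L, 16L)) || !(R %in% c(1L, 2L))) {
    abort("supported LBP configurations: P in {8, 16}, R in {1, 2}")
  }
  if (P == 16 && R == 1) abort("LBP(16, 1) is not supported")
  invisible(NULL)
}

#' Single LBP code from a centre and its ordered neighbours
#'
#' Bit k is set when `neighbors[k] >= center`; the code is
#' `sum(bit_k * 2^k)` with bit 0 taken from the first neighbour.
#'
#' @param center Centre pixel intensity.
#' @param neighbors Numeric vector of exactly P neighbour intensities in
#'   circular order.
#' @return Integer code in `[0, 2^P - 1]`.
#' @export
#' @examples
#' lbp_code(100, rep(100, 8))            # 255: flat patch, >= comparison
#' lbp_code(5, c(9, 1, 9, 1, 9, 1, 9, 1))  # 85
lbp_code <- function(center, neighbors) {
  P <- length(neighbors)
  if (P < 1) abort("at least one neighbor required")
  sum((neighbors >= center) * 2^(seq_len(P) - 1))
}

#' Circular 0/1 transition count of an LBP code
#'
#' @param code LBP code(s) in `[0, 2^P - 1]` (vectorised).
#' @param P Number of sampling points.
#' @return Number of bitwise changes around the circular bit string.
#' @export
#' @examples
#' transition_count(0L, 8)        # 00000000 -> 0
#' transition_count(15L, 8)       # 00001111 -> 2
#' transition_count(85L, 8)       # 01010101 -> 8
transition_count <- function(code, P) {
  if (any(code < 0 | code >= 2^P)) abort("code out of range for P")
  bits <- vapply(0:(P - 1), function(k) bitwAnd(bitwShiftR(as.integer(code), k), 1L),
                 integer(length(code)))
  bits <- matrix(bits, ncol = P)
  nxt <- bits[, c(2:P, 1), drop = FALSE]
  rowSums(bits != nxt)
}

# code -> bin lookup tables, cached per P
.lbp_cache <- new.env(parent = emptyenv())

uniform_map <- function(P) {
  key <- paste0("P", P)
  if (!is.null(.lbp_cache[[key]])) return(.lbp_cache[[key]])
  codes <- 0:(2^P - 1)
  u <- transition_count(codes, P)
  uniform <- codes[u <= 2]                 # ascending by construction
  map <- rep.int(length(uniform), 2^P)     # non-uniform bin = last index
  map[uniform + 1] <- seq_along(uniform) - 1
  .lbp_cache[[key]] <- map
  map
}

#' Uniform-pattern bin index of an LBP code
#'
#' Uniform codes (at most two circular transitions) map bijectively, in
#' ascending code order, onto bins `0 .. n_uniform - 1`; every non-uniform
#' code maps to the single trailing bin. For P = 8 that is 58 uniform bins
#' plus bin 58; for P = 16, 242 plus bin 242.
#'
#' @inheritParams transition_count
#' @return Bin indices (vectorised).
#' @export
uniform_bin_index <- function(code, P) {
  if (any(code < 0 | code >= 2^P)) abort("code out of range for P")
  uniform_map(P)[code + 1]
}

#' Number of histogram bins for a uniform-LBP configuration
#'
#' `P * (P - 1) + 2` uniform bins plus one non-uniform bin: 59 for P = 8,
#' 243 for P = 16.
#'
#' @param P Number of sampling points.
#' @return Integer bin count.
#' @export
lbp_n_bins <- function(P) as.integer(P * (P - 1) + 2 + 1)

# Vectorised code computation over all interior pixels of a grayscale
# matrix; returns a matrix of codes of dim (h - 2R) x (w - 2R).
lbp_code_matrix <- function(gray, P, R) {
  h <- nrow(gray); w <- ncol(gray)
  ri <- (R + 1):(h - R); ci <- (R + 1):(w - R)
  centre <- gray[ri, ci, drop = FALSE]
  off <- lbp_offsets(P, R)
  codes <- matrix(0, nrow(centre), ncol(centre))
  for (k in seq_len(P)) {
    dx <- off$dx[k]; dy <- off$dy[k]
    x0 <- floor(dx); y0 <- floor(dy)
    fx <- dx - x0;   fy <- dy - y0
    sub <- function(ox, oy) gray[ri + oy, ci + ox, drop = FALSE]
    if (fx == 0 && fy == 0) {
      nb <- sub(x0, y0)
    } else {
      nb <- (1 - fy) * ((1 - fx) * sub(x0, y0) + fx * sub(x0 + 1, y0)) +
                  fy * ((1 - fx) * sub(x0, y0 + 1) + fx * sub(x0 + 1, y0 + 1))
    }
    codes <- codes + (nb >= centre) * 2^(k - 1)
  }
  codes
}

#' Normalised uniform-LBP histogram of a block
#'
#' Codes are computed at every pixel whose full circular neighbourhood
#' lies inside the block (no padding), so for a square block of side s
#' there are `(s - 2R)^2` codes; the histogram is normalised by that
#' count and sums to one.
#'
#' @param block RGB array `c(h, w, 3)` (converted to grayscale first) or a
#'   grayscale matrix.
#' @param P Sampling points (8 or 16). Default LBP(8, 1), the preferred
#'   operator configuration.
#' @param R Sampling radius in pixels (1 or 2).
#' @return Named numeric vector of length [lbp_n_bins()] (`lbp_00` ...),
#'   with attributes `P` and `R`.
#' @export
lbp_histogram <- function(block, P = 8, R = 1) {
  check_lbp_config(P, R)
  gray <- if (length(dim(block)) == 3L) to_grayscale(block) else block
  if (min(dim(gray)) < 2 * R + 1) {
    abort("block too small for the requested LBP radius")
  }
  codes <- lbp_code_matrix(gray, P, R)
  bins <- uniform_bin_index(as.vector(codes), P)
  nb <- lbp_n_bins(P)
  counts <- tabulate(bins + 1, nbins = nb)
  hist <- counts / length(codes)
  names(hist) <- sprintf("lbp_%02d", 0:(nb - 1))
  attr(hist, "P") <- P
  attr(hist, "R") <- R
  hist
}
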