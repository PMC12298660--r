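# Independent oracles used across the suite.  These are deliberately
# naive scalar implementations, kept separate from the package's
# vectorised code paths.

# Textbook hexcone HSV of one RGB triple (0-255): H in degrees, S and V
# in [0, 1].
oracle_hsv <- function(rgb) {
  v <- rgb / 255
  mx <- max(v); mn <- min(v); d <- mx - mn
  h <- if (d == 0) 0
  else if (mx == v[1]) 60 * (((v[2] - v[3]) / d) %% 6)
  else if (mx == v[2]) 60 * ((v[3] - v[1]) / d + 2)
  else 60 * ((v[1] - v[2]) / d + 4)
  s <- if (mx == 0) 0 else d / mx
  c(h = h, s = s, v = mx)
}

# CIE L*a*b* of one sRGB triple (0-255) under D65, from the standard
# formulas: sRGB inverse companding, linear RGB -> XYZ, XYZ -> Lab.
oracle_lab <- function(rgb) {
  lin <- sapply(rgb / 255, function(c) {
    if (c <= 0.04045) c / 12.92 else ((c + 0.055) / 1.055)^2.4
  })
  M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
  xyz <- as.vector(M %*% lin)
  wp <- c(0.95047, 1, 1.08883)            # D65
  f <- function(t) if (t > (6 / 29)^3) t^(1 / 3) else t / (3 * (6 / 29)^2) + 4 / 29
  fx <- f(xyz[1] / wp[1]); fy <- f(xyz[2] / wp[2]); fz <- f(xyz[3] / wp[3])
  c(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

# Naive per-pixel uniform-LBP histogram of a grayscale matrix: double
# loop over interior pixels, scalar bilinear sampling, scalar transition
# counting.  Mirrors the stated conventions (neighbour k at angle
# 2*pi*k/P counterclockwise from +x with y downward; the unit-radius
# 8-point operator on the integer 3x3 ring) without sharing code.
naive_lbp_hist <- function(gray, P, R) {
  h <- nrow(gray); w <- ncol(gray)
  ang <- 2 * pi * (0:(P - 1)) / P
  dx <- R * cos(ang); dy <- -R * sin(ang)
  if (P == 8 && R == 1) { dx <- round(dx); dy <- round(dy) }
  dx <- ifelse(abs(dx - round(dx)) < 1e-9, round(dx), dx)
  dy <- ifelse(abs(dy - round(dy)) < 1e-9, round(dy), dy)
  bilin <- function(x, y) {
    x0 <- floor(x); y0 <- floor(y); fx <- x - x0; fy <- y - y0
    (1 - fy) * ((1 - fx) * gray[y0 + 1, x0 + 1] + fx * gray[y0 + 1, x0 + 2]) +
      fy * ((1 - fx) * gray[y0 + 2, x0 + 1] + fx * gray[y0 + 2, x0 + 2])
  }
  trans <- function(bits) sum(bits != bits[c(2:P, 1)])
  n_uni <- P * (P - 1) + 2
  # ascending-code rank of uniform codes
  all_codes <- 0:(2^P - 1)
  is_uni <- sapply(all_codes, function(cd) {
    bits <- as.integer(intToBits(cd))[1:P]
    trans(bits) <= 2
  })
  uni_rank <- cumsum(is_uni)               # 1-based rank among uniform codes
  counts <- numeric(n_uni + 1)
  for (yy in R:(h - 1 - R)) {
    for (xx in R:(w - 1 - R)) {
      centre <- gray[yy + 1, xx + 1]
      bits <- integer(P)
      for (k in 1:P) {
        xs <- xx + dx[k]; ys <- yy + dy[k]
        nb <- if (xs == round(xs) && ys == round(ys)) {
          gray[round(ys) + 1, round(xs) + 1]
        } else bilin(xs, ys)
        bits[k] <- as.integer(nb >= centre)
      }
      code <- sum(bits * 2^(0:(P - 1)))
      bin <- if (trans(bits) <= 2) uni_rank[code + 1] - 1 else n_uni
      counts[bin + 1] <- counts[bin + 1] + 1
    }
  }
  counts / sum(counts)
}

# Exhaustive per-pixel ellipse-containment test of one block (independent
# of the package's corner shortcut).
brute_block_inside <- function(width, height, scale, x, y, size) {
  cx <- width / 2; cy <- height / 2
  a <- scale * width / 2; b <- scale * height / 2
  px <- rep(x:(x + size - 1), times = size)
  py <- rep(y:(y + size - 1), each = size)
  all(((px + 0.5 - cx) / a)^2 + ((py + 0.5 - cy) / b)^2 <= 1)
}

# Three well-separated Gaussian clusters in 2-D, one per beef class.
toy_clusters <- function(n_per_class = 30, sep = 1.5, sd = 0.01, seed = 1) {
  withr::with_seed(seed, {
    centres <- rbind(wagyu = c(0, 0), regular = c(sep, 0),
                     fat_injected = c(0, sep))
    x <- do.call(rbind, lapply(rownames(centres), function(cl) {
      cbind(rnorm(n_per_class, centres[cl, 1], sd),
            rnorm(n_per_class, centres[cl, 2], sd))
    }))
    list(x = x,
         y = beef_class(rep(rownames(centres), each = n_per_class)),
         centres = centres)
  })
}

# Nearest-centroid separability oracle.
nearest_centroid <- function(x, centres) {
  d <- sapply(seq_len(nrow(centres)), function(i) {
    rowSums(sweep(x, 2, centres[i, ])^2)
  })
  beef_class(rownames(centres)[max.col(-d)])
}

# A small random RGB block for feature tests.
random_block <- function(side = 80, seed = 1) {
  withr::with_seed(seed,
    array(sample(0:255, side * side * 3, replace = TRUE), c(side, side, 3)))
}
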