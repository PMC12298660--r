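# Synthetic beef-surface image generator.
#
# Emulates the three surface phenotypes the classifier must separate:
#   wagyu        - many small, low-elongation fat flecks, scattered and
#                  mostly disconnected, on bright-red lean;
#   regular      - low fat fraction, few flecks, mid-red lean;
#   fat_injected - fewer, strongly elongated streaks chained end-to-end
#                  along a dominant orientation (interconnected), on
#                  darker red lean.
# Fat is rendered near-white with anti-aliased elliptical primitives; the
# binary ground-truth fat mask actually rendered is returned with every
# image.  All randomness flows from a single integer seed per image.
#
# The quantitative defaults (colours, fractions, counts, elongations) are
# free parameters of the generator chosen to realise those qualitative
# contrasts; they are documented in the methods vignette.

#' Phenotype specification for the synthetic generator
#'
#' @param beef_class `"wagyu"`, `"regular"` or `"fat_injected"`.
#' @param lean_color_mean,lean_color_sd Length-3 RGB mean and per-channel
#'   pixel noise SD of the lean background, 0-255.
#' @param fat_fraction_range Target fat area fraction of the ROI, `(0,1)`.
#' @param fleck_count_range Integer range of fat primitives per image.
#' @param elongation_range Major/minor axis ratio range of the primitives.
#' @param connectivity `"scattered"` (independent placement) or
#'   `"interconnected"` (primitives chained along a dominant orientation).
#' @param orientation_jitter SD (degrees) of primitive orientation about
#'   the image's dominant direction; 90 or more is effectively isotropic.
#' @param fat_color_mean,fat_color_sd Fat colour (near-white gray-pink)
#'   mean and pixel noise SD.
#' @param area_cv Log-scale SD of per-fleck area (fat thickness
#'   variability).
#' @return An object of class `phenotype_spec`.
#' @export
phenotype_spec <- function(beef_class,
                           lean_color_mean, lean_color_sd,
                           fat_fraction_range, fleck_count_range,
                           elongation_range,
                           connectivity = c("scattered", "interconnected"),
                           orientation_jitter = 90,
                           fat_color_mean = c(235, 227, 223),
                           fat_color_sd = 10,
                           area_cv = 0.5) {
  connectivity <- match.arg(connectivity)
  stopifnot(length(lean_color_mean) == 3, length(fat_fraction_range) == 2,
            length(fleck_count_range) == 2, length(elongation_range) == 2)
  if (any(fat_fraction_range <= 0) || any(fat_fraction_range >= 1) ||
      diff(fat_fraction_range) < 0) {
    abort("fat_fraction_range must be a nonempty range inside (0, 1)")
  }
  structure(
    list(beef_class = as.character(beef_class(beef_class)),
         lean_color_mean = lean_color_mean, lean_color_sd = lean_color_sd,
         fat_fraction_range = fat_fraction_range,
         fleck_count_range = fleck_count_range,
         elongation_range = elongation_range,
         connectivity = connectivity,
         orientation_jitter = orientation_jitter,
         fat_color_mean = fat_color_mean, fat_color_sd = fat_color_sd,
         area_cv = area_cv),
    class = "phenotype_spec")
}

#' Default phenotype specifications for the three beef classes
#'
#' @return Named list of [phenotype_spec()] objects
#'   (`wagyu`, `regular`, `fat_injected`).
#' @export
default_phenotypes <- function() {
  list(
    wagyu = phenotype_spec(
      "wagyu",
      lean_color_mean = c(185, 75, 70), lean_color_sd = c(14, 10, 10),
      fat_fraction_range = c(0.18, 0.32),
      fleck_count_range = c(140, 260),
      elongation_range = c(1.2, 3),
      connectivity = "scattered", orientation_jitter = 90,
      area_cv = 0.6),
    regular = phenotype_spec(
      "regular",
      lean_color_mean = c(170, 62, 60), lean_color_sd = c(8, 6, 6),
      fat_fraction_range = c(0.02, 0.07),
      fleck_count_range = c(8, 25),
      elongation_range = c(1.5, 3.5),
      connectivity = "scattered", orientation_jitter = 90,
      area_cv = 0.5),
    fat_injected = phenotype_spec(
      "fat_injected",
      lean_color_mean = c(120, 45, 48), lean_color_sd = c(12, 9, 9),
      fat_fraction_range = c(0.15, 0.28),
      fleck_count_range = c(24, 48),
      elongation_range = c(5, 12),
      connectivity = "interconnected", orientation_jitter = 12,
      area_cv = 0.25)
  )
}

# Per-fleck maximum plausible area (px); a spec whose count range cannot
# reach its fat fraction with flecks of at most this size is infeasible.
MAX_FLECK_AREA <- 20000

# Soft-edged rotated-ellipse alpha patch (edge width ~1 px) with its
# target row/column indices; the caller composites it into the
# accumulator (kept a local variable there so subassignment stays
# in place).
fleck_patch <- function(cx, cy, ra, rb, theta, h, w) {
  half <- ceiling(ra) + 1
  x0 <- max(0, floor(cx - half)); x1 <- min(w - 1, ceiling(cx + half))
  y0 <- max(0, floor(cy - half)); y1 <- min(h - 1, ceiling(cy + half))
  if (x0 > x1 || y0 > y1) return(NULL)
  xs <- x0:x1; ys <- y0:y1
  lx <- xs - cx; ly <- ys - cy
  ct <- cos(theta); stn <- sin(theta)
  ur <- outer(ly * stn, lx * ct, "+")    # x cos + y sin
  vr <- outer(ly * ct, -lx * stn, "+")   # -x sin + y cos
  q <- sqrt((ur / ra)^2 + (vr / rb)^2)
  alpha <- pmin(pmax((1 - q) * rb, 0), 1)
  list(rows = ys + 1, cols = xs + 1, alpha = alpha)
}

# Separable bilinear upsampling of a coarse field to h x w (low-frequency
# background mottling).
upsample_field <- function(coarse, h, w) {
  interp_mat <- function(n_out, n_in) {
    pos <- (0:(n_out - 1)) / (n_out - 1) * (n_in - 1)
    i0 <- pmin(floor(pos), n_in - 2)
    f <- pos - i0
    M <- matrix(0, n_out, n_in)
    M[cbind(1:n_out, i0 + 1)] <- 1 - f
    M[cbind(1:n_out, i0 + 2)] <- M[cbind(1:n_out, i0 + 2)] + f
    M
  }
  interp_mat(h, nrow(coarse)) %*% coarse %*% t(interp_mat(w, ncol(coarse)))
}

#' Generate one synthetic beef-surface image
#'
#' Renders a 960 x 720 (by default) RGB capture: noisy lean background
#' with low-frequency mottling, plus near-white fat primitives placed
#' according to the phenotype (scattered flecks or chained directional
#' streaks) until the target fat fraction of the ROI is covered.
#'
#' @param spec A [phenotype_spec()].
#' @param seed Integer seed; identical `(spec, seed)` give bit-identical
#'   output.
#' @param mask ROI used for the fat-fraction bookkeeping (fat is placed
#'   inside it); default the medium 75% ellipse.
#' @return An object of class `synth_beef`: list with `image`
#'   (`c(H, W, 3)`, 0-255), `fat_mask` (logical `H x W`, the rendered
#'   ground truth), `fat_fraction` (of the ROI), `class`, `seed`.
#' @export
synth_image <- function(spec, seed, mask = ellipse_mask(960, 720, 0.75)) {
  stopifnot(inherits(spec, "phenotype_spec"))
  withr::with_seed(as.integer(seed), {
    h <- as.integer(mask$height); w <- as.integer(mask$width)
    roi <- mask_raster(mask)
    roi_area <- sum(roi)

    target <- runif(1, spec$fat_fraction_range[1], spec$fat_fraction_range[2])
    n <- round(runif(1, spec$fleck_count_range[1], spec$fleck_count_range[2]))
    mean_area <- target * roi_area / n
    if (target * roi_area / spec$fleck_count_range[2] > MAX_FLECK_AREA) {
      abort("infeasible phenotype: fat fraction unreachable with fleck count range")
    }

    # lean background: low-frequency mottling + spatially correlated
    # surface grain (noise drawn at half resolution and bilinearly
    # upsampled, emulating the finite grain of a camera image of muscle
    # tissue rather than per-pixel white noise)
    coarse <- matrix(rnorm(9 * 12, 0, 6), 9, 12)
    field <- upsample_field(coarse, h, w)
    h2 <- ceiling(h / 2) + 1; w2 <- ceiling(w / 2) + 1
    img <- array(0, c(h, w, 3))
    for (ch in 1:3) {
      grain <- upsample_field(
        matrix(rnorm(h2 * w2, 0, 1.35 * spec$lean_color_sd[ch]), h2, w2),
        h, w)
      img[, , ch] <- spec$lean_color_mean[ch] + field + grain
    }

    # fat placement; the alpha accumulator A stays a local variable and
    # patches are composited inline so subassignment updates it in place
    A <- matrix(0, h, w)
    dominant <- runif(1, 0, pi)
    jit <- spec$orientation_jitter * pi / 180
    sample_centre <- function() {
      repeat {
        x <- runif(1, mask$center_x - mask$semi_axis_x,
                   mask$center_x + mask$semi_axis_x)
        y <- runif(1, mask$center_y - mask$semi_axis_y,
                   mask$center_y + mask$semi_axis_y)
        if (((x - mask$center_x) / (0.95 * mask$semi_axis_x))^2 +
            ((y - mask$center_y) / (0.95 * mask$semi_axis_y))^2 <= 1) {
          return(c(x, y))
        }
      }
    }
    fleck_geom <- function() {
      area <- min(stats::rlnorm(1, log(mean_area), spec$area_cv),
                  MAX_FLECK_AREA)
      e <- runif(1, spec$elongation_range[1], spec$elongation_range[2])
      rb <- sqrt(area / (pi * e))
      c(ra = e * rb, rb = rb)
    }
    placed <- 0L
    fatpix <- 0L
    cap <- 3L * n
    goal <- target * roi_area
    if (spec$connectivity == "scattered") {
      while (placed < cap && (placed < n || fatpix < goal)) {
        if (fatpix >= goal && placed >= spec$fleck_count_range[1]) break
        ctr <- sample_centre()
        g <- fleck_geom()
        theta <- if (jit < pi / 2) rnorm(1, dominant, jit) else runif(1, 0, pi)
        p <- fleck_patch(ctr[1], ctr[2], g["ra"], g["rb"], theta, h, w)
        if (!is.null(p)) {
          sub <- A[p$rows, p$cols, drop = FALSE]
          upd <- pmax(sub, p$alpha)
          A[p$rows, p$cols] <- upd
          fatpix <- fatpix +
            sum(upd >= 0.5 & sub < 0.5 & roi[p$rows, p$cols, drop = FALSE])
        }
        placed <- placed + 1L
      }
    } else {
      # chains of streaks advancing along a jittered dominant orientation
      while (placed < cap && (placed < n || fatpix < goal)) {
        if (fatpix >= goal && placed >= spec$fleck_count_range[1]) break
        pt <- sample_centre()
        dir <- rnorm(1, dominant, jit)
        seg <- sample(4:8, 1)
        for (s in seq_len(seg)) {
          if (placed >= cap) break
          g <- fleck_geom()
          theta <- dir + rnorm(1, 0, jit / 2)
          p <- fleck_patch(pt[1], pt[2], g["ra"], g["rb"], theta, h, w)
          if (!is.null(p)) {
            sub <- A[p$rows, p$cols, drop = FALSE]
            upd <- pmax(sub, p$alpha)
            A[p$rows, p$cols] <- upd
            fatpix <- fatpix +
              sum(upd >= 0.5 & sub < 0.5 & roi[p$rows, p$cols, drop = FALSE])
          }
          placed <- placed + 1L
          step <- 1.7 * g["ra"]
          pt <- pt + step * c(cos(theta), sin(theta))
          if (((pt[1] - mask$center_x) / mask$semi_axis_x)^2 +
              ((pt[2] - mask$center_y) / mask$semi_axis_y)^2 > 0.9) break
        }
      }
    }

    fat_mask <- A >= 0.5
    # fat colour noise only where fat is visible
    idx <- which(A > 0)
    for (ch in 1:3) {
      layer <- img[, , ch]
      fatcol <- spec$fat_color_mean[ch] +
        rnorm(length(idx), 0, spec$fat_color_sd)
      layer[idx] <- layer[idx] * (1 - A[idx]) + fatcol * A[idx]
      img[, , ch] <- layer
    }
    structure(
      list(image = round(clip255(img)), fat_mask = fat_mask,
           fat_fraction = sum(fat_mask & roi) / roi_area,
           class = spec$beef_class, seed = as.integer(seed)),
      class = "synth_beef")
  })
}

#' @export
print.synth_beef <- function(x, ...) {
  cat(sprintf("<synth_beef: %s, seed %d, fat fraction %.3f>\n",
              x$class, x$seed, x$fat_fraction))
  invisible(x)
}

#' Brightness ladder of the capture-condition study
#'
#' Seven target mean-brightness levels `mu + 1.5 k sigma`,
#' `k = -3 ... 3`, from "very dark" to "very bright". The default
#' `(mu, sigma)` reproduces the reference ladder
#' 21.0 / 47.0 / 72.94 / 98.91 / 124.88 / 150.85 / 176.82.
#'
#' @param mu Normal-condition mean brightness (gray levels).
#' @param sigma Brightness SD; default derived from the ladder step
#'   `mu - 1.5 sigma = 72.94`.
#' @return Named numeric vector of the 7 target means (k = -3 .. 3).
#' @export
#' @examples
#' brightness_levels()[["3"]]   # 176.82
brightness_levels <- function(mu = 98.91, sigma = (98.91 - 72.94) / 1.5) {
  k <- -3:3
  setNames(mu + 1.5 * k * sigma, as.character(k))
}

#' Mean ROI brightness of an image
#'
#' Grayscale mean over the region of interest; the brightness ladder for
#' a robustness sweep is calibrated on these values over the study's own
#' images (the reference ladder was likewise derived from its dataset).
#'
#' @param image Array `c(H, W, 3)`, 0-255.
#' @param mask An [ellipse_mask()].
#' @return Mean gray level (0-255).
#' @export
roi_brightness <- function(image, mask = ellipse_mask(dim(image)[2],
                                                      dim(image)[1], 0.75)) {
  mean(to_grayscale(image)[mask_raster(mask)])
}

PERTURB_KINDS <- c("none", "brightness", "label", "reflection", "tilt")

#' Apply a capture-condition perturbation to an image
#'
#' Simulates the disturbances of handheld capture:
#' * `brightness` - global gain (with clipping) so the ROI grayscale mean
#'   hits the ladder level `mu + 1.5 k sigma` (see [brightness_levels()]);
#' * `label` - an opaque white rounded rectangle with dark text-like
#'   strokes occluding `occlusion_fraction` of the ROI;
#' * `reflection` - soft-edged near-white specular blobs;
#' * `tilt` - perspective warp equivalent to rotating the camera by
#'   `tilt_angle` degrees about the horizontal (forward/backward) or
#'   vertical (left/right) axis, resampled to the original frame;
#' * `none` - identity.
#'
#' @param image Array `c(H, W, 3)`, 0-255.
#' @param kind One of `"none"`, `"brightness"`, `"label"`, `"reflection"`,
#'   `"tilt"`.
#' @param brightness_k Ladder index k in -3..3 (`brightness` only).
#' @param brightness_mu,brightness_sigma Ladder parameters.
#' @param occlusion_fraction Fraction of the ROI occluded by the label,
#'   in `[0, 0.25]`.
#' @param tilt_angle Camera tilt in degrees (>= 0).
#' @param tilt_direction `"forward"`, `"backward"`, `"left"`, `"right"`.
#' @param mask ROI for brightness bookkeeping and occlusion placement.
#' @param seed Optional integer seed for the stochastic kinds
#'   (label/reflection placement).
#' @return Perturbed image array, 0-255.
#' @export
perturb_image <- function(image, kind = PERTURB_KINDS,
                          brightness_k = 0, brightness_mu = 98.91,
                          brightness_sigma = (98.91 - 72.94) / 1.5,
                          occlusion_fraction = 0.05,
                          tilt_angle = 0,
                          tilt_direction = c("forward", "backward",
                                             "left", "right"),
                          mask = ellipse_mask(dim(image)[2], dim(image)[1],
                                              0.75),
                          seed = NULL) {
  kind <- match.arg(kind, PERTURB_KINDS)
  tilt_direction <- match.arg(tilt_direction)
  run <- function() switch(
    kind,
    none = image,
    brightness = perturb_brightness(image, mask,
                                    brightness_mu +
                                      1.5 * brightness_k * brightness_sigma),
    label = perturb_label(image, mask, occlusion_fraction),
    reflection = perturb_reflection(image, mask),
    tilt = perturb_tilt(image, tilt_angle, tilt_direction))
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

perturb_brightness <- function(image, mask, target) {
  roi <- mask_raster(mask)
  out <- image
  for (i in 1:8) {
    m <- mean(to_grayscale(out)[roi])
    if (abs(m - target) < 0.25) break
    out <- clip255(out * (target / m))
  }
  round(out)
}

perturb_label <- function(image, mask, occlusion_fraction) {
  if (occlusion_fraction < 0 || occlusion_fraction > 0.25) {
    abort("occlusion_fraction must be in [0, 0.25]")
  }
  if (occlusion_fraction == 0) return(image)
  area <- occlusion_fraction * mask_area(mask)
  aspect <- runif(1, 1.6, 2.4)
  lw <- sqrt(area * aspect); lh <- area / lw
  # corner rounding removes (4 - pi) r^2; enlarge to compensate
  r <- 0.1 * lh
  scale <- sqrt(area / (area - (4 - pi) * r^2))
  lw <- lw * scale; lh <- lh * scale; r <- 0.1 * lh
  repeat {
    cx <- runif(1, mask$center_x - 0.6 * mask$semi_axis_x,
                mask$center_x + 0.6 * mask$semi_axis_x)
    cy <- runif(1, mask$center_y - 0.6 * mask$semi_axis_y,
                mask$center_y + 0.6 * mask$semi_axis_y)
    corners_x <- c(cx - lw / 2, cx + lw / 2, cx - lw / 2, cx + lw / 2)
    corners_y <- c(cy - lh / 2, cy - lh / 2, cy + lh / 2, cy + lh / 2)
    if (all(ellipse_inside(mask, corners_x, corners_y))) break
  }
  h <- dim(image)[1]; w <- dim(image)[2]
  xs <- max(0, round(cx - lw / 2)):min(w - 1, round(cx + lw / 2) - 1)
  ys <- max(0, round(cy - lh / 2)):min(h - 1, round(cy + lh / 2) - 1)
  u <- outer(ys, xs, function(y, x) x - cx)
  v <- outer(ys, xs, function(y, x) y - cy)
  # rounded-rectangle membership
  qx <- pmax(abs(u) - (lw / 2 - r), 0)
  qy <- pmax(abs(v) - (lh / 2 - r), 0)
  inside <- sqrt(qx^2 + qy^2) <= r
  # dark text-like strokes
  strokes <- (abs(v) < lh * 0.32) &
    (((v + lh) %% (lh * 0.22)) < lh * 0.055) & (abs(u) < lw * 0.38)
  out <- image
  for (ch in 1:3) {
    sub <- out[ys + 1, xs + 1, ch]
    sub[inside] <- 245
    sub[inside & strokes] <- 60
    out[ys + 1, xs + 1, ch] <- sub
  }
  out
}

perturb_reflection <- function(image, mask) {
  h <- dim(image)[1]; w <- dim(image)[2]
  nb <- sample(3:7, 1)
  A <- matrix(0, h, w)
  for (i in seq_len(nb)) {
    repeat {
      cx <- runif(1, 0, w - 1); cy <- runif(1, 0, h - 1)
      if (ellipse_inside(mask, cx, cy)) break
    }
    s <- runif(1, 12, 35)
    peak <- runif(1, 0.75, 0.95)
    half <- ceiling(3 * s)
    xs <- max(0, floor(cx - half)):min(w - 1, ceiling(cx + half))
    ys <- max(0, floor(cy - half)):min(h - 1, ceiling(cy + half))
    d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
    A[ys + 1, xs + 1] <- pmax(A[ys + 1, xs + 1], peak * exp(-d2 / (2 * s^2)))
  }
  glare <- c(252, 252, 255)
  out <- image
  for (ch in 1:3) out[, , ch] <- image[, , ch] * (1 - A) + glare[ch] * A
  round(clip255(out))
}

perturb_tilt <- function(image, tilt_angle, tilt_direction, focal = 960) {
  if (tilt_angle < 0) abort("tilt_angle must be >= 0")
  if (tilt_angle == 0) return(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  cx <- w / 2; cy <- h / 2
  phi <- tilt_angle * pi / 180 *
    switch(tilt_direction, forward = 1, backward = -1, left = 1, right = -1)
  about_x <- tilt_direction %in% c("forward", "backward")
  # inverse map: for each output pixel, rotate its viewing ray and
  # re-project onto the original image plane
  xo <- rep(0:(w - 1), times = h); yo <- rep(0:(h - 1), each = w)
  u <- (xo + 0.5 - cx) / focal; v <- (yo + 0.5 - cy) / focal
  if (about_x) {
    uy <- v * cos(phi) - sin(phi)
    uz <- v * sin(phi) + cos(phi)
    ux <- u
  } else {
    ux <- u * cos(phi) + sin(phi)
    uz <- -u * sin(phi) + cos(phi)
    uy <- v
  }
  xi <- cx + focal * ux / uz - 0.5
  yi <- cy + focal * uy / uz - 0.5
  out <- array(0, c(h, w, 3))
  for (ch in 1:3) {
    vsamp <- sample_bilinear(image[, , ch], xi, yi, fill = 6)
    out[, , ch] <- matrix(vsamp, nrow = h, byrow = TRUE)
  }
  round(clip255(out))
}

#' Generate a labelled synthetic dataset manifest
#'
#' Produces a class-balanced, seeded manifest with disjoint
#' train/validation/test splits. Images are rendered lazily with
#' [render_image()] (or materialised with [write_dataset()]), so large
#' datasets never need to be held in memory.
#'
#' @param n_per_class Images per class; the reference large-sample design
#'   is 200 per class split 120/40/40.
#' @param split Named ratios `c(train, validation, test)` summing to 1.
#' @param specs Named list of [phenotype_spec()] per class.
#' @param seed Master seed; all per-image seeds derive from it.
#' @param mask ROI mask used at rendering time.
#' @return A tibble of class `marble_dataset`: `image_id`, `class`,
#'   `split`, `image_seed`, with the specs/mask/seed as attributes.
#' @export
#' @examples
#' d <- generate_dataset(10, seed = 1)
#' dplyr::count(d, class, split)
generate_dataset <- function(n_per_class = 200,
                             split = c(train = 0.6, validation = 0.2,
                                       test = 0.2),
                             specs = default_phenotypes(), seed = 1,
                             mask = ellipse_mask(960, 720, 0.75)) {
  if (abs(sum(split) - 1) > 1e-9) abort("split ratios must sum to 1")
  if (!all(c("train", "validation", "test") %in% names(split))) {
    abort("split must have names train, validation, test")
  }
  counts <- round(n_per_class * split[c("train", "validation", "test")])
  counts[1] <- n_per_class - sum(counts[-1])
  if (any(counts < 1)) abort("n_per_class too small for the split ratios")
  classes <- BEEF_CLASSES
  if (!all(classes %in% names(specs))) {
    abort("specs must be named for all three classes")
  }
  seeds <- withr::with_seed(as.integer(seed),
                            sample.int(2^31 - 2, 3 * n_per_class))
  manifest <- purrr::map2_dfr(classes, seq_along(classes), function(cl, i) {
    tibble(image_id = sprintf("%s_%03d", cl, seq_len(n_per_class)),
           class = cl,
           split = rep(c("train", "validation", "test"), counts),
           image_seed = seeds[(i - 1) * n_per_class + seq_len(n_per_class)])
  })
  manifest$class <- beef_class(manifest$class)
  structure(manifest,
            class = c("marble_dataset", class(tibble())),
            specs = specs, seed = as.integer(seed), mask = mask)
}

#' Render one image of a dataset manifest
#'
#' @param dataset A [generate_dataset()] manifest.
#' @param image_id An `image_id` present in the manifest.
#' @return A `synth_beef` object (see [synth_image()]).
#' @export
render_image <- function(dataset, image_id) {
  row <- dataset[dataset$image_id == image_id, ]
  if (nrow(row) != 1) abort(paste0("unknown image_id: ", image_id))
  specs <- attr(dataset, "specs")
  synth_image(specs[[as.character(row$class)]], row$image_seed,
              mask = attr(dataset, "mask"))
}

#' Materialise a dataset on disk
#'
#' Writes `images/<class>/<id>.png`, ground-truth `masks/<id>.png`
#' (single-channel), and `manifest.csv`.
#'
#' @param dataset A [generate_dataset()] manifest.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  for (cl in BEEF_CLASSES) {
    dir.create(file.path(dir, "images", cl), recursive = TRUE,
               showWarnings = FALSE)
  }
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  purrr::walk(dataset$image_id, function(id) {
    sb <- render_image(dataset, id)
    write_beef_image(sb$image,
                     file.path(dir, "images", sb$class, paste0(id, ".png")))
    write_beef_image(sb$fat_mask, file.path(dir, "masks", paste0(id, ".png")))
  })
  write.csv(as.data.frame(dataset), file.path(dir, "manifest.csv"),
            row.names = FALSE)
  invisible(dir)
}
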