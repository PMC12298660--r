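# ggplot2 views of the result objects.

image_to_raster <- function(image) {
  grDevices::as.raster(image / 255)
}

#' Plot a synthetic beef image
#'
#' @param object A `synth_beef` from [synth_image()].
#' @param show_mask Overlay the ground-truth fat mask outline colour.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.synth_beef <- function(object, show_mask = FALSE, ...) {
  img <- object$image
  if (show_mask) {
    m <- object$fat_mask
    img[, , 1][m] <- 255; img[, , 2][m] <- 80; img[, , 3][m] <- 255
  }
  h <- dim(img)[1]; w <- dim(img)[2]
  ggplot2::ggplot() +
    ggplot2::annotation_raster(image_to_raster(img), 0, w, -h, 0) +
    ggplot2::xlim(0, w) + ggplot2::ylim(-h, 0) +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(title = sprintf("%s (seed %d, fat %.1f%%)", object$class,
                                  object$seed, 100 * object$fat_fraction)) +
    ggplot2::theme_void()
}

#' Plot block- or image-level metrics
#'
#' @param object A `marble_metrics`.
#' @param ... Unused.
#' @return A ggplot bar chart of the five metrics (percent).
#' @export
autoplot.marble_metrics <- function(object, ...) {
  df <- tidy(object)
  df$metric <- factor(df$metric,
                      levels = c("alpha", "recall", "precision", "cr", "f1"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$value), "NA",
                     sprintf("%.2f", .data$value))), vjust = -0.4) +
    ggplot2::ylim(0, 105) +
    ggplot2::labs(x = NULL, y = "percent",
                  title = sprintf("%s-level metrics (n = %d)", object$level,
                                  object$n)) +
    ggplot2::theme_minimal()
}

#' Plot a grid-search surface
#'
#' @param object A `marble_grid` from [grid_search()].
#' @param ... Unused.
#' @return A ggplot tile map of validation block CR over (C, gamma).
#' @export
autoplot.marble_grid <- function(object, ...) {
  df <- object$table
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$C),
                                   y = factor(.data$gamma),
                                   fill = .data$block_cr)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", .data$block_cr)),
                       colour = "white", size = 3) +
    ggplot2::scale_fill_viridis_c(name = "block CR %") +
    ggplot2::labs(x = "C (penalty)", y = "gamma (kernel)",
                  title = "Validation block classification rate") +
    ggplot2::theme_minimal()
}

#' Overlay per-block labels on an image
#'
#' Mirrors the system's visual report: each classified block is tinted by
#' its predicted class (wagyu green, regular blue, fat-injected red).
#'
#' @param image Image array `c(H, W, 3)`, 0-255.
#' @param blocks Tibble with `x`, `y`, `size` and `.pred` (from
#'   [classify_image()]).
#' @return A ggplot.
#' @export
plot_block_map <- function(image, blocks) {
  h <- dim(image)[1]; w <- dim(image)[2]
  cols <- c(wagyu = "#2ca02c", regular = "#1f77b4", fat_injected = "#d62728")
  ggplot2::ggplot() +
    ggplot2::annotation_raster(image_to_raster(image), 0, w, -h, 0) +
    ggplot2::geom_rect(
      data = blocks,
      ggplot2::aes(xmin = .data$x, xmax = .data$x + .data$size,
                   ymin = -(.data$y + .data$size), ymax = -.data$y,
                   fill = .data$.pred),
      alpha = 0.35, colour = "white", linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = cols, name = "block label",
                               drop = FALSE) +
    ggplot2::xlim(0, w) + ggplot2::ylim(-h, 0) +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::theme_void()
}
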