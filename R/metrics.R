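# Image-level vote aggregation and the block- / image-level evaluation
# metrics.
#
# The screening task is one-vs-rest for the fat-injected class:
#   misjudgment rate (alpha) = truly non-injected items predicted
#     fat-injected / all truly non-injected items (Type I error),
#   detection rate (recall, 1 - beta) = correctly detected injected items
#     / all truly injected items,
#   precision = correctly detected injected items / all items predicted
#     injected,
#   CR = three-class accuracy (trace of the confusion matrix / total),
#   F1 = harmonic mean of recall and precision.
# All reported as percentages.  Zero-denominator metrics are NA with a
# warning, never silently 0 or 100.

#' Majority vote over block labels with priority tie-break
#'
#' Returns the plurality class among the block predictions of one image;
#' ties among maximal counts are resolved conservatively in the order
#' fat_injected > regular > wagyu.
#'
#' @param block_labels Nonempty vector of block classes (coercible via
#'   [beef_class()]).
#' @return An object of class `marble_vote`: list with `counts` (named,
#'   all three classes), `final` (factor), `tie` (logical).
#' @export
#' @examples
#' vote_image(rep(c("wagyu", "regular", "fat_injected"), c(10, 10, 16)))$final
#' vote_image(rep(c("wagyu", "regular", "fat_injected"), c(12, 12, 12)))$final
vote_image <- function(block_labels) {
  if (length(block_labels) == 0) abort("empty block label list")
  y <- beef_class(block_labels)
  counts <- table(y)
  tied <- names(counts)[counts == max(counts)]
  final <- priority_pick(tied)
  structure(list(counts = setNames(as.integer(counts), names(counts)),
                 final = factor(final, levels = BEEF_CLASSES),
                 tie = length(tied) > 1),
            class = "marble_vote")
}

#' @export
print.marble_vote <- function(x, ...) {
  cat(sprintf("<marble_vote: %s (%s)%s>\n", as.character(x$final),
              paste(sprintf("%s=%d", names(x$counts), x$counts),
                    collapse = ", "),
              if (x$tie) ", tie broken by priority" else ""))
  invisible(x)
}

#' Confusion matrix of beef-class predictions
#'
#' @param predicted,truth Equal-length class vectors.
#' @return 3x3 table, truth in rows, prediction in columns.
#' @export
confusion_matrix <- function(predicted, truth) {
  table(truth = beef_class(truth), predicted = beef_class(predicted))
}

#' Block- and image-level classification metrics
#'
#' `block_metrics()` and `image_metrics()` evaluate the same quantities at
#' the two stages of the system: individual grid-block predictions, and
#' final image labels after majority voting.
#'
#' @param predicted,truth Equal-length nonempty class vectors.
#' @param level `"block"` or `"image"` (set by the wrappers).
#' @return An object of class `marble_metrics`: `level`, `n`, `alpha`,
#'   `recall`, `precision`, `cr`, `f1` (percent; `NA` where a denominator
#'   is zero) and the 3x3 `confusion` table.
#' @export
classification_metrics <- function(predicted, truth,
                                   level = c("block", "image")) {
  level <- match.arg(level)
  if (length(predicted) == 0) abort("empty prediction list")
  if (length(predicted) != length(truth)) {
    abort("predicted and truth lengths differ")
  }
  pred <- beef_class(predicted)
  tru <- beef_class(truth)
  inj <- "fat_injected"
  n_non_inj <- sum(tru != inj)
  n_inj <- sum(tru == inj)
  n_detected <- sum(pred == inj)
  tp <- sum(pred == inj & tru == inj)
  fp <- sum(pred == inj & tru != inj)

  rate <- function(num, den, what) {
    if (den == 0) {
      warn(paste0(what, " undefined: zero denominator"))
      return(NA_real_)
    }
    100 * num / den
  }
  alpha <- rate(fp, n_non_inj, "misjudgment rate")
  recall <- rate(tp, n_inj, "detection rate")
  precision <- rate(tp, n_detected, "precision")
  cr <- 100 * mean(pred == tru)
  f1 <- if (is.na(recall) || is.na(precision) || recall + precision == 0) {
    if (!is.na(recall) && !is.na(precision)) {
      warn("F1 undefined: recall + precision is zero")
    }
    NA_real_
  } else {
    2 * recall * precision / (recall + precision)
  }
  structure(list(level = level, n = length(pred), alpha = alpha,
                 recall = recall, precision = precision, cr = cr, f1 = f1,
                 confusion = confusion_matrix(pred, tru)),
            class = "marble_metrics")
}

#' @rdname classification_metrics
#' @export
block_metrics <- function(predicted, truth) {
  classification_metrics(predicted, truth, "block")
}

#' @rdname classification_metrics
#' @export
image_metrics <- function(predicted, truth) {
  classification_metrics(predicted, truth, "image")
}

#' @export
print.marble_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.2f%%", v)
  cat(sprintf("<marble_metrics, %s level, n = %d>\n", x$level, x$n))
  cat(sprintf("  misjudgment rate (alpha): %s\n", fmt(x$alpha)))
  cat(sprintf("  detection rate (recall):  %s\n", fmt(x$recall)))
  cat(sprintf("  precision:                %s\n", fmt(x$precision)))
  cat(sprintf("  classification rate (CR): %s\n", fmt(x$cr)))
  cat(sprintf("  F1 (fat-injected):        %s\n", fmt(x$f1)))
  invisible(x)
}

#' @rdname classification_metrics
#' @param x A `marble_metrics` object.
#' @param ... Unused.
#' @export
tidy.marble_metrics <- function(x, ...) {
  tibble(level = x$level,
         metric = c("alpha", "recall", "precision", "cr", "f1"),
         value = c(x$alpha, x$recall, x$precision, x$cr, x$f1))
}

#' @rdname classification_metrics
#' @export
glance.marble_metrics <- function(x, ...) {
  tibble(level = x$level, n = x$n, alpha = x$alpha, recall = x$recall,
         precision = x$precision, cr = x$cr, f1 = x$f1)
}

#' Serialise metrics to JSON
#'
#' @param metrics A `marble_metrics` object.
#' @param path Output JSON path.
#' @param config Optional configuration list embedded for audit.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path, config = NULL) {
  out <- list(level = metrics$level, n = metrics$n, alpha = metrics$alpha,
              recall = metrics$recall, precision = metrics$precision,
              cr = metrics$cr, f1 = metrics$f1,
              confusion = as.data.frame(metrics$confusion))
  if (!is.null(config)) out$config <- config
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
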