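# RBF-kernel SVM block classifier.
#
# Three pairwise C-SVC machines (wagyu/regular, wagyu/fat_injected,
# regular/fat_injected) are trained on min-max-scaled features and
# combined by one-vs-one voting.  A vote tie is resolved by the same
# conservative class priority used at the image level:
# fat_injected > regular > wagyu.  Training is deterministic for a fixed
# input order (fixed tolerance 1e-3, no randomised components).

#' Gaussian RBF kernel
#'
#' `K(x, y) = exp(-gamma * ||x - y||^2)`; equals 1 at zero distance.
#'
#' @param x,y Numeric vectors of equal length.
#' @param gamma Kernel coefficient (> 0).
#' @return Kernel value in (0, 1].
#' @export
rbf_kernel <- function(x, y, gamma = 1) exp(-gamma * sum((x - y)^2))

#' Train the three-class RBF-SVM block classifier
#'
#' Fits the min-max scaler on the supplied (training) features, scales
#' them to \[0, 1\], and trains one-vs-one RBF C-SVC machines. The default
#' `C = 64`, `gamma = 1` is the preferred operating point found by grid
#' search on the validation split.
#'
#' @param x Numeric matrix or data frame of unscaled feature rows.
#' @param y Block labels (coercible via [beef_class()]); all three classes
#'   must be present.
#' @param C Penalty parameter (> 0).
#' @param gamma RBF kernel coefficient (> 0).
#' @param scaler Optionally a pre-fitted [fit_scaler()] result; by default
#'   the scaler is fitted on `x`.
#' @return An object of class `marble_svm`.
#' @export
marble_svm <- function(x, y, C = 64, gamma = 1, scaler = NULL) {
  if (C <= 0 || gamma <= 0) abort("C and gamma must be positive")
  y <- beef_class(y)
  x <- as.matrix(x)
  if (nrow(x) != length(y)) abort("x and y lengths differ")
  if (!all(BEEF_CLASSES %in% y)) {
    abort("training data must contain at least one example of each class")
  }
  scaler <- scaler %||% fit_scaler(x)
  xs <- apply_scaler(scaler, x)
  pairs <- utils::combn(BEEF_CLASSES, 2, simplify = FALSE)
  machines <- lapply(pairs, function(pr) {
    keep <- y %in% pr
    e1071::svm(xs[keep, , drop = FALSE], factor(y[keep], levels = pr),
               type = "C-classification", kernel = "radial",
               cost = C, gamma = gamma, scale = FALSE, tolerance = 1e-3)
  })
  structure(
    list(machines = machines, pairs = pairs, scaler = scaler,
         C = C, gamma = gamma, dims = ncol(x),
         multiclass_strategy = "one_vs_one", version = "marble_svm/1"),
    class = "marble_svm")
}

#' @export
print.marble_svm <- function(x, ...) {
  cat(sprintf("<marble_svm: RBF C = %g, gamma = %g, %d features, one-vs-one>\n",
              x$C, x$gamma, x$dims))
  invisible(x)
}

# Highest-priority class among a character vector of candidates.
priority_pick <- function(candidates) {
  BEEF_PRIORITY[match(TRUE, BEEF_PRIORITY %in% candidates)]
}

#' Predict block labels
#'
#' Applies the frozen training scaler, runs the three pairwise machines
#' and returns the one-vs-one vote winner per row; 1-1-1 vote ties go to
#' the highest-priority class (fat_injected > regular > wagyu).
#'
#' @param object A [marble_svm()] model.
#' @param newdata Matrix / data frame of unscaled feature rows, or one
#'   numeric vector.
#' @param ... Unused.
#' @return Factor of predicted classes.
#' @export
predict.marble_svm <- function(object, newdata, ...) {
  vec <- is.null(dim(newdata))
  x <- if (vec) matrix(as.numeric(newdata), nrow = 1) else as.matrix(newdata)
  if (ncol(x) != object$dims) {
    abort(sprintf("model expects %d features, got %d", object$dims, ncol(x)))
  }
  xs <- apply_scaler(object$scaler, x)
  if (is.null(dim(xs))) xs <- matrix(xs, nrow = 1)
  votes <- matrix(0L, nrow(xs), 3, dimnames = list(NULL, BEEF_CLASSES))
  for (m in object$machines) {
    p <- as.character(predict(m, xs))
    votes[cbind(seq_len(nrow(xs)), match(p, BEEF_CLASSES))] <-
      votes[cbind(seq_len(nrow(xs)), match(p, BEEF_CLASSES))] + 1L
  }
  win <- apply(votes, 1, function(v) priority_pick(BEEF_CLASSES[v == max(v)]))
  factor(win, levels = BEEF_CLASSES)
}

#' @rdname marble_svm
#' @param x A `marble_svm`.
#' @param ... Unused.
#' @export
tidy.marble_svm <- function(x, ...) {
  tibble(
    pair = vapply(x$pairs, paste, character(1), collapse = " vs "),
    n_support_vectors = vapply(x$machines, function(m) m$tot.nSV, integer(1)),
    rho = vapply(x$machines, function(m) as.numeric(m$rho), numeric(1)))
}

#' @rdname marble_svm
#' @export
glance.marble_svm <- function(x, ...) {
  tibble(C = x$C, gamma = x$gamma, n_features = x$dims,
         n_machines = length(x$machines),
         total_support_vectors = sum(vapply(x$machines,
                                            function(m) m$tot.nSV, integer(1))))
}

#' Persist / restore a trained model
#'
#' The artifact bundles the SVM configuration, the frozen feature scaler
#' and the decision machinery, version-tagged.
#'
#' @param model A `marble_svm`.
#' @param path File path (RDS).
#' @return `save_model()` returns `path` invisibly; `load_model()` the
#'   restored model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "marble_svm")) abort("file does not contain a marble_svm")
  m
}

#' Grid search over (C, gamma)
#'
#' Trains one model per lattice point on the training split and scores
#' the block-level classification rate on the validation split. The
#' default lattice is `C in {16, 32, 64, 128, 256}` by
#' `gamma in {0.25, 0.5, 1, 2, 4}` (the refined region of the dyadic
#' range `[2^-8, 2^8]`). Ties on CR are broken toward smaller C, then
#' smaller gamma.
#'
#' @param train_x,train_y Training features (unscaled) and labels.
#' @param val_x,val_y Validation features and labels.
#' @param C_values,gamma_values Nonempty numeric vectors.
#' @return An object of class `marble_grid`: `$table` (tibble of C, gamma,
#'   block_cr), `$best_C`, `$best_gamma`, `$best_model`.
#' @export
grid_search <- function(train_x, train_y, val_x, val_y,
                        C_values = c(16, 32, 64, 128, 256),
                        gamma_values = c(0.25, 0.5, 1, 2, 4)) {
  if (length(C_values) == 0 || length(gamma_values) == 0) {
    abort("C_values and gamma_values must be nonempty")
  }
  if (NROW(train_x) == 0 || NROW(val_x) == 0) abort("empty dataset")
  val_y <- beef_class(val_y)
  lattice <- tidyr::expand_grid(C = sort(C_values), gamma = sort(gamma_values))
  fits <- purrr::pmap(lattice, function(C, gamma) {
    m <- marble_svm(train_x, train_y, C = C, gamma = gamma)
    cr <- 100 * mean(predict(m, val_x) == val_y)
    list(model = m, cr = cr)
  })
  tab <- dplyr::mutate(lattice,
                       block_cr = vapply(fits, function(f) f$cr, numeric(1)))
  best <- dplyr::arrange(tab, dplyr::desc(.data$block_cr), .data$C,
                         .data$gamma)[1, ]
  idx <- which(tab$C == best$C & tab$gamma == best$gamma)
  structure(list(table = tab, best_C = best$C, best_gamma = best$gamma,
                 best_model = fits[[idx]]$model),
            class = "marble_grid")
}

#' @export
print.marble_grid <- function(x, ...) {
  cat(sprintf("<marble_grid: %d lattice points, best (C, gamma) = (%g, %g), CR %.2f%%>\n",
              nrow(x$table), x$best_C, x$best_gamma,
              max(x$table$block_cr)))
  invisible(x)
}

#' @rdname grid_search
#' @param x A `marble_grid`.
#' @param ... Unused.
#' @export
tidy.marble_grid <- function(x, ...) x$table

#' Export a grid-search table as CSV (C rows down, gamma across)
#'
#' @param grid A `marble_grid`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_grid_table <- function(grid, path) {
  wide <- tidyr::pivot_wider(grid$table, names_from = "C",
                             values_from = "block_cr", names_prefix = "C_")
  write.csv(wide, path, row.names = FALSE)
  invisible(path)
}
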