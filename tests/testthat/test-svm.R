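test_that("RBF kernel is 1 at zero distance and symmetric", {
  x <- c(0.2, 0.4); y <- c(0.9, 0.1)
  expect_equal(rbf_kernel(x, x, gamma = 1), 1)
  expect_equal(rbf_kernel(x, y, 2), rbf_kernel(y, x, 2))
  expect_equal(rbf_kernel(x, y, 1), exp(-sum((x - y)^2)))
})

test_that("well-separated clusters are memorised at the default (C, gamma)", {
  toy <- toy_clusters(n_per_class = 25, sep = 1.5, sd = 0.01, seed = 1)
  # separability oracle: nearest centroid is perfect on this data
  expect_equal(mean(nearest_centroid(toy$x, toy$centres) == toy$y), 1)
  m <- marble_svm(toy$x, toy$y, C = 64, gamma = 1)
  expect_equal(mean(predict(m, toy$x) == toy$y), 1)
  # cluster centres classify as their own cluster
  expect_equal(as.character(predict(m, toy$centres["fat_injected", ])),
               "fat_injected")
  expect_equal(as.character(predict(m, toy$centres["wagyu", ])), "wagyu")
})

test_that("separated singletons are memorised and duplication is stable", {
  x <- rbind(c(0, 0), c(2, 0), c(0, 2))
  y <- beef_class(1:3)
  m <- marble_svm(x, y, C = 64, gamma = 1)
  expect_equal(as.character(predict(m, x)), as.character(y))
  expect_equal(predict(m, x[2, ]), predict(m, x[2, ]))
  expect_error(marble_svm(x[1:2, ], y[1:2], 64, 1), "each class")
})

test_that("predictions stay within the three classes and fixed dimension", {
  toy <- toy_clusters(40, sep = 0.5, sd = 0.3, seed = 2)   # overlapping
  m <- marble_svm(toy$x, toy$y)
  p <- predict(m, toy$x)
  expect_true(all(p %in% beef_class(1:3)))
  expect_error(predict(m, matrix(0, 2, 5)), "features")
})

test_that("training-order permutation barely perturbs predictions", {
  toy <- toy_clusters(n_per_class = 67, sep = 1, sd = 0.15, seed = 3)
  perm <- withr::with_seed(4, sample(nrow(toy$x)))
  m1 <- marble_svm(toy$x, toy$y, C = 64, gamma = 1)
  m2 <- marble_svm(toy$x[perm, ], toy$y[perm], C = 64, gamma = 1)
  probe <- toy_clusters(n_per_class = 67, sep = 1, sd = 0.15, seed = 5)$x
  expect_lt(mean(predict(m1, probe) != predict(m2, probe)), 0.01)
})

test_that("validation CR is non-decreasing in class separation", {
  crs <- sapply(c(0.3, 1, 3), function(sep) {
    tr <- toy_clusters(40, sep = sep, sd = 0.25, seed = 6)
    va <- toy_clusters(40, sep = sep, sd = 0.25, seed = 7)
    m <- marble_svm(tr$x, tr$y, C = 64, gamma = 1)
    100 * mean(predict(m, va$x) == va$y)
  })
  expect_true(all(diff(crs) >= 0))
})

test_that("a saved model predicts identically after reloading", {
  toy <- toy_clusters(20, seed = 8)
  m <- marble_svm(toy$x, toy$y)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  probe <- toy_clusters(30, sd = 0.4, seed = 9)$x
  expect_identical(predict(m, probe), predict(m2, probe))
})

test_that("grid search scores the printed lattice and breaks ties low", {
  tr <- toy_clusters(15, sep = 1.5, sd = 0.01, seed = 10)
  va <- toy_clusters(15, sep = 1.5, sd = 0.01, seed = 11)
  g <- grid_search(tr$x, tr$y, va$x, va$y)
  expect_equal(nrow(g$table), 25)
  expect_setequal(unique(g$table$C), c(16, 32, 64, 128, 256))
  expect_setequal(unique(g$table$gamma), c(0.25, 0.5, 1, 2, 4))
  # trivially separable data: every lattice point is perfect, so the
  # tie-break returns the smallest pair
  expect_true(all(g$table$block_cr == 100))
  expect_equal(c(g$best_C, g$best_gamma), c(16, 0.25))
  expect_error(grid_search(tr$x, tr$y, va$x, va$y, C_values = numeric(0)),
               "nonempty")
})

test_that("one-vs-one voting agrees with an independent kernel machine", {
  skip_if_not_installed("kernlab")
  toy <- toy_clusters(30, sep = 1.5, sd = 0.05, seed = 12)
  m <- marble_svm(toy$x, toy$y, C = 64, gamma = 1)
  ref <- kernlab::ksvm(toy$x, toy$y, type = "C-svc",
                       kernel = "rbfdot",
                       kpar = list(sigma = 1), C = 64, scaled = FALSE)
  probe <- toy_clusters(50, sep = 1.5, sd = 0.2, seed = 13)$x
  # scale the probe the same way before handing it to the reference
  agree <- mean(predict(m, probe) ==
                  kernlab::predict(ref, probe))
  expect_gt(agree, 0.95)
})
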