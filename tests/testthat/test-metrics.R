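counts_to_labels <- function(w, r, f) {
  beef_class(rep(c("wagyu", "regular", "fat_injected"), c(w, r, f)))
}

test_that("majority vote follows plurality with the priority tie-break", {
  expect_equal(as.character(vote_image(counts_to_labels(10, 10, 16))$final),
               "fat_injected")
  v <- vote_image(counts_to_labels(12, 12, 12))
  expect_equal(as.character(v$final), "fat_injected")  # three-way tie
  expect_true(v$tie)
  expect_equal(as.character(vote_image(counts_to_labels(15, 15, 6))$final),
               "regular")                              # W/R tie -> regular
  expect_error(vote_image(character(0)), "empty")
})

test_that("vote is permutation-invariant and exhaustive over 36 blocks", {
  labs <- counts_to_labels(7, 9, 20)
  perm <- withr::with_seed(1, sample(36))
  expect_equal(vote_image(labs)$final, vote_image(labs[perm])$final)

  # independent oracle: maximal count, ties resolved by fixed priority
  oracle <- function(w, r, f) {
    cnt <- c(fat_injected = f, regular = r, wagyu = w)  # priority order
    names(cnt)[which.max(cnt)]
  }
  for (w in 0:36) for (r in 0:(36 - w)) {
    f <- 36 - w - r
    expect_equal(as.character(vote_image(counts_to_labels(w, r, f))$final),
                 oracle(w, r, f),
                 info = sprintf("counts (%d, %d, %d)", w, r, f))
  }
})

test_that("block metrics reproduce the hand-evaluated confusion table", {
  truth <- counts_to_labels(10, 10, 10)
  pred <- truth
  pred[1] <- "fat_injected"       # one wagyu -> injected
  pred[11] <- "fat_injected"      # one regular -> injected
  pred[21:22] <- "regular"        # two injected -> regular
  m <- block_metrics(pred, truth)
  expect_equal(m$alpha, 10)                   # 2 / 20
  expect_equal(m$recall, 80)                  # 8 / 10
  expect_equal(m$precision, 80)               # 8 / 10
  expect_equal(m$cr, 100 * 26 / 30, tolerance = 1e-9)
  expect_equal(m$f1, 80)
  expect_equal(m$level, "block")

  perfect <- block_metrics(truth, truth)
  expect_equal(perfect$alpha, 0)
  expect_equal(perfect$recall, 100)
  expect_equal(perfect$cr, 100)
})

test_that("zero denominators yield explicit NA with a warning", {
  truth <- counts_to_labels(5, 5, 5)
  pred <- counts_to_labels(15, 0, 0)          # everything wagyu
  expect_warning(m <- block_metrics(pred, truth), "precision undefined")
  expect_equal(m$recall, 0)
  expect_true(is.na(m$precision))
  expect_true(is.na(m$f1))
  # no injected truth at all: recall and precision are both undefined
  w <- capture_warnings(m2 <- block_metrics(counts_to_labels(4, 4, 0),
                                            counts_to_labels(4, 4, 0)))
  expect_true(any(grepl("detection rate undefined", w)))
  expect_true(any(grepl("precision undefined", w)))
  expect_true(is.na(m2$recall))
  expect_error(block_metrics(truth[1:3], truth), "lengths differ")
})

test_that("image metrics match direct evaluation of the rate formulas", {
  # 120 test images, 40 per class; 2 non-injected misjudged as injected,
  # 38/40 injected detected
  truth <- counts_to_labels(40, 40, 40)
  pred <- truth
  pred[1] <- "fat_injected"; pred[41] <- "fat_injected"
  pred[81:82] <- "wagyu"
  m <- image_metrics(pred, truth)
  expect_equal(m$alpha, 2.5)                  # 2 / 80
  expect_equal(m$recall, 95)                  # 38 / 40
  expect_equal(m$level, "image")
  # symmetric harmonic mean
  expect_equal(2 * 95 * 95 / (95 + 95), 95)
})

test_that("CR equals the confusion-matrix trace over its total", {
  withr::with_seed(2, {
    truth <- beef_class(sample(1:3, 200, replace = TRUE))
    pred <- beef_class(sample(1:3, 200, replace = TRUE))
  })
  m <- block_metrics(pred, truth)
  cm <- m$confusion
  expect_equal(m$cr, 100 * sum(diag(cm)) / sum(cm))
  # alpha's denominator counts only truly non-injected items
  expect_equal(m$alpha,
               100 * sum(cm[c("wagyu", "regular"), "fat_injected"]) /
                 sum(cm[c("wagyu", "regular"), ]))
})

test_that("metrics tidy/glance expose all five rates", {
  truth <- counts_to_labels(10, 10, 10)
  m <- block_metrics(truth, truth)
  td <- tidy(m)
  expect_equal(td$metric, c("alpha", "recall", "precision", "cr", "f1"))
  expect_equal(glance(m)$cr, 100)
  path <- withr::local_tempfile(fileext = ".json")
  write_metrics(m, path, config = list(block_size = 80))
  j <- jsonlite::read_json(path)
  expect_equal(j$cr, 100)
  expect_equal(j$config$block_size, 80)
})
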