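px <- function(r, g, b) array(c(r, g, b), c(1, 1, 3))

test_that("colour-space conversion handles the canonical pixels", {
  gray <- convert_colorspace(px(128, 128, 128), "hsv")
  expect_equal(gray[1, 1, 2], 0)            # achromatic: S = 0
  expect_equal(gray[1, 1, 3], 128)          # V = 128
  red <- convert_colorspace(px(255, 0, 0), "hsv")
  expect_equal(red[1, 1, ], c(0, 255, 255))
  rgb_id <- convert_colorspace(px(10, 20, 30), "rgb")
  expect_equal(rgb_id[1, 1, ], c(10, 20, 30))
  expect_error(convert_colorspace(px(1, 2, 3), "xyz"))
})

test_that("HSV and Lab agree with scalar textbook conversions", {
  pixels <- list(c(200, 80, 60), c(12, 200, 33), c(60, 60, 200),
                 c(255, 255, 0), c(5, 5, 5), c(240, 180, 160))
  for (p in pixels) {
    got_hsv <- convert_colorspace(px(p[1], p[2], p[3]), "hsv")[1, 1, ]
    ref <- oracle_hsv(p)
    expect_equal(got_hsv[1], ref[["h"]] * 255 / 360, tolerance = 1e-6)
    expect_equal(got_hsv[2], ref[["s"]] * 255, tolerance = 1e-6)
    expect_equal(got_hsv[3], ref[["v"]] * 255, tolerance = 1e-6)
    # absolute slack 0.5 on the 0-255 scale: the installed converter and
    # the textbook matrix round the D65 chromaticities differently
    got_lab <- convert_colorspace(px(p[1], p[2], p[3]), "lab")[1, 1, ]
    ref_lab <- oracle_lab(p)
    expect_lt(abs(got_lab[1] - ref_lab[["L"]] * 255 / 100), 0.5)
    expect_lt(abs(got_lab[2] - (ref_lab[["a"]] + 128)), 0.5)
    expect_lt(abs(got_lab[3] - (ref_lab[["b"]] + 128)), 0.5)
  }
})

test_that("colour statistics match closed forms and a brute-force oracle", {
  flat <- array(77, c(8, 8, 3))
  st <- color_stats(flat, "rgb")
  expect_equal(unlist(st[, c("mu_1", "mu_2", "mu_3")]), c(77, 77, 77),
               ignore_attr = TRUE)
  expect_equal(unlist(st[, c("sd_1", "sd_2", "sd_3")]), c(0, 0, 0),
               ignore_attr = TRUE)

  # half 0 / half 255 in one channel: mu = sigma = 127.5
  two <- array(100, c(4, 4, 3))
  two[, 1:2, 1] <- 0; two[, 3:4, 1] <- 255
  st2 <- color_stats(two, "rgb")
  expect_equal(st2$mu_1, 127.5)
  expect_equal(st2$sd_1, 127.5)

  blk <- random_block(80, seed = 11)
  st3 <- color_stats(blk, "rgb")
  n <- 80 * 80
  for (ch in 1:3) {
    acc <- 0; acc2 <- 0
    v <- as.vector(blk[, , ch])
    for (val in v) { acc <- acc + val; acc2 <- acc2 + val^2 }
    mu <- acc / n; sig <- sqrt(acc2 / n - mu^2)
    expect_equal(st3[[paste0("mu_", ch)]], mu, tolerance = 1e-9)
    expect_equal(st3[[paste0("sd_", ch)]], sig, tolerance = 1e-9)
  }
  expect_error(color_stats(array(0, c(0, 4, 3)), "rgb"), "empty")
})

test_that("channel shift moves the mean and leaves the sd alone", {
  blk <- random_block(16, seed = 2)
  blk[, , 2] <- pmin(blk[, , 2], 200)      # headroom for the shift
  shifted <- blk; shifted[, , 2] <- shifted[, , 2] + 40
  a <- color_stats(blk, "rgb"); b <- color_stats(shifted, "rgb")
  expect_equal(b$mu_2, a$mu_2 + 40)
  expect_equal(b$sd_2, a$sd_2, tolerance = 1e-12)
})

test_that("statistics are invariant to pixel shuffling", {
  blk <- random_block(12, seed = 3)
  perm <- withr::with_seed(4, sample(144))
  shuf <- blk
  for (ch in 1:3) shuf[, , ch] <- matrix(as.vector(blk[, , ch])[perm], 12, 12)
  for (cs in c("rgb", "hsv", "lab")) {
    expect_equal(color_stats(shuf, cs), color_stats(blk, cs),
                 tolerance = 1e-12)
  }
})

test_that("generated phenotypes show the expected colour orderings", {
  mask <- ellipse_mask(960, 720, 0.75)
  blocks <- valid_blocks(mask, 80)
  specs <- default_phenotypes()
  sig_by_class <- sapply(names(specs), function(cl) {
    img <- synth_image(specs[[cl]], seed = 301)$image
    st <- dplyr::bind_rows(lapply(seq_len(nrow(blocks)), function(i) {
      b <- img[(blocks$y[i] + 1):(blocks$y[i] + 80),
               (blocks$x[i] + 1):(blocks$x[i] + 80), , drop = FALSE]
      color_stats(b, "rgb")
    }))
    # red dominates in every class
    expect_true(all(st$mu_1 > st$mu_2), label = paste(cl, "mu_R > mu_G"))
    expect_true(all(st$mu_1 > st$mu_3), label = paste(cl, "mu_R > mu_B"))
    mean(c(st$sd_1, st$sd_2, st$sd_3))
  })
  expect_lt(sig_by_class[["regular"]], sig_by_class[["wagyu"]])
  expect_lt(sig_by_class[["regular"]], sig_by_class[["fat_injected"]])
})
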