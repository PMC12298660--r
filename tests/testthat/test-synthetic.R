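specs <- default_phenotypes()

test_that("identical (spec, seed) renders bit-identical images", {
  a <- synth_image(specs$fat_injected, 99)
  b <- synth_image(specs$fat_injected, 99)
  expect_identical(a$image, b$image)
  expect_identical(a$fat_mask, b$fat_mask)
  c <- synth_image(specs$fat_injected, 100)
  expect_false(identical(a$image, c$image))
})

test_that("rendered fat fraction lands in the phenotype range", {
  for (cl in names(specs)) {
    lo <- specs[[cl]]$fat_fraction_range[1]
    hi <- specs[[cl]]$fat_fraction_range[2]
    for (seed in c(11, 12, 13)) {
      fr <- synth_image(specs[[cl]], seed)$fat_fraction
      expect_gte(fr, lo - 0.02)
      expect_lte(fr, hi + 0.02)
    }
  }
})

test_that("infeasible phenotypes are rejected", {
  bad <- phenotype_spec("wagyu", c(180, 70, 65), c(10, 8, 8),
                        fat_fraction_range = c(0.5, 0.6),
                        fleck_count_range = c(1, 2),
                        elongation_range = c(1, 2))
  expect_error(synth_image(bad, 1), "infeasible")
})

test_that("wagyu fat is more fragmented than injected fat", {
  cc_count <- function(cl, seed) {
    m <- synth_image(specs[[cl]], seed)$fat_mask
    lab <- EBImage::bwlabel(EBImage::Image(t(m)))
    max(lab)
  }
  seeds <- 201:208
  wagyu_cc <- sapply(seeds, function(s) cc_count("wagyu", s))
  inj_cc <- sapply(seeds, function(s) cc_count("fat_injected", s))
  expect_gt(stats::median(wagyu_cc), stats::median(inj_cc))
})

test_that("rendered fat is brighter than the lean background", {
  sb <- synth_image(specs$wagyu, 77)
  g <- to_grayscale(sb$image)
  roi <- mask_raster(ellipse_mask())
  lean_p90 <- stats::quantile(g[roi & !sb$fat_mask], 0.9)
  expect_gt(mean(g[sb$fat_mask & roi] > lean_p90), 0.95)
})

test_that("brightness ladder follows mu + 1.5 k sigma", {
  lv <- brightness_levels()
  expect_length(lv, 7)
  expect_equal(unname(lv[["0"]]), 98.91)
  expect_equal(unname(lv[["-1"]]), 72.94)
  expect_equal(unname(lv[["3"]]), 176.82)   # 98.91 + 3 * (98.91 - 72.94)
  expect_equal(unname(diff(lv)), rep(98.91 - 72.94, 6))
  custom <- brightness_levels(mu = 100, sigma = 10)
  expect_equal(unname(custom), 100 + 1.5 * (-3:3) * 10)
})

test_that("brightness adjustment hits the target ROI mean", {
  sb <- synth_image(specs$regular, 55)
  roi <- mask_raster(ellipse_mask())
  for (k in c(-2, 0, 1)) {
    target <- brightness_levels()[[as.character(k)]]
    out <- perturb_image(sb$image, "brightness", brightness_k = k)
    expect_lt(abs(mean(to_grayscale(out)[roi]) - target), 1.0)
  }
})

test_that("label occlusion covers the requested ROI fraction", {
  sb <- synth_image(specs$wagyu, 56)
  roi <- mask_raster(ellipse_mask())
  out <- perturb_image(sb$image, "label", occlusion_fraction = 0.05,
                       seed = 42)
  changed <- (out[, , 1] != sb$image[, , 1]) |
    (out[, , 2] != sb$image[, , 2]) | (out[, , 3] != sb$image[, , 3])
  occ <- sum(changed & roi) / sum(roi)
  expect_lt(abs(occ - 0.05), 0.005)
  expect_error(perturb_image(sb$image, "label", occlusion_fraction = 0.4),
               "occlusion_fraction")
})

test_that("reflections brighten without leaving the frame", {
  sb <- synth_image(specs$regular, 57)
  out <- perturb_image(sb$image, "reflection", seed = 3)
  expect_true(all(out >= 0 & out <= 255))
  expect_gt(mean(out), mean(sb$image))      # glare only adds light
})

test_that("zero tilt is the identity and tilt is seed-free deterministic", {
  sb <- synth_image(specs$wagyu, 58)
  expect_identical(perturb_image(sb$image, "tilt", tilt_angle = 0),
                   sb$image)
  t1 <- perturb_image(sb$image, "tilt", tilt_angle = 8,
                      tilt_direction = "left")
  t2 <- perturb_image(sb$image, "tilt", tilt_angle = 8,
                      tilt_direction = "left")
  expect_identical(t1, t2)
  expect_false(identical(t1, sb$image))
  expect_error(perturb_image(sb$image, "smudge"))
})

test_that("dataset manifests are balanced, disjoint and seeded", {
  d <- generate_dataset(200, seed = 3)
  tab <- table(d$class, d$split)
  expect_true(all(tab[, "train"] == 120))
  expect_true(all(tab[, "validation"] == 40))
  expect_true(all(tab[, "test"] == 40))
  d2 <- generate_dataset(80, split = c(train = 0.5, validation = 0.25,
                                       test = 0.25), seed = 3)
  tab2 <- table(d2$class, d2$split)
  expect_true(all(tab2[, "train"] == 40))
  expect_true(all(tab2[, "validation"] == 20))
  expect_true(all(tab2[, "test"] == 20))
  expect_equal(anyDuplicated(d$image_id), 0)
  # same seed, same manifest; different seed, different images
  expect_identical(generate_dataset(10, seed = 5), generate_dataset(10, seed = 5))
  a <- generate_dataset(10, seed = 5); b <- generate_dataset(10, seed = 6)
  expect_false(identical(a$image_seed, b$image_seed))
  expect_identical(dim(a), dim(b))
  expect_error(generate_dataset(10, split = c(train = 0.5, validation = 0.2,
                                              test = 0.2)),
               "sum to 1")
})

test_that("a manifest image renders through render_image", {
  d <- generate_dataset(4, split = c(train = 0.5, validation = 0.25,
                                     test = 0.25), seed = 9)
  sb <- render_image(d, d$image_id[1])
  expect_s3_class(sb, "synth_beef")
  expect_equal(dim(sb$image), c(720, 960, 3))
  expect_equal(as.character(d$class[1]), sb$class)
  expect_error(render_image(d, "nope"), "unknown image_id")
})
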