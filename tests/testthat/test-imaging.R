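test_that("k-means segmentation separates solid colors exactly", {
  pal <- default_palette()
  img <- array(0, c(20, 20, 3))
  for (ch in 1:3) {
    img[, 1:10, ch] <- pal["fibrous", ch]
    img[, 11:20, ch] <- pal["background", ch]
  }
  lm <- segment_kmeans(img, k = 2, seed = 1)
  expect_true(all(lm$labels[, 1:10] == 1L))
  expect_true(all(lm$labels[, 11:20] == 0L))
  expect_error(segment_kmeans(img, k = 5, seed = 1), "distinct colors")
})

test_that("noiseless phantoms are recovered exactly by both routes", {
  ph <- generate_phantom(small_phantom_spec(noise_sd = 0))
  lab_true <- ph$labelmap$labels
  lm_lab <- segment_lab_nearest(ph$image, um_per_px = 40)
  expect_identical(lm_lab$labels, lab_true)
  k <- length(unique(as.vector(lab_true)))
  lm_km <- segment_kmeans(ph$image, k = k, seed = 1, um_per_px = 40)
  expect_identical(lm_km$labels, lab_true)
  expect_identical(lm_km$labels, lm_lab$labels)
})

test_that("segmentation is idempotent on its own rendering", {
  ph <- generate_phantom(small_phantom_spec(noise_sd = 0))
  lm1 <- segment_lab_nearest(ph$image, um_per_px = 40)
  img2 <- render_labels(lm1)
  lm2 <- segment_lab_nearest(img2, um_per_px = 40)
  expect_identical(lm1$labels, lm2$labels)
})

test_that("noisy phantoms segment with high per-class Dice", {
  ph <- generate_phantom(small_phantom_spec(seed = 2, noise_sd = 8))
  lm <- segment_kmeans(ph$image, k = 6, seed = 1, um_per_px = 40)
  for (cls in 0:4) {
    d <- dice_coefficient(lm$labels, ph$labelmap$labels, cls)
    expect_gte(d, 0.95)
  }
})

test_that("nearest-prototype ties break to the lowest class index", {
  pal <- default_palette()
  pal["cellular", ] <- pal["fibrous", ]  # two identical prototypes
  proto <- color_prototypes(pal)
  img <- array(rep(pal["fibrous", ], each = 4), c(2, 2, 3))
  lm <- segment_lab_nearest(img, proto)
  expect_true(all(lm$labels == 1L))  # fibrous (1) beats cellular (2)
})

test_that("stain thresholding matches its construction", {
  expect_equal(percent_positive(
    threshold_stain(array(1, c(8, 8, 3)), "nova_red")), 0)

  # paint the canonical positive color on exactly 10% of pixels
  thr <- default_stain_thresholds()
  img <- array(1, c(10, 10, 3))
  pos_idx <- cbind(rep(1, 10), 1:10)
  for (ch in 1:3) {
    m <- img[, , ch]
    m[pos_idx] <- thr$nova_red$color[ch]
    img[, , ch] <- m
  }
  pmap <- threshold_stain(img, "nova_red")
  expect_equal(percent_positive(pmap), 0.10)

  # masked region excluded from numerator and denominator
  mask <- matrix(TRUE, 10, 10)
  mask[1, ] <- FALSE  # mask out the positive row
  pmasked <- threshold_stain(img, "nova_red", mask = mask)
  expect_equal(percent_positive(pmasked), 0)
  expect_equal(sum(!is.na(pmasked)), 90)

  expect_error(threshold_stain(img, "unknown_stain"), "unknown_stain")
})

test_that("percent positive handles edge cases and is rotation invariant", {
  pos <- matrix(0L, 10, 10)
  pos[1:3, 1] <- 1L
  mask <- matrix(TRUE, 10, 10)
  expect_equal(percent_positive(pos, mask), 0.03)
  expect_true(is.nan(percent_positive(pos, matrix(FALSE, 10, 10))))
  expect_equal(percent_positive(matrix(1L, 4, 4)), 1)

  rot90 <- function(m) t(m)[, nrow(m):1]
  expect_equal(percent_positive(pos, mask),
               percent_positive(rot90(pos), rot90(mask)))
})
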