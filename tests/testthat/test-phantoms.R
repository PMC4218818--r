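test_that("phantom generation is deterministic and validates its inputs", {
  spec <- small_phantom_spec(seed = 4, noise_sd = 8)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$image, b$image)
  expect_identical(a$labelmap$labels, b$labelmap$labels)
  expect_identical(a$geometry$lumen, b$geometry$lumen)

  expect_error(phantom_spec(lumen_radius_um = 2000, iel_radius_um = 1800),
               "radii ordering")
  expect_error(phantom_spec(compression_ratio = 0), "compression_ratio")
  expect_error(phantom_spec(lumen_eccentricity_um = 900), "strictly inside")
  expect_error(phantom_spec(calcification_fraction = 1), "calcification")
})

test_that("phantom composition and geometry follow the construction rules", {
  # no calcified pixels when the calcification fraction is zero
  ph0 <- generate_phantom(small_phantom_spec(calcification_fraction = 0))
  expect_false(any(ph0$labelmap$labels == 4L))
  expect_true(all(ph0$labelmap$labels %in% 0:4))

  # compression shrinks the lumen x-extent by the stated ratio
  phc <- generate_phantom(small_phantom_spec(compression_ratio = 0.7))
  bb <- apply(phc$geometry$lumen, 2, function(v) diff(range(v)))
  expect_equal(bb[1] / bb[2], 0.7, tolerance = 1e-6)

  # polygonization bound on the generated lumen area
  spec <- small_phantom_spec(compression_ratio = 0.7)
  expect_gte(polygon_area(phc$geometry$lumen),
             pi * (spec$lumen_radius_um * spec$compression_ratio)^2 * 0.95)

  # uncompressed lumen is a circle up to polygonization
  ph1 <- generate_phantom(small_phantom_spec())
  sig <- radius_signature(ph1$geometry$lumen, 90L)
  expect_lt(diff(range(sig)) / mean(sig), 1e-3)
})

test_that("lame phantom is a homogeneous concentric annulus", {
  lp <- lame_phantom(1000, 2000, 5e5)
  lab <- lp$labelmap$labels
  # tissue fraction of the disc of radius b equals (b^2 - a^2)/b^2 = 0.75
  upp <- lp$labelmap$um_per_px
  n <- nrow(lab)
  x <- ((1:n) - 0.5) * upp
  ctr <- n / 2 * upp
  r <- sqrt(outer(rep(1, n), x - ctr)^2 + outer(x - ctr, rep(1, n))^2)
  inside_b <- r <= 2000
  expect_equal(sum(lab[inside_b] != 0) / sum(inside_b), 0.75, tolerance = 0.01)
  # single tissue class
  expect_identical(sort(unique(as.vector(lab))), c(0L, 1L))
  # concentric contours
  expect_lt(sqrt(sum((polygon_centroid(lp$geometry$lumen) -
                        polygon_centroid(lp$geometry$outer))^2)), 1e-6)
  expect_true(all(lp$materials$modulus_pa == 5e5))
  expect_error(lame_phantom(2000, 1000), "0 < a < b")
})

test_that("stain maps follow their Bernoulli model", {
  ph <- generate_phantom(small_phantom_spec())
  lm <- ph$labelmap

  zero <- generate_stain_map(lm, NULL,
                             stain_model("m", "uniform",
                                         list(baseline_positivity = 0)),
                             seed = 1)
  expect_true(all(zero == 0L))

  # uncoupled (beta = 0) strain-coupled model hits the baseline within 3
  # binomial standard deviations
  e <- matrix(0, nrow(lm$labels), ncol(lm$labels))
  p0 <- 0.1
  sm <- stain_model("m", "strain_coupled",
                    list(baseline_positivity = p0, coupling_beta = 0))
  pos <- generate_stain_map(lm, e, sm, seed = 2)
  n <- sum(lm$labels != 0)
  frac <- sum(pos) / n
  expect_lt(abs(frac - p0), 3 * sqrt(p0 * (1 - p0) / n))

  # background pixels always negative
  expect_true(all(pos[lm$labels == 0] == 0L))

  # positive coupling raises positivity in the top excursion decile over
  # the bottom decile (Monte Carlo over seeds)
  e2 <- matrix(rep(seq(-1, 3, length.out = ncol(lm$labels)),
                   each = nrow(lm$labels)), nrow(lm$labels))
  sm2 <- stain_model("m", "strain_coupled",
                     list(baseline_positivity = 0.1, coupling_beta = 2))
  wins <- vapply(1:10, function(s) {
    p <- generate_stain_map(lm, e2, sm2, seed = s)
    ev <- e2[lm$labels != 0]; pv <- p[lm$labels != 0]
    qs <- quantile(ev, c(0.1, 0.9))
    mean(pv[ev >= qs[2]]) > mean(pv[ev <= qs[1]])
  }, logical(1))
  expect_true(all(wins))

  # region restriction confines positives to the requested classes
  sr <- stain_model("m", "region_restricted",
                    list(baseline_positivity = 0.5, classes = "lipid_necrotic"))
  posr <- generate_stain_map(lm, NULL, sr, seed = 3)
  expect_true(all(lm$labels[posr == 1L] == 3L))

  expect_error(generate_stain_map(lm, matrix(0, 2, 2), sm, 1), "shape")
  expect_identical(generate_stain_map(lm, e, sm, seed = 9),
                   generate_stain_map(lm, e, sm, seed = 9))
})

test_that("stain positivity passes binomial goodness of fit across seeds", {
  lm <- generate_phantom(small_phantom_spec())$labelmap
  n <- sum(lm$labels != 0)
  p0 <- 0.1
  sm <- stain_model("m", "uniform", list(baseline_positivity = p0))
  pass <- vapply(1:100, function(s) {
    k <- sum(generate_stain_map(lm, NULL, sm, seed = s))
    x2 <- (k - n * p0)^2 / (n * p0) + ((n - k) - n * (1 - p0))^2 / (n * (1 - p0))
    pchisq(x2, df = 1, lower.tail = FALSE) >= 0.01
  }, logical(1))
  expect_gte(sum(pass), 95)
})
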