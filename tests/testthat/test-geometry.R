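test_that("radius signature matches analytic shapes", {
  circ <- plaquemech:::circle_polygon(c(0, 0), 100, 720)
  sig <- radius_signature(circ, 360L)
  expect_equal(mean(sig), 100, tolerance = 1e-4)
  expect_lt(diff(range(sig)), 0.1)

  th <- seq(0, 2 * pi, length.out = 721)[-721]
  ell <- cbind(100 * cos(th), 50 * sin(th))
  sige <- radius_signature(ell, 360L, center = c(0, 0))
  expect_equal(which.max(sige), 1L)              # angle 0 -> semi-major
  expect_equal(max(sige), 100, tolerance = 1e-3)
  expect_equal(sige[91], 50, tolerance = 1e-3)   # 90 degrees -> semi-minor
})

test_that("radius signature is equivariant under rotation", {
  th <- seq(0, 2 * pi, length.out = 241)[-241]
  poly <- cbind(80 * cos(th) + 10 * cos(3 * th), 60 * sin(th))
  n <- 120L
  sig <- radius_signature(poly, n, center = c(0, 0))
  k <- 17L
  a <- 2 * pi * k / n
  rot <- poly %*% rbind(c(cos(a), sin(a)), c(-sin(a), cos(a)))
  sig_rot <- radius_signature(rot, n, center = c(0, 0))
  expect_equal(sig_rot, sig[((seq_len(n) - 1 - k) %% n) + 1], tolerance = 1e-6)
})

test_that("rotation registration recovers known rotations", {
  th <- seq(0, 2 * pi, length.out = 241)[-241]
  poly <- cbind(100 * cos(th), 60 * sin(th))
  sig <- radius_signature(poly, 360L, center = c(0, 0))

  expect_equal(register_rotation(sig, sig)$angle_deg, 0)
  shifted <- sig[((seq_len(360) - 1 - 90) %% 360) + 1]
  expect_equal(register_rotation(sig, shifted)$angle_deg, 90)

  set.seed(11)
  for (i in 1:20) {
    ang <- runif(1, -180, 180)
    a <- ang * pi / 180
    rot <- poly %*% rbind(c(cos(a), sin(a)), c(-sin(a), cos(a)))
    sig_rot <- radius_signature(rot, 360L, center = c(0, 0))
    rec <- register_rotation(sig, sig_rot)$angle_deg
    # ellipse has a 180-degree symmetry; compare modulo 180
    d <- abs(((rec - ang + 90) %% 180) - 90)
    expect_lte(d, 1)
  }

  circ <- plaquemech:::circle_polygon(c(0, 0), 50, 360)
  r <- register_rotation(radius_signature(circ, 360L),
                         radius_signature(circ, 360L))
  expect_true(r$degenerate)
  expect_equal(r$angle_deg, 0)
})

test_that("registration is antisymmetric within one bin", {
  th <- seq(0, 2 * pi, length.out = 241)[-241]
  poly <- cbind(90 * cos(th) + 15 * cos(2 * th), 70 * sin(th))
  sig <- radius_signature(poly, 360L, center = c(0, 0))
  set.seed(5)
  for (i in 1:5) {
    k <- sample.int(359, 1)
    shifted <- sig[((seq_len(360) - 1 - k) %% 360) + 1]
    f <- register_rotation(sig, shifted)$angle_deg
    b <- register_rotation(shifted, sig)$angle_deg
    expect_lte(min(abs((f + b) %% 360), 360 - abs((f + b) %% 360)), 1)
  }
})

test_that("minimum enclosing circle agrees with brute force", {
  set.seed(7)
  for (i in 1:12) {
    n <- sample(5:50, 1)
    pts <- cbind(rnorm(n, sd = 50), rnorm(n, sd = 30))
    mec <- min_enclosing_circle(pts)
    oracle <- brute_min_circle(pts)
    expect_equal(mec$radius, oracle$radius, tolerance = 1e-6)
    d <- sqrt((pts[, 1] - mec$center[1])^2 + (pts[, 2] - mec$center[2])^2)
    expect_true(all(d <= mec$radius * (1 + 1e-9) + 1e-9))
  }
})

test_that("morphometry reproduces analytic fixtures", {
  ctr <- c(2560, 2560)
  lumen <- plaquemech:::circle_polygon(ctr, 1000, 360)
  iel <- plaquemech:::circle_polygon(ctr, 2000, 360)
  outer_c <- plaquemech:::circle_polygon(ctr, 2000.1, 360)
  lab <- annulus_labelmap(1000, 2000, 20, 256)
  geom <- vessel_geometry(lumen, iel, outer_c, um_per_px = 20)
  m <- morphometry(geom, lab)
  expect_equal(m$plaque_burden, 0.75, tolerance = 0.01)
  expect_lt(m$eccentricity, 1e-9)
  expect_equal(m$radius_um, 2000.1, tolerance = 1e-6)

  # offset lumen: eccentricity = 500 / min-circle radius 2500
  geom2 <- vessel_geometry(plaquemech:::circle_polygon(ctr + c(500, 0), 900, 360),
                           plaquemech:::circle_polygon(ctr, 2000, 360),
                           plaquemech:::circle_polygon(ctr, 2500, 360),
                           um_per_px = 20)
  expect_equal(morphometry(geom2)$eccentricity, 0.2, tolerance = 1e-6)

  # concentric media annulus 1800 -> 2000
  geom3 <- vessel_geometry(lumen, iel, plaquemech:::circle_polygon(ctr, 2500, 360),
                           media_inner = plaquemech:::circle_polygon(ctr, 1800, 360),
                           media_outer = plaquemech:::circle_polygon(ctr, 2000, 360),
                           um_per_px = 20)
  expect_equal(morphometry(geom3)$media_thickness_um, 200, tolerance = 0.5)

  expect_true(is.na(morphometry(geom)$media_thickness_um))
})

test_that("morphometry is scale equivariant", {
  ctr <- c(2560, 2560)
  geom <- vessel_geometry(plaquemech:::circle_polygon(ctr + c(300, 0), 800, 180),
                          plaquemech:::circle_polygon(ctr, 1900, 180),
                          plaquemech:::circle_polygon(ctr + c(100, 50), 2300, 180),
                          media_inner = plaquemech:::circle_polygon(ctr, 1900, 180),
                          media_outer = plaquemech:::circle_polygon(ctr, 2100, 180),
                          um_per_px = 20)
  m1 <- morphometry(geom)
  cc <- 2.5
  scale_poly <- function(p) p * cc
  geom2 <- vessel_geometry(scale_poly(geom$lumen), scale_poly(geom$iel),
                           scale_poly(geom$outer),
                           media_inner = scale_poly(geom$media_inner),
                           media_outer = scale_poly(geom$media_outer),
                           um_per_px = 20 * cc)
  m2 <- morphometry(geom2)
  expect_equal(m2$radius_um, cc * m1$radius_um, tolerance = 1e-9)
  expect_equal(m2$media_thickness_um, cc * m1$media_thickness_um,
               tolerance = 1e-9)
  expect_equal(m2$eccentricity, m1$eccentricity, tolerance = 1e-9)
})

test_that("near-lumen band matches the analytic annulus", {
  n <- 256; upp <- 1
  ctr <- c(n / 2, n / 2)
  lumen <- plaquemech:::circle_polygon(ctr, 100, 720)
  geom <- vessel_geometry(lumen,
                          plaquemech:::circle_polygon(ctr, 110, 360),
                          plaquemech:::circle_polygon(ctr, 120, 360),
                          um_per_px = upp)
  pos <- matrix(1L, n, n)
  band <- near_lumen_band(geom, 10, pos)
  expect_equal(band$n_band_total, pi * (110^2 - 100^2), tolerance = 0.03)
  expect_equal(band$fraction, 1)

  # exclusion mask: positives live only in the masked-out half
  pos2 <- matrix(0L, n, n)
  pos2[, 1:(n / 2)] <- 1L
  mask <- matrix(TRUE, n, n)
  mask[, 1:(n / 2)] <- FALSE
  band2 <- near_lumen_band(geom, 10, pos2, mask = mask)
  expect_equal(band2$fraction, 0)
  expect_error(near_lumen_band(geom, -5, pos), "positive")
})

test_that("contour tracing follows a low-cost boundary", {
  n <- 128; upp <- 2
  x <- ((1:n) - 0.5) * upp
  ctr <- n * upp / 2
  r <- sqrt(outer(rep(1, n), x - ctr)^2 + outer(x - ctr, rep(1, n))^2)
  cost <- 0.01 + abs(r - 80)
  th <- seq(0, 2 * pi, length.out = 5)[-5]
  wp <- cbind(ctr + 80 * cos(th), ctr + 80 * sin(th))
  poly <- trace_contour(cost, wp, upp)
  expect_equal(polygon_area(poly), pi * 80^2, tolerance = 0.02)

  # uniform cost: straight-line connections between waypoints
  tri_wp <- rbind(c(40, 40), c(200, 40), c(40, 200))
  ptri <- trace_contour(matrix(1, n, n), tri_wp, upp)
  expect_equal(polygon_area(ptri), 0.5 * 160 * 160, tolerance = 0.05)

  expect_error(trace_contour(matrix(1, n, n), tri_wp[1:2, ], upp),
               "3 waypoints")
  expect_error(trace_contour(matrix(0, n, n), tri_wp, upp), "positive")
})
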