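small_fem <- function(seed = 1, budget = 400L) {
  ph <- generate_phantom(small_phantom_spec(seed = seed))
  geom <- ph$geometry
  area <- polygon_area(geom$outer) - polygon_area(geom$lumen)
  mesh <- mesh_domain(geom, target_element_area_um2 = area / budget)
  emod <- assign_moduli(mesh, ph$labelmap)
  list(fem = solve_inflation(fe_model(mesh, emod)), phantom = ph)
}

test_that("marker attachment respects footprints, masks and rotation", {
  sf <- small_fem()
  fem <- sf$fem
  dimpx <- dim(sf$phantom$labelmap$labels)
  upp <- sf$phantom$labelmap$um_per_px

  # a single positive pixel at an element's centroid marks exactly that
  # element positive
  idmap <- rasterize_element_values(fem$mesh, seq_len(nrow(fem$mesh$tri)),
                                    dimpx, upp)
  target <- as.integer(names(which.max(table(idmap))))
  cent <- fem$mesh$centroids[target, ]
  pos <- matrix(0L, dimpx[1], dimpx[2])
  pos[round(cent[2] / upp + 0.5), round(cent[1] / upp + 0.5)] <- 1L
  obs <- attach_markers(fem, pos, upp)
  expect_true(obs$positive[obs$element_id == target])
  expect_equal(sum(obs$positive), 1L)

  # all-negative raster
  obs0 <- attach_markers(fem, matrix(0L, dimpx[1], dimpx[2]), upp)
  expect_false(any(obs0$positive))

  # rotating the raster by 90 degrees and registering with -90 restores the
  # unrotated observations (interior elements; 90-degree NN rotation exact)
  rot <- rotate_raster(pos, 90, fem$mesh$center, upp)
  obs_rot <- attach_markers(fem, rot, upp, rotation_deg = -90)
  expect_identical(obs_rot$positive, obs$positive)

  # fully masked-out elements are dropped
  posm <- matrix(NA_integer_, dimpx[1], dimpx[2])
  expect_error(attach_markers(fem, posm, upp), "no overlap")
})

test_that("excursion binning matches the stated pooling rule", {
  e <- c(-0.5, -0.1, 0.0, 0.1, 0.3, 0.4, 0.5, 0.6, 0.7, 0.9)
  obs <- data.frame(strain_excursion = e, stress_excursion = e,
                    positive = rep(c(TRUE, FALSE), 5))
  suppressWarnings(b <- bin_by_excursion(obs, "strain", "tertile"))
  tab <- b$table
  expect_equal(tab$n, c(4L, 2L, 2L, 2L))
  expect_equal(tab$e_max[1], 0.1)
  expect_equal(unname(unlist(tab[tab$bin == 1, c("e_min", "e_max")])),
               c(0.3, 0.4))
  expect_equal(unname(unlist(tab[tab$bin == 3, c("e_min", "e_max")])),
               c(0.7, 0.9))

  # all below the cut is an error path
  low <- data.frame(strain_excursion = seq(-0.5, 0.2, length.out = 50),
                    stress_excursion = 0, positive = FALSE)
  expect_error(bin_by_excursion(low, "strain", "tertile"), "baseline")

  # bin sizes differ by at most one
  set.seed(2)
  big <- data.frame(strain_excursion = rnorm(517, 0.5, 0.5),
                    stress_excursion = 0,
                    positive = runif(517) < 0.2)
  bd <- bin_by_excursion(big, "strain", "decile")
  sizes <- bd$table$n[bd$table$bin > 0]
  expect_lte(diff(range(sizes)), 1L)
  expect_equal(sum(bd$table$n), 517L)
})

test_that("chi-squared gate and two-proportion post hocs are correct", {
  # 3 bins + baseline with constructed counts
  mk_obs <- function(fracs, n_each = 100, n_base = 100, base_frac = 0.10) {
    e <- c(seq(-0.5, 0.2, length.out = n_base),
           rep(seq(0.3, 0.9, length.out = length(fracs)), each = n_each))
    pos <- c(runif(n_base) < 0, rep(FALSE, n_each * length(fracs)))
    pos[1:(n_base * base_frac)] <- TRUE
    for (i in seq_along(fracs)) {
      idx <- n_base + (i - 1) * n_each + seq_len(n_each * fracs[i])
      pos[idx] <- TRUE
    }
    data.frame(strain_excursion = e, stress_excursion = e, positive = pos)
  }
  obs <- mk_obs(c(0.30, 0.10, 0.10))
  b <- bin_by_excursion(obs, "strain", "tertile")
  res <- test_association(b, bonferroni_m = 4)

  # oracle: chi-squared on the same contingency table
  tab <- cbind(res$table$n_pos, res$table$n - res$table$n_pos)
  chis <- chisq.test(tab, correct = FALSE)
  expect_equal(res$chisq$statistic, unname(chis$statistic))
  expect_equal(res$chisq$p, unname(chis$p.value))

  # pooled two-proportion z for 30/100 vs 10/100 (hand-derived)
  z1 <- res$posthoc$z[res$posthoc$bin == 1]
  expect_equal(z1, 0.20 / sqrt(0.20 * 0.80 * (1 / 100 + 1 / 100)),
               tolerance = 1e-12)
  expect_equal(z1, 3.5355, tolerance = 1e-4)
  expect_equal(res$posthoc$p_raw[res$posthoc$bin == 1], 4.066e-4,
               tolerance = 1e-3)
  expect_equal(res$posthoc$p_adj, pmin(1, res$posthoc$p_raw * 4))

  # identical fractions: chi-squared p = 1, no post hoc run
  flat <- mk_obs(c(0.10, 0.10, 0.10))
  bf <- test_association(bin_by_excursion(flat, "strain", "tertile"))
  expect_gt(bf$chisq$p, 0.99)
  expect_null(bf$posthoc)

  # invariance under observation reordering
  perm <- obs[sample.int(nrow(obs)), ]
  res2 <- test_association(bin_by_excursion(perm, "strain", "tertile"),
                           bonferroni_m = 4)
  expect_equal(res2$table, res$table)
  expect_equal(res2$posthoc, res$posthoc)
})

test_that("phenotype comparison runs ANOVA with Tukey and Bonferroni", {
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3), d = c(1, 2, 3))
  cmp <- compare_phenotypes(g)
  expect_equal(cmp$f, 0)
  expect_false(any(cmp$pairs$significant))
  expect_equal(nrow(cmp$pairs), 6L)

  g2 <- list(a = c(0, 0, 0, 0) + c(0, 1e-3, -1e-3, 0),
             b = c(0, 0, 0, 0) + c(1e-3, 0, 0, -1e-3),
             c = c(0, 0, 0, 0) + c(0, -1e-3, 1e-3, 0),
             d = c(10, 10, 10, 10) + c(1e-3, -1e-3, 0, 0))
  cmp2 <- compare_phenotypes(g2)
  sig_pairs <- cmp2$pairs$pair[cmp2$pairs$significant]
  expect_length(sig_pairs, 3L)
  expect_true(all(grepl("d", sig_pairs)))

  # two-group degenerate call: F equals t^2
  g3 <- list(a = c(1.2, 0.8, 1.1, 0.9), b = c(2.1, 1.8, 2.2, 1.9))
  cmp3 <- compare_phenotypes(g3)
  tt <- t.test(g3$a, g3$b, var.equal = TRUE)
  expect_equal(cmp3$f, unname(tt$statistic)^2, tolerance = 1e-9)

  expect_error(compare_phenotypes(list(a = c(1, 1), b = c(1, 1))),
               "zero")
  expect_error(compare_phenotypes(list(a = 1:3)), "at least 2 groups")
})

test_that("strain-coupled staining dissociates from stress at weak coupling", {
  # frozen witness: stain coupled to strain excursion only; the strain
  # association is detected while the stress association stays below the
  # chi-squared gate (the pattern reported for vulnerable lesions)
  cfg <- run_config(preinflate_iters = 0L, element_budget = 1500L)
  ph <- generate_phantom(phantom_spec(seed = 3, coupling_beta = 0.25,
                                      noise_sd = 8))
  res <- plaquemech:::analyse_phantom(ph, cfg, coupling_beta = 0.25,
                                      stain_seed = 10)
  expect_lt(res$associations$marker$strain$chisq$p, 0.05)
  expect_gt(res$associations$marker$stress$chisq$p, 0.05)
})
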