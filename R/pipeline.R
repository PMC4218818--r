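# End-to-end orchestration: configuration, single-specimen analysis, and
# the all-synthetic phantom study that exercises every stage.

#' Pipeline configuration
#'
#' Scalar constants and stage options for the full analysis. Defaults
#' follow the study conditions: +40 mmHg incremental pressure, 10
#' pre-inflation iterations, baseline excursion cut 0.25.
#'
#' @param um_per_px Raster scale, micrometres per pixel.
#' @param materials A [material_table()].
#' @param pressure_mmhg Incremental luminal pressure (mmHg).
#' @param preinflate_iters Pre-inflation iterations (0 disables).
#' @param baseline_cut Baseline excursion threshold.
#' @param scheme Binning scheme, "decile" or "tertile".
#' @param bonferroni_m Post-hoc Bonferroni factor (NULL = scheme default).
#' @param element_budget Approximate number of mesh elements.
#' @param segmentation "lab_nearest" or "kmeans".
#' @param k Number of k-means clusters when segmentation = "kmeans".
#' @param seed Base RNG seed.
#' @param alpha Significance level.
#' @return Object of class `run_config`.
#' @export
run_config <- function(um_per_px = 20, materials = material_table(),
                       pressure_mmhg = 40, preinflate_iters = 10L,
                       baseline_cut = 0.25, scheme = c("decile", "tertile"),
                       bonferroni_m = NULL, element_budget = 5000L,
                       segmentation = c("lab_nearest", "kmeans"), k = 6L,
                       seed = 1L, alpha = 0.05) {
  scheme <- match.arg(scheme)
  segmentation <- match.arg(segmentation)
  stopifnot(pressure_mmhg > 0, preinflate_iters >= 0, element_budget >= 64)
  structure(list(um_per_px = um_per_px, materials = materials,
                 pressure_mmhg = pressure_mmhg,
                 preinflate_iters = as.integer(preinflate_iters),
                 baseline_cut = baseline_cut, scheme = scheme,
                 bonferroni_m = bonferroni_m,
                 element_budget = as.integer(element_budget),
                 segmentation = segmentation, k = as.integer(k),
                 seed = as.integer(seed), alpha = alpha),
            class = "run_config")
}

#' Load a pipeline configuration from YAML
#' @param path YAML file; keys as in [run_config()], with materials given
#'   as `moduli_pa: {fibrous: ..., ...}` and `poisson_ratio`.
#' @return A [run_config()].
#' @export
read_config_yaml <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  mats <- material_table()
  if (!is.null(y$moduli_pa))
    # YAML readers keep plain-exponent numbers ("2.0e6") as strings
    mats <- do.call(material_table,
                    c(lapply(y$moduli_pa, as.numeric),
                      list(poisson_ratio = as.numeric(y$poisson_ratio %||% 0.49))))
  args <- y[intersect(names(y), names(formals(run_config)))]
  args$materials <- mats
  do.call(run_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Analyse one specimen end to end
#'
#' Segments the image, computes morphometry, meshes the wall domain,
#' assigns rule-of-mixtures moduli, (optionally) pre-inflates, solves the
#' inflation problem, computes excursion fields, and associates each
#' supplied stain map with stress and strain excursion. Stain stages are
#' skipped gracefully when no stains are given.
#'
#' @param image RGB array or path to a PNG/TIFF image.
#' @param geometry A [vessel_geometry()] or path to a contour CSV.
#' @param stains Named list of binary positivity rasters (1/0/NA), paths
#'   to PNGs, or lists `list(image =, stain = )` to threshold an RGB stain
#'   image.
#' @param masks Optional named list of logical exclusion masks per stain.
#' @param config A [run_config()].
#' @param out_dir Optional output directory; when given, all tables are
#'   written there along with a machine-readable run manifest.
#' @return List with `labelmap`, `morphometry`, `fem`, `preinflation`
#'   (NULL when disabled), `staining`, and `associations` (per stain and
#'   metric).
#' @export
run_specimen <- function(image, geometry, stains = list(), masks = NULL,
                         config = run_config(), out_dir = NULL) {
  if (is.character(image)) image <- read_image(image)
  if (is.character(geometry))
    geometry <- read_contours_csv(geometry, config$um_per_px)

  labelmap <- if (config$segmentation == "kmeans") {
    segment_kmeans(image, k = config$k, geometry = geometry,
                   seed = config$seed)
  } else {
    segment_lab_nearest(image, geometry = geometry)
  }
  morpho <- morphometry(geometry, labelmap)

  area <- polygon_area(geometry$outer) - polygon_area(geometry$lumen)
  mesh <- mesh_domain(geometry, target_element_area_um2 = area / config$element_budget)
  emod <- assign_moduli(mesh, labelmap, config$materials)
  model <- fe_model(mesh, emod, config$materials$poisson_ratio,
                    config$pressure_mmhg)
  pre <- NULL
  if (config$preinflate_iters > 0) {
    pre <- preinflate(model, config$preinflate_iters)
    fem <- pre$fem
  } else {
    fem <- solve_inflation(model)
  }

  stain_rasters <- lapply(names(stains), function(nm) {
    s <- stains[[nm]]
    if (is.character(s)) {
      img <- read_image(s)
      matrix(as.integer(img[, , 1] > 0.5), dim(img)[1])
    } else if (is.list(s)) {
      threshold_stain(s$image, s$stain)
    } else {
      matrix(as.integer(s), nrow(s))
    }
  })
  names(stain_rasters) <- names(stains)

  staining <- list(); associations <- list()
  for (nm in names(stain_rasters)) {
    pos <- stain_rasters[[nm]]
    msk <- if (!is.null(masks)) masks[[nm]] else NULL
    if (!is.null(msk)) pos[!msk] <- NA_integer_
    tissue <- labelmap$mask & !is.na(pos)
    staining[[nm]] <- list(pos = sum(pos[tissue] > 0), tot = sum(tissue))
    obs <- attach_markers(fem, pos, config$um_per_px)
    associations[[nm]] <- lapply(c(strain = "strain", stress = "stress"),
                                 function(metric) {
      bins <- bin_by_excursion(obs, metric, config$scheme, config$baseline_cut)
      test_association(bins, config$bonferroni_m, config$alpha)
    })
  }

  res <- list(labelmap = labelmap, morphometry = morpho, fem = fem,
              preinflation = pre, staining = staining,
              associations = associations, config = config)
  if (!is.null(out_dir)) write_specimen_outputs(res, out_dir)
  res
}

write_specimen_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_solution_csv(res$fem, file.path(out_dir, "elements.csv"))
  m <- res$morphometry
  morpho_df <- data.frame(Radius_mm = signif(m$radius_um / 1000, 6),
                          Area_um2 = signif(m$lesion_area_um2, 6),
                          Media_thick_um = signif(m$media_thickness_um, 6),
                          Plaque_burden = signif(m$plaque_burden, 6),
                          Eccentricity_normalized_to_radius = signif(m$eccentricity, 6))
  if (!is.null(m$composition))
    for (nm in names(m$composition))
      morpho_df[[paste0(nm, "_fraction")]] <- signif(m$composition[[nm]], 6)
  write.csv(morpho_df, file.path(out_dir, "morphometry.csv"), row.names = FALSE)
  if (length(res$staining))
    write_staining_csv(res$staining, file.path(out_dir, "staining.csv"))
  if (length(res$associations)) {
    rows <- list()
    for (nm in names(res$associations))
      for (metric in names(res$associations[[nm]])) {
        b <- res$associations[[nm]][[metric]]
        tab <- b$table
        tab$stain <- nm; tab$metric <- metric; tab$scheme <- b$scheme
        tab$chisq_p <- b$chisq$p
        if (!is.null(b$posthoc)) {
          ph <- merge(tab, b$posthoc, by = "bin", all.x = TRUE)
        } else {
          ph <- tab; ph$z <- NA; ph$p_raw <- NA; ph$p_adj <- NA
          ph$significant <- NA
        }
        rows[[paste(nm, metric)]] <- ph
      }
    assoc <- do.call(rbind, rows)
    num <- vapply(assoc, is.numeric, TRUE)
    assoc[num] <- lapply(assoc[num], signif, 6)
    write.csv(assoc, file.path(out_dir, "associations.csv"), row.names = FALSE)
  }
  if (!is.null(res$preinflation))
    write.csv(data.frame(iter = res$preinflation$convergence$iter,
                         d_stress_excursion_pct =
                           signif(res$preinflation$convergence$d_stress_excursion_pct, 6),
                         d_strain_excursion_pct =
                           signif(res$preinflation$convergence$d_strain_excursion_pct, 6)),
              file.path(out_dir, "preinflation.csv"), row.names = FALSE)
  invisible(out_dir)
}

#' Default phantom-study scenarios
#'
#' Two lesion archetypes crossed with coupled/uncoupled staining: a
#' thin-cap lesion whose marker positivity is coupled to strain excursion
#' (the vulnerable-plaque-like pattern) and a thick-cap lesion with
#' uncoupled (uniform) staining (the stable-plaque-like pattern).
#' @return Named list of scenario parameter lists.
#' @export
default_phantom_scenarios <- function() {
  list(thin_cap_coupled = list(cap_thickness_um = 150, core_angle_deg = 140,
                               coupling_beta = 2),
       thick_cap_uncoupled = list(cap_thickness_um = 450, core_angle_deg = 100,
                                  coupling_beta = 0))
}

#' Run an all-synthetic phantom study
#'
#' Generates `n_per_scenario` phantoms per scenario, runs the full
#' segment -> mesh -> (pre-inflate) -> solve -> excursion -> associate
#' pipeline on each, and (optionally) writes per-specimen and pooled
#' tables plus a machine-readable manifest.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory.
#' @param n_per_scenario Phantoms per scenario.
#' @param scenarios Scenario list as in [default_phantom_scenarios()].
#' @return List with per-specimen results (`specimens`) and pooled
#'   per-scenario association tests (`pooled`).
#' @export
run_phantom_study <- function(config = run_config(), out_dir = NULL,
                              n_per_scenario = 2L,
                              scenarios = default_phantom_scenarios()) {
  specimens <- list(); pooled <- list()
  for (si in seq_along(scenarios)) {
    sc <- scenarios[[si]]
    sc_name <- names(scenarios)[si]
    obs_pool <- NULL
    for (rep_i in seq_len(n_per_scenario)) {
      seed <- config$seed + 1000L * si + rep_i
      spec_args <- c(list(seed = seed, um_per_px = config$um_per_px),
                     sc[setdiff(names(sc), "coupling_beta")])
      spec <- do.call(phantom_spec, spec_args)
      ph <- generate_phantom(spec)
      res <- analyse_phantom(ph, config,
                             coupling_beta = sc$coupling_beta %||% 0,
                             stain_seed = seed + 7L)
      specimens[[paste0(sc_name, "_", rep_i)]] <- res
      obs_pool <- rbind(obs_pool, res$observations)
    }
    pooled[[sc_name]] <- lapply(c(strain = "strain", stress = "stress"),
                                function(metric) {
      bins <- bin_by_excursion(obs_pool, metric, config$scheme,
                               config$baseline_cut)
      test_association(bins, config$bonferroni_m, config$alpha)
    })
  }
  out <- list(specimens = specimens, pooled = pooled, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(specimens))
      write_specimen_outputs(specimens[[nm]], file.path(out_dir, nm))
    manifest <- list(package_version = as.character(utils::packageVersion("plaquemech")),
                     seed = config$seed,
                     n_per_scenario = n_per_scenario,
                     scenarios = scenarios,
                     config = config[setdiff(names(config), "materials")],
                     moduli_pa = as.list(config$materials$modulus_pa),
                     poisson_ratio = config$materials$poisson_ratio)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

# Single-phantom analysis used by the study driver and the acceptance
# checks: segmentation runs on the rendered image; the synthetic stain is
# drawn from the ground-truth label map with optional strain coupling.
analyse_phantom <- function(phantom, config = run_config(),
                            coupling_beta = 0, stain_seed = 1L,
                            marker_name = "marker") {
  labelmap <- if (config$segmentation == "kmeans") {
    segment_kmeans(phantom$image, k = config$k, geometry = phantom$geometry,
                   seed = config$seed)
  } else {
    segment_lab_nearest(phantom$image, geometry = phantom$geometry)
  }
  geom <- phantom$geometry
  area <- polygon_area(geom$outer) - polygon_area(geom$lumen)
  mesh <- mesh_domain(geom, target_element_area_um2 = area / config$element_budget)
  emod <- assign_moduli(mesh, labelmap, config$materials)
  model <- fe_model(mesh, emod, config$materials$poisson_ratio,
                    config$pressure_mmhg)
  pre <- NULL
  if (config$preinflate_iters > 0) {
    pre <- preinflate(model, config$preinflate_iters)
    fem <- pre$fem
  } else {
    fem <- solve_inflation(model)
  }

  dimpx <- dim(phantom$labelmap$labels)
  if (coupling_beta != 0) {
    strain_raster <- rasterize_element_values(fem$mesh,
                                              fem$elements$strain_excursion,
                                              dimpx, config$um_per_px)
    model_stain <- stain_model(marker_name, "strain_coupled",
                               list(baseline_positivity =
                                      phantom$spec$baseline_positivity,
                                    coupling_beta = coupling_beta))
    pos <- generate_stain_map(phantom$labelmap, strain_raster, model_stain,
                              seed = stain_seed)
  } else {
    model_stain <- stain_model(marker_name, "uniform",
                               list(baseline_positivity =
                                      phantom$spec$baseline_positivity))
    pos <- generate_stain_map(phantom$labelmap, NULL, model_stain,
                              seed = stain_seed)
  }
  obs <- attach_markers(fem, pos, config$um_per_px)
  morpho <- morphometry(geom, labelmap)
  list(labelmap = labelmap, morphometry = morpho, fem = fem,
       preinflation = pre, observations = obs,
       staining = setNames(list(list(pos = sum(pos[labelmap$mask] > 0),
                                     tot = sum(labelmap$mask))), marker_name),
       associations = setNames(list(
         lapply(c(strain = "strain", stress = "stress"), function(metric) {
           bins <- bin_by_excursion(obs, metric, config$scheme,
                                    config$baseline_cut)
           test_association(bins, config$bonferroni_m, config$alpha)
         })), marker_name),
       config = config)
}
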