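# Print / summary / plot methods for the package's classed objects.

#' @export
print.phantom_spec <- function(x, ...) {
  cat("Vessel phantom spec: lumen", x$lumen_radius_um, "um, IEL",
      x$iel_radius_um, "um, outer", x$outer_radius_um, "um\n")
  cat("  compression", x$compression_ratio, "| cap", x$cap_thickness_um,
      "um | core", x$core_angle_deg, "deg | seed", x$seed, "\n")
  invisible(x)
}

#' @export
print.tissue_labelmap <- function(x, ...) {
  tab <- table(factor(x$labels, levels = TISSUE_CLASSES,
                      labels = names(TISSUE_CLASSES)))
  cat("Tissue label map", paste(dim(x$labels), collapse = " x "), "px @",
      x$um_per_px, "um/px\n")
  print(tab)
  invisible(x)
}

#' @export
print.vessel_geometry <- function(x, ...) {
  cat("Vessel geometry (um): lumen area", round(polygon_area(x$lumen)),
      "| IEL area", round(polygon_area(x$iel)),
      "| outer area", round(polygon_area(x$outer)), "\n")
  invisible(x)
}

#' @export
print.vessel_mesh <- function(x, ...) {
  cat("Annular mesh:", nrow(x$tri), "quadratic elements,",
      nrow(x$nodes), "nodes (", x$n_theta, "x", x$n_r, "rays x rings )\n")
  invisible(x)
}

#' @export
print.fe_model <- function(x, ...) {
  cat("Plane-strain FE model:", nrow(x$mesh$tri), "elements, nu =",
      x$poisson_ratio, ", p =", x$pressure_mmhg, "mmHg\n")
  cat("  modulus range:", format(min(x$modulus_pa), digits = 4), "-",
      format(max(x$modulus_pa), digits = 4), "Pa\n")
  invisible(x)
}

#' @export
print.vessel_fem <- function(x, ...) {
  cat("Solved plane-strain inflation:", nrow(x$mesh$tri), "elements\n")
  cat("  median VM stress:", format(median(x$elements$vm_stress), digits = 5),
      "Pa | median VM strain:",
      format(median(x$elements$vm_strain), digits = 5), "\n")
  cat("  equilibrium residual:", format(x$equilibrium_residual, digits = 3), "\n")
  invisible(x)
}

#' @export
summary.vessel_fem <- function(object, ...) {
  el <- object$elements
  out <- list(n_elements = nrow(el),
              vm_stress = quantile(el$vm_stress, c(0, .25, .5, .75, 1)),
              vm_strain = quantile(el$vm_strain, c(0, .25, .5, .75, 1)),
              stress_excursion = range(el$stress_excursion),
              strain_excursion = range(el$strain_excursion),
              equilibrium_residual = object$equilibrium_residual)
  class(out) <- "summary.vessel_fem"
  out
}

#' @export
print.summary.vessel_fem <- function(x, ...) {
  cat("Elements:", x$n_elements, "\n")
  cat("VM stress quartiles (Pa):\n"); print(signif(x$vm_stress, 4))
  cat("VM strain quartiles:\n"); print(signif(x$vm_strain, 4))
  cat("Stress excursion range:", signif(x$stress_excursion, 3), "\n")
  cat("Strain excursion range:", signif(x$strain_excursion, 3), "\n")
  invisible(x)
}

#' Plot a per-element field of a solved model
#'
#' Draws the mesh with elements filled by the chosen field (default
#' strain excursion).
#' @param x A solved `vessel_fem`.
#' @param field Column of `x$elements` to display.
#' @param n_colors Palette resolution.
#' @param ... Unused.
#' @export
plot.vessel_fem <- function(x, field = "strain_excursion", n_colors = 64, ...) {
  v <- x$elements[[field]]
  pal <- hcl.colors(n_colors, "viridis")
  idx <- pmax(1L, pmin(n_colors, as.integer(cut(v, n_colors))))
  nodes <- x$mesh$nodes; tri <- x$mesh$tri
  plot.new()
  plot.window(range(nodes[, 1]), rev(range(nodes[, 2])), asp = 1)
  for (e in seq_len(nrow(tri)))
    polygon(nodes[tri[e, ], 1], nodes[tri[e, ], 2],
            col = pal[idx[e]], border = NA)
  title(main = field, xlab = "x (um)", ylab = "y (um)")
  axis(1); axis(2)
  invisible(x)
}

#' @export
print.preinflation <- function(x, ...) {
  cat("Pre-inflation:", x$n_iter, "iterations\n")
  if (!is.null(x$convergence)) {
    last <- x$convergence[nrow(x$convergence), ]
    cat("  last-step mean |d excursion|: stress",
        signif(last$d_stress_excursion_pct, 3), "% | strain",
        signif(last$d_strain_excursion_pct, 3), "%\n")
  }
  cat("  lumen circularity:", signif(x$circularity[1], 4), "->",
      signif(x$circularity[length(x$circularity)], 4), "\n")
  invisible(x)
}

#' @export
print.excursion_bins <- function(x, ...) {
  cat(x$scheme, "binning of", x$metric, "excursion (baseline <",
      x$baseline_cut, ")\n")
  print(transform(x$table, fraction = signif(fraction, 4),
                  e_min = signif(e_min, 3), e_max = signif(e_max, 3)),
        row.names = FALSE)
  if (!is.null(x$chisq))
    cat("chi-squared:", signif(x$chisq$statistic, 4), "df", x$chisq$df,
        "p =", format(x$chisq$p, digits = 3), "\n")
  if (!is.null(x$posthoc)) {
    cat("post hoc (vs baseline, Bonferroni m =", x$bonferroni_m, "):\n")
    print(transform(x$posthoc, z = signif(z, 3),
                    p_raw = signif(p_raw, 3), p_adj = signif(p_adj, 3)),
          row.names = FALSE)
  }
  invisible(x)
}

#' @export
print.phenotype_comparison <- function(x, ...) {
  cat("One-way ANOVA: F(", x$df[1], ",", x$df[2], ") =",
      signif(x$f, 4), ", p =", format(x$p, digits = 3), "\n")
  cat("Tukey HSD pairs (Bonferroni m =", x$bonferroni_m, "):\n")
  print(transform(x$pairs, diff = signif(diff, 4),
                  p_tukey = signif(p_tukey, 3), p_adj = signif(p_adj, 3)),
        row.names = FALSE)
  invisible(x)
}

#' @export
print.morphometry_record <- function(x, ...) {
  cat("Morphometry: radius", signif(x$radius_um, 5), "um | eccentricity",
      signif(x$eccentricity, 4), "\n")
  if (!is.na(x$lesion_area_um2))
    cat("  lesion area", signif(x$lesion_area_um2, 5), "um^2 | plaque burden",
        signif(x$plaque_burden, 4), "\n")
  if (!is.na(x$media_thickness_um))
    cat("  media thickness", signif(x$media_thickness_um, 5), "um\n")
  invisible(x)
}

#' @export
print.band_result <- function(x, ...) {
  cat("Near-lumen band:", x$n_band, "analysable px,", x$n_pos,
      "positive, fraction", signif(x$fraction, 4), "\n")
  invisible(x)
}
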