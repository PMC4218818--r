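# Synthetic vessel cross-section phantoms. These emulate the statistical
# structure the analysis assumes in real stained sections: an annular wall
# between a lumen and an outer border, heterogeneous tissue composition
# (fibrous cap and shoulders, a lipid/necrotic core arc with optional
# calcified subsector, a cellular medial/adventitial ring), an optional
# anisotropic compression artifact from fixation/embedding, and binary
# marker maps whose positivity can be coupled to local strain excursion.

#' Phantom specimen specification
#'
#' @param seed Integer RNG seed; all phantom randomness derives from it.
#' @param image_size_px Integer pair (rows, cols) of the rendered image.
#' @param um_per_px Physical pixel size, micrometres per pixel.
#' @param lumen_radius_um,iel_radius_um,outer_radius_um Radii of the lumen,
#'   internal elastic lamina and outer border in micrometres
#'   (lumen < iel < outer).
#' @param lumen_eccentricity_um Offset of the lumen centroid from the IEL
#'   centroid (along +x), micrometres.
#' @param compression_ratio Anisotropic x-scaling in (0, 1] emulating the
#'   horizontal compression artifact of fixed specimens; 1 = no artifact.
#' @param cap_thickness_um Fibrous cap thickness over the core, micrometres.
#' @param core_angle_deg Arc subtended by the lipid/necrotic core, degrees.
#' @param calcification_fraction Fraction of the core arc converted to
#'   calcified tissue, in `[0, 1)`.
#' @param noise_sd Gaussian color noise standard deviation on the 8-bit
#'   (0-255) scale.
#' @param coupling_beta Log-odds slope linking strain excursion to stain
#'   positivity in strain-coupled stain maps.
#' @param baseline_positivity Per-pixel positivity probability at zero
#'   excursion, in (0, 1).
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(seed = 1L,
                         image_size_px = c(256L, 256L),
                         um_per_px = 20,
                         lumen_radius_um = 1000,
                         iel_radius_um = 1800,
                         outer_radius_um = 2200,
                         lumen_eccentricity_um = 0,
                         compression_ratio = 1,
                         cap_thickness_um = 250,
                         core_angle_deg = 120,
                         calcification_fraction = 0.15,
                         noise_sd = 0,
                         coupling_beta = 0,
                         baseline_positivity = 0.02) {
  spec <- list(seed = as.integer(seed), image_size_px = as.integer(image_size_px),
               um_per_px = um_per_px, lumen_radius_um = lumen_radius_um,
               iel_radius_um = iel_radius_um, outer_radius_um = outer_radius_um,
               lumen_eccentricity_um = lumen_eccentricity_um,
               compression_ratio = compression_ratio,
               cap_thickness_um = cap_thickness_um,
               core_angle_deg = core_angle_deg,
               calcification_fraction = calcification_fraction,
               noise_sd = noise_sd, coupling_beta = coupling_beta,
               baseline_positivity = baseline_positivity)
  with(spec, {
    if (!(lumen_radius_um < iel_radius_um && iel_radius_um < outer_radius_um))
      stop("invalid radii ordering: need lumen < iel < outer")
    if (lumen_eccentricity_um < 0) stop("lumen_eccentricity_um must be >= 0")
    if (lumen_eccentricity_um + lumen_radius_um >= iel_radius_um)
      stop("lumen (radius + eccentricity) must stay strictly inside the IEL")
    if (compression_ratio <= 0 || compression_ratio > 1)
      stop("compression_ratio must lie in (0, 1]")
    if (calcification_fraction < 0 || calcification_fraction >= 1)
      stop("calcification_fraction must lie in [0, 1)")
    if (baseline_positivity <= 0 || baseline_positivity >= 1)
      stop("baseline_positivity must lie in (0, 1)")
    if (um_per_px <= 0 || cap_thickness_um <= 0) stop("scales must be positive")
  })
  structure(spec, class = "phantom_spec")
}

#' Tissue label map
#'
#' Per-pixel tissue class raster: 0 = background, 1 = fibrous, 2 = cellular,
#' 3 = lipid/necrotic, 4 = calcified, together with its physical scale and a
#' mask of analysable pixels.
#'
#' @param labels Integer matrix of class codes.
#' @param um_per_px Micrometres per pixel.
#' @param mask Logical matrix of analysable pixels; defaults to all tissue
#'   (non-background) pixels.
#' @return Object of class `tissue_labelmap`.
#' @export
tissue_labelmap <- function(labels, um_per_px, mask = NULL) {
  labels <- matrix(as.integer(labels), nrow = nrow(labels))
  if (!all(labels %in% TISSUE_CLASSES))
    stop("labels outside the declared class set 0..4")
  if (is.null(mask)) mask <- labels != TISSUE_CLASSES[["background"]]
  stopifnot(identical(dim(mask), dim(labels)))
  structure(list(labels = labels, um_per_px = um_per_px, mask = mask),
            class = "tissue_labelmap")
}

#' Generate a synthetic vessel cross-section phantom
#'
#' Builds the ground-truth tissue label map, its RGB rendering under a
#' pentachrome-like palette with optional Gaussian color noise, and the
#' vessel contours. The wall between lumen and IEL is fibrous with a
#' lipid/necrotic core arc (optionally partly calcified) under a fibrous
#' cap; the ring between IEL and outer border is cellular. The compression
#' artifact scales the x axis of everything about the section center.
#'
#' @param spec A [phantom_spec()].
#' @param palette 5 x 3 RGB (0-1) palette matrix with rows background,
#'   fibrous, cellular, lipid_necrotic, calcified.
#' @return List of class `vessel_phantom` with elements `image` (rows x
#'   cols x 3 array in 0-1), `labelmap` ([tissue_labelmap]), `geometry`
#'   ([vessel_geometry]) and `spec`.
#' @export
generate_phantom <- function(spec, palette = default_palette()) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  nr <- spec$image_size_px[1]; nc <- spec$image_size_px[2]
  upp <- spec$um_per_px
  cx <- nc / 2 * upp; cy <- nr / 2 * upp
  cr <- spec$compression_ratio

  pc <- pixel_centers(c(nr, nc), upp)
  # undo the compression artifact to classify in the round reference frame
  dx <- outer(rep(1, nr), (pc$x - cx) / cr)
  dy <- outer(pc$y - cy, rep(1, nc))
  r0 <- sqrt(dx^2 + dy^2)
  dxl <- dx - spec$lumen_eccentricity_um
  rl <- sqrt(dxl^2 + dy^2)
  ang <- atan2(dy, dxl)

  core_half <- spec$core_angle_deg / 2 * pi / 180
  calc_half <- core_half * spec$calcification_fraction
  # core sits on the thick side of the wall, opposite the lumen offset
  dev <- abs(atan2(sin(ang - pi), cos(ang - pi)))

  lab <- matrix(TISSUE_CLASSES[["background"]], nr, nc)
  wall <- rl > spec$lumen_radius_um & r0 <= spec$outer_radius_um
  intima <- wall & r0 <= spec$iel_radius_um
  media <- wall & r0 > spec$iel_radius_um
  lab[media] <- TISSUE_CLASSES[["cellular"]]
  lab[intima] <- TISSUE_CLASSES[["fibrous"]]
  core <- intima & dev <= core_half &
    rl > spec$lumen_radius_um + spec$cap_thickness_um
  lab[core] <- TISSUE_CLASSES[["lipid_necrotic"]]
  if (spec$calcification_fraction > 0)
    lab[core & dev <= calc_half] <- TISSUE_CLASSES[["calcified"]]

  labelmap <- tissue_labelmap(lab, upp)
  img <- render_labels(labelmap, palette)
  if (spec$noise_sd > 0) {
    img <- img + rnorm(length(img), sd = spec$noise_sd / 255)
    img[img < 0] <- 0; img[img > 1] <- 1
  }
  # quantize to 8-bit depth like a real acquisition (also makes PNG
  # round-trips exact)
  img <- round(img * 255) / 255

  compress_x <- function(p) cbind(cx + (p[, 1] - cx) * cr, p[, 2])
  lumen <- compress_x(circle_polygon(c(cx + spec$lumen_eccentricity_um, cy),
                                     spec$lumen_radius_um, 256))
  iel <- compress_x(circle_polygon(c(cx, cy), spec$iel_radius_um, 256))
  outer_c <- compress_x(circle_polygon(c(cx, cy), spec$outer_radius_um, 256))
  geom <- vessel_geometry(lumen, iel, outer_c,
                          media_inner = iel, media_outer = outer_c,
                          um_per_px = upp)

  structure(list(image = img, labelmap = labelmap, geometry = geom,
                 spec = spec),
            class = "vessel_phantom")
}

#' Stain model for synthetic marker maps
#'
#' @param marker_name Marker label, e.g. "CD68".
#' @param positivity_mode One of "uniform", "strain_coupled",
#'   "region_restricted".
#' @param params Named list of reals: `baseline_positivity` (all modes),
#'   `coupling_beta` (strain_coupled), `classes` (character vector of tissue
#'   classes, region_restricted).
#' @return Object of class `stain_model`.
#' @export
stain_model <- function(marker_name, positivity_mode = c("uniform",
                        "strain_coupled", "region_restricted"),
                        params = list()) {
  positivity_mode <- match.arg(positivity_mode)
  structure(list(marker_name = marker_name, positivity_mode = positivity_mode,
                 params = params),
            class = "stain_model")
}

#' Draw a binary stain positivity map from a stain model
#'
#' Each tissue pixel is drawn Bernoulli with probability given by the
#' model; background pixels are always negative. In strain-coupled mode the
#' per-pixel probability is
#' `plogis(qlogis(baseline_positivity) + coupling_beta * e)` where `e` is
#' the local strain excursion.
#'
#' @param labelmap A [tissue_labelmap()].
#' @param strain_excursion Real raster of per-pixel strain excursion, same
#'   shape as the label map; required iff mode is "strain_coupled". Pixels
#'   with `NA` excursion fall back to the baseline probability.
#' @param model A [stain_model()].
#' @param seed Integer seed for the Bernoulli draw.
#' @return Integer matrix (0/1) of the same shape as the label map.
#' @export
generate_stain_map <- function(labelmap, strain_excursion = NULL, model,
                               seed = 1L) {
  stopifnot(inherits(labelmap, "tissue_labelmap"), inherits(model, "stain_model"))
  lab <- labelmap$labels
  if (model$positivity_mode == "strain_coupled") {
    if (is.null(strain_excursion))
      stop("strain_coupled stain model requires a strain excursion raster")
    if (!identical(dim(strain_excursion), dim(lab)))
      stop("strain excursion raster shape does not match the label map")
  } else if (!is.null(strain_excursion) &&
             !identical(dim(strain_excursion), dim(lab))) {
    stop("strain excursion raster shape does not match the label map")
  }
  p0 <- model$params$baseline_positivity
  if (is.null(p0)) stop("stain model params must include baseline_positivity")

  prob <- matrix(0, nrow(lab), ncol(lab))
  tissue <- lab != TISSUE_CLASSES[["background"]]
  if (model$positivity_mode == "uniform") {
    prob[tissue] <- p0
  } else if (model$positivity_mode == "strain_coupled") {
    beta <- model$params$coupling_beta
    if (is.null(beta)) stop("strain_coupled model requires coupling_beta")
    e <- strain_excursion
    e[is.na(e)] <- 0
    prob[tissue] <- plogis(qlogis(p0) + beta * e[tissue])
  } else { # region_restricted
    cls <- model$params$classes
    if (is.null(cls)) stop("region_restricted model requires params$classes")
    codes <- TISSUE_CLASSES[cls]
    if (any(is.na(codes))) stop("unknown tissue class in params$classes")
    prob[tissue & (lab %in% codes)] <- p0
  }
  set.seed(seed)
  pos <- matrix(0L, nrow(lab), ncol(lab))
  draw <- prob > 0
  pos[draw] <- rbinom(sum(draw), 1L, prob[draw])
  pos
}

#' Homogeneous annulus phantom for analytic validation
#'
#' A concentric, single-class (fibrous-coded) thick-walled annulus whose
#' inflation under internal pressure has the closed-form thick-walled
#' cylinder (Lame) solution, used to validate the finite-element solver.
#'
#' @param a_um,b_um Inner and outer radii, micrometres (0 < a < b).
#' @param modulus_pa Elastic modulus applied to every tissue class.
#' @param image_size_px Raster size (square).
#' @return List with `labelmap`, `geometry` and `materials` (all classes at
#'   `modulus_pa`).
#' @export
lame_phantom <- function(a_um, b_um, modulus_pa = 1.821e6,
                         image_size_px = 256L) {
  if (!(a_um > 0 && a_um < b_um)) stop("need 0 < a < b")
  n <- as.integer(image_size_px)
  upp <- 2.5 * b_um / n
  cx <- n / 2 * upp
  pc <- pixel_centers(c(n, n), upp)
  dx <- outer(rep(1, n), pc$x - cx)
  dy <- outer(pc$y - cx, rep(1, n))
  r <- sqrt(dx^2 + dy^2)
  lab <- matrix(TISSUE_CLASSES[["background"]], n, n)
  lab[r > a_um & r <= b_um] <- TISSUE_CLASSES[["fibrous"]]
  labelmap <- tissue_labelmap(lab, upp)
  geom <- vessel_geometry(circle_polygon(c(cx, cx), a_um, 360),
                          circle_polygon(c(cx, cx), (a_um + b_um) / 2, 360),
                          circle_polygon(c(cx, cx), b_um, 360),
                          um_per_px = upp)
  mats <- material_table(fibrous = modulus_pa, cellular = modulus_pa,
                         lipid_necrotic = modulus_pa, calcified = modulus_pa)
  list(labelmap = labelmap, geometry = geom, materials = mats)
}
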