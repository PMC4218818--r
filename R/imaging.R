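# Color segmentation of pentachrome-like histology images and thresholding
# of chromogen-stained marker images. Two segmentation routes are provided:
# k-means clustering of pixel colors in RGB space with automatic mapping of
# cluster centers to tissue classes, and direct nearest-prototype
# classification in LAB space. LAB conversion uses 8-bit sRGB input and the
# D65 white point throughout so results are bit-stable.

#' Default pentachrome-like palette
#'
#' Rendering colors per tissue class (rows background, fibrous, cellular,
#' lipid_necrotic, calcified; RGB in 0-1). The palette is a configuration
#' value: segmentation is palette-agnostic as long as prototypes match the
#' rendering.
#' @return 5 x 3 numeric matrix with class rownames.
#' @export
default_palette <- function() {
  pal <- rbind(background     = c(1.00, 1.00, 1.00),
               fibrous        = c(0.94, 0.86, 0.24),
               cellular       = c(0.78, 0.24, 0.47),
               lipid_necrotic = c(0.75, 0.78, 0.84),
               calcified      = c(0.35, 0.20, 0.43))
  colnames(pal) <- c("r", "g", "b")
  pal
}

#' Render a tissue label map to RGB
#' @param labelmap A [tissue_labelmap()].
#' @param palette Palette matrix as in [default_palette()].
#' @return rows x cols x 3 array in 0-1.
#' @export
render_labels <- function(labelmap, palette = default_palette()) {
  lab <- labelmap$labels
  arr <- array(0, c(nrow(lab), ncol(lab), 3))
  for (ch in 1:3) arr[, , ch] <- matrix(palette[lab + 1L, ch], nrow(lab))
  arr
}

#' Convert sRGB colors to LAB (D65)
#' @param rgb n x 3 matrix of sRGB values in 0-1.
#' @return n x 3 matrix of L, a, b coordinates.
#' @export
rgb_to_lab <- function(rgb) {
  grDevices::convertColor(rgb, from = "sRGB", to = "Lab",
                          to.ref.white = "D65")
}

#' Color prototypes and stain thresholds
#'
#' Bundles the per-class reference colors used by nearest-prototype
#' segmentation (stored both as sRGB and LAB) with per-stain HSV threshold
#' boxes for marker positivity.
#'
#' @param palette 5 x 3 RGB palette (one prototype per tissue class).
#' @param thresholds Named list; each entry a list with `h`, `s`, `v`
#'   (length-2 bounds in 0-1; an `h` range with lo > hi wraps around the
#'   hue circle) and optionally `color` (canonical positive RGB).
#' @return Object of class `color_prototypes`.
#' @export
color_prototypes <- function(palette = default_palette(),
                             thresholds = default_stain_thresholds()) {
  structure(list(classes = rownames(palette), rgb = palette,
                 lab = rgb_to_lab(palette), thresholds = thresholds),
            class = "color_prototypes")
}

#' Default HSV threshold boxes for chromogen stains
#'
#' Axis-aligned HSV boxes for a red chromogen ("nova_red") and a brown one
#' ("dab"), with the canonical positive color of each. These stand in for
#' empirically tuned per-stain levels and are meant to be overridden per
#' study.
#' @return Named list of threshold specifications.
#' @export
default_stain_thresholds <- function() {
  list(nova_red = list(h = c(0.95, 0.10), s = c(0.40, 1.00), v = c(0.30, 0.95),
                       color = c(0.72, 0.15, 0.12)),
       dab = list(h = c(0.04, 0.13), s = c(0.30, 1.00), v = c(0.20, 0.80),
                  color = c(0.45, 0.29, 0.14)))
}

# Build the forced-background mask from contours: pixels inside the lumen or
# outside the outer border are background and not analysable.
geometry_mask <- function(dim_px, geometry) {
  pc <- pixel_centers(dim_px, geometry$um_per_px)
  pts <- cbind(rep(pc$x, each = dim_px[1]), rep(pc$y, times = dim_px[2]))
  inside_outer <- points_in_polygon(geometry$outer, pts)
  inside_lumen <- points_in_polygon(geometry$lumen, pts)
  matrix(inside_outer & !inside_lumen, dim_px[1], dim_px[2])
}

as_pixel_matrix <- function(img) {
  stopifnot(length(dim(img)) == 3, dim(img)[3] >= 3)
  cbind(as.vector(img[, , 1]), as.vector(img[, , 2]), as.vector(img[, , 3]))
}

#' Segment an RGB image by nearest color prototype in LAB space
#'
#' Each pixel is assigned the tissue class whose prototype is nearest in
#' Euclidean LAB distance; ties break to the lowest class index. If a
#' geometry is supplied, pixels inside the lumen or outside the outer
#' border are forced to background and excluded from the analysable mask.
#'
#' @param img rows x cols x 3 RGB array (0-1).
#' @param prototypes A [color_prototypes()].
#' @param geometry Optional [vessel_geometry()] for contour masking.
#' @return A [tissue_labelmap()].
#' @param um_per_px Micrometres per pixel of `img` (ignored if `geometry`
#'   is given, which carries its own scale).
#' @export
segment_lab_nearest <- function(img, prototypes = color_prototypes(),
                                geometry = NULL, um_per_px = 1) {
  px <- as_pixel_matrix(img)
  if (nrow(px) == 0) stop("empty image")
  lab <- rgb_to_lab(px)
  proto <- prototypes$lab
  d2 <- matrix(0, nrow(px), nrow(proto))
  for (k in seq_len(nrow(proto)))
    d2[, k] <- (lab[, 1] - proto[k, 1])^2 + (lab[, 2] - proto[k, 2])^2 +
      (lab[, 3] - proto[k, 3])^2
  cls <- max.col(-d2, ties.method = "first") - 1L
  labels <- matrix(cls, dim(img)[1], dim(img)[2])
  finalize_labelmap(labels, geometry,
                    if (is.null(geometry)) um_per_px else geometry$um_per_px)
}

finalize_labelmap <- function(labels, geometry, um_per_px) {
  if (!is.null(geometry)) {
    gm <- geometry_mask(dim(labels), geometry)
    labels[!gm] <- TISSUE_CLASSES[["background"]]
    tissue_labelmap(labels, um_per_px, mask = gm & labels != 0L)
  } else {
    tissue_labelmap(labels, um_per_px)
  }
}

#' Segment an RGB image by k-means color clustering
#'
#' Pixel colors are clustered in RGB space with k-means (deterministic
#' farthest-point seeding from the given RNG seed, Lloyd iterations), then
#' each cluster center is mapped to the tissue class whose prototype is
#' nearest in LAB space. Several clusters may map to one class.
#'
#' @inheritParams segment_lab_nearest
#' @param k Number of color clusters; must be at least the number of
#'   classes and no larger than the number of distinct pixel colors.
#' @param seed Integer seed fixing the farthest-point initialization.
#' @return A [tissue_labelmap()]. The cluster assignment and the
#'   cluster-to-class map are attached as attributes `clustering` and
#'   `cluster_class`.
#' @export
segment_kmeans <- function(img, k = 6L, prototypes = color_prototypes(),
                           seed = 1L, geometry = NULL, um_per_px = 1) {
  px <- as_pixel_matrix(img)
  if (nrow(px) == 0) stop("empty image")
  ucol <- unique(px)
  if (nrow(ucol) < k)
    stop("k = ", k, " exceeds the number of distinct colors (", nrow(ucol), ")")

  # farthest-point (maximin) seeding on a deterministic subsample
  set.seed(seed)
  idx <- if (nrow(ucol) > 20000) sample.int(nrow(ucol), 20000) else seq_len(nrow(ucol))
  cand <- ucol[idx, , drop = FALSE]
  ctr <- matrix(0, k, 3)
  d0 <- rowSums(sweep(cand, 2, colMeans(cand))^2)
  ctr[1, ] <- cand[which.max(d0), ]
  mind <- rowSums(sweep(cand, 2, ctr[1, ])^2)
  for (j in seq_len(k - 1) + 1) {
    ctr[j, ] <- cand[which.max(mind), ]
    mind <- pmin(mind, rowSums(sweep(cand, 2, ctr[j, ])^2))
  }
  km <- suppressWarnings(kmeans(px, centers = ctr, iter.max = 100,
                                algorithm = "Lloyd"))

  proto <- prototypes$lab
  ctr_lab <- rgb_to_lab(km$centers)
  d2 <- matrix(0, k, nrow(proto))
  for (q in seq_len(nrow(proto)))
    d2[, q] <- (ctr_lab[, 1] - proto[q, 1])^2 + (ctr_lab[, 2] - proto[q, 2])^2 +
      (ctr_lab[, 3] - proto[q, 3])^2
  cluster_class <- max.col(-d2, ties.method = "first") - 1L

  labels <- matrix(cluster_class[km$cluster], dim(img)[1], dim(img)[2])
  out <- finalize_labelmap(labels, geometry,
                           if (is.null(geometry)) um_per_px else geometry$um_per_px)
  attr(out, "clustering") <- matrix(km$cluster, dim(img)[1], dim(img)[2])
  attr(out, "cluster_class") <- cluster_class
  out
}

#' Threshold a stained image into a binary positivity map
#'
#' A pixel is positive iff its HSV coordinates fall inside the stain's
#' threshold box and (if given) the mask is true there.
#'
#' @param img rows x cols x 3 RGB array (0-1).
#' @param stain_name Name of the stain in `prototypes$thresholds`.
#' @param prototypes A [color_prototypes()].
#' @param mask Optional logical matrix of analysable pixels; masked-out
#'   pixels are returned as `NA` so they count in neither numerator nor
#'   denominator downstream.
#' @return Integer matrix: 1 positive, 0 negative, `NA` masked out.
#' @export
threshold_stain <- function(img, stain_name, prototypes = color_prototypes(),
                            mask = NULL) {
  thr <- prototypes$thresholds[[stain_name]]
  if (is.null(thr)) stop("no thresholds defined for stain '", stain_name, "'")
  px <- as_pixel_matrix(img)
  hsv <- t(grDevices::rgb2hsv(t(px), maxColorValue = 1))
  h <- hsv[, 1]; s <- hsv[, 2]; v <- hsv[, 3]
  h_ok <- if (thr$h[1] <= thr$h[2]) h >= thr$h[1] & h <= thr$h[2]
          else h >= thr$h[1] | h <= thr$h[2]
  pos <- h_ok & s >= thr$s[1] & s <= thr$s[2] & v >= thr$v[1] & v <= thr$v[2]
  out <- matrix(as.integer(pos), dim(img)[1], dim(img)[2])
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), dim(out)))
    out[!mask] <- NA_integer_
  }
  out
}

#' Fraction of positive pixels over the analysable region
#'
#' Positives divided by total analysable pixels. When the analysable region
#' is empty the result is the undefined-marker sentinel `NaN`.
#'
#' @param positive Integer/logical raster: 1/TRUE positive, 0/FALSE
#'   negative, `NA` excluded.
#' @param mask Optional logical raster further restricting the region.
#' @return Real in `[0, 1]`, or `NaN` when no pixel is analysable.
#' @export
percent_positive <- function(positive, mask = NULL) {
  keep <- !is.na(positive)
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), dim(positive)))
    keep <- keep & mask
  }
  n <- sum(keep)
  if (n == 0) return(NaN)
  sum(positive[keep] > 0) / n
}
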