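# Closed simple polygons are stored as open n x 2 matrices (columns x, y in
# micrometres, image frame: origin top-left, x right, y down) with positive
# shoelace orientation, i.e. counter-clockwise in the (x, y) coordinate
# numbers. The last vertex is NOT repeated.

#' Signed polygon area (shoelace)
#'
#' @param poly n x 2 matrix of vertices (open polygon).
#' @return Signed area; positive for the package's canonical orientation.
#' @export
polygon_area_signed <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

#' Polygon area (absolute)
#' @inheritParams polygon_area_signed
#' @export
polygon_area <- function(poly) abs(polygon_area_signed(poly))

#' Polygon perimeter
#' @inheritParams polygon_area_signed
#' @export
polygon_perimeter <- function(poly) {
  d <- poly[c(2:nrow(poly), 1), ] - poly
  sum(sqrt(rowSums(d^2)))
}

#' Polygon centroid (area-weighted)
#' @inheritParams polygon_area_signed
#' @return Length-2 numeric vector (x, y).
#' @export
polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  cr <- x * ys - xs * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps)
    return(colMeans(poly))
  c(sum((x + xs) * cr), sum((y + ys) * cr)) / (6 * a)
}

# Ensure positive (canonical) orientation.
orient_polygon <- function(poly) {
  if (polygon_area_signed(poly) < 0) poly[rev(seq_len(nrow(poly))), , drop = FALSE] else poly
}

#' Isoperimetric circularity of a polygon
#'
#' `4 * pi * area / perimeter^2`; 1 for a circle, smaller for elongated or
#' irregular shapes.
#' @inheritParams polygon_area_signed
#' @export
polygon_circularity <- function(poly) {
  4 * pi * polygon_area(poly) / polygon_perimeter(poly)^2
}

#' Vessel cross-section geometry
#'
#' Bundles the traced contours of one specimen: lumen, internal elastic
#' lamina (IEL) and outer (periadventitial) border, plus optional media
#' contours. Contours are closed simple polygons in micrometres; the
#' constructor normalizes orientation and checks nesting
#' (lumen inside IEL inside outer).
#'
#' @param lumen,iel,outer n x 2 vertex matrices in micrometres.
#' @param media_inner,media_outer Optional media boundary polygons.
#' @param um_per_px Physical pixel size of the raster the contours refer to.
#' @return Object of class `vessel_geometry`.
#' @export
vessel_geometry <- function(lumen, iel, outer, media_inner = NULL,
                            media_outer = NULL, um_per_px = 1) {
  as_poly <- function(p, name) {
    p <- as.matrix(p)
    if (ncol(p) != 2 || nrow(p) < 3)
      stop("contour '", name, "' must be an n x 2 matrix with n >= 3")
    if (polygon_area(p) <= 0) stop("contour '", name, "' has zero area")
    orient_polygon(p)
  }
  lumen <- as_poly(lumen, "lumen")
  iel <- as_poly(iel, "iel")
  outer <- as_poly(outer, "outer")
  if (!all(points_in_polygon(iel, lumen)))
    stop("geometry invariant violated: lumen not strictly inside iel")
  if (!all(points_in_polygon(outer, iel)))
    stop("geometry invariant violated: iel not strictly inside outer")
  if (!is.null(media_inner)) media_inner <- as_poly(media_inner, "media_inner")
  if (!is.null(media_outer)) media_outer <- as_poly(media_outer, "media_outer")
  structure(list(lumen = lumen, iel = iel, outer = outer,
                 media_inner = media_inner, media_outer = media_outer,
                 um_per_px = um_per_px),
            class = "vessel_geometry")
}

# Regular n-gon approximating a circle; vertices ordered by increasing angle
# (canonical positive orientation in the package frame).
circle_polygon <- function(center, radius, n = 256) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
}

# Pixel-center coordinate grids (micrometres) for a raster of size dim_px
# (rows, cols). Returns a list with x (cols) and y (rows) vectors.
pixel_centers <- function(dim_px, um_per_px) {
  list(x = (seq_len(dim_px[2]) - 0.5) * um_per_px,
       y = (seq_len(dim_px[1]) - 0.5) * um_per_px)
}
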