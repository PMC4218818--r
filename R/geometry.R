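# Contour-based geometry: polar radius signatures and rotation-only rigid
# registration of serial sections, vessel morphometry, near-lumen band
# quantification, and a non-interactive shortest-path contour tracer.

#' Centroid-to-boundary radius signature of a polygon
#'
#' Distance from the polygon centroid to the boundary along uniformly
#' spaced rays (angle 0 along +x, proceeding counter-clockwise in the
#' package axis convention). For each ray the first boundary crossing is
#' used, so the polygon must be star-shaped enough that every ray hits the
#' boundary.
#'
#' @param poly n x 2 vertex matrix (micrometres).
#' @param n_angles Number of angular bins (default 360, i.e. 1 degree).
#' @param center Optional ray origin; defaults to the polygon centroid.
#' @return Numeric vector of length `n_angles` (micrometres).
#' @export
radius_signature <- function(poly, n_angles = 360L, center = NULL) {
  if (is.null(center)) center <- polygon_centroid(poly)
  if (!as.logical(points_in_polygon(poly, matrix(center, 1))))
    stop("signature center lies outside the polygon")
  th <- (seq_len(n_angles) - 1) * 2 * pi / n_angles
  dx <- cos(th); dy <- sin(th)
  a <- poly
  b <- poly[c(2:nrow(poly), 1), , drop = FALSE]
  ex <- b[, 1] - a[, 1]; ey <- b[, 2] - a[, 2]
  qx <- a[, 1] - center[1]; qy <- a[, 2] - center[2]
  # ray: c + t d ; edge: a + s e ; solve by 2D cross products
  denom <- outer(dx, ey) - outer(dy, ex)            # n_angles x n_edges
  t_num <- matrix(qx * ey - qy * ex, n_angles, length(ex), byrow = TRUE)
  s_num <- outer(dy, qx) * -1 + outer(dx, qy)       # qy*dx - qx*dy per pair
  ok <- abs(denom) > 1e-12
  tt <- ifelse(ok, t_num / denom, Inf)
  ss <- ifelse(ok, -s_num / denom, -1)
  # inclusive endpoint tolerance: a ray passing exactly through a vertex
  # must hit one of the two adjacent edges despite rounding
  tt[!(ss >= -1e-9 & ss <= 1 + 1e-9 & tt > 1e-9)] <- Inf
  sig <- apply(tt, 1, min)
  if (any(!is.finite(sig)))
    stop("polygon is not star-shaped about the center: some rays miss")
  sig
}

#' Rotation registration of two radius signatures
#'
#' Finds the rotation (in signature bins, reported in degrees) that
#' maximizes the circular cross-correlation of two equal-length lumen
#' radius signatures; this is the rotation-only rigid registration used to
#' align serial sections. Ties break to the smallest absolute angle.
#' Constant signatures (circle against circle) are degenerate: the angle is
#' 0 and `degenerate` is set.
#'
#' @param sig_ref,sig_moving Equal-length numeric signatures.
#' @return List with `angle_deg` (in (-180, 180]), `shift_bins`,
#'   `degenerate`.
#' @export
register_rotation <- function(sig_ref, sig_moving) {
  n <- length(sig_ref)
  if (length(sig_moving) != n) stop("signatures must have equal length")
  r <- sig_ref - mean(sig_ref)
  m <- sig_moving - mean(sig_moving)
  if (sd(sig_ref) < 1e-9 || sd(sig_moving) < 1e-9)
    return(list(angle_deg = 0, shift_bins = 0L, degenerate = TRUE))
  cc <- vapply(0:(n - 1), function(s) {
    sum(r * m[((seq_len(n) - 1 + s) %% n) + 1])
  }, numeric(1))
  best <- max(cc)
  cand <- which(cc >= best - 1e-9 * max(abs(best), 1)) - 1L
  ang <- cand * 360 / n
  ang <- ifelse(ang > 180, ang - 360, ang)
  # smallest absolute angle; exact-magnitude ties (symmetric shapes)
  # resolve to the positive rotation
  pick <- order(abs(ang), -ang)[1]
  list(angle_deg = ang[pick], shift_bins = cand[pick], degenerate = FALSE)
}

# Deterministic pseudo-shuffle (LCG) so the expected-linear-time minimum
# enclosing circle runs without touching the global RNG.
lcg_permutation <- function(n, seed = 12345) {
  idx <- seq_len(n)
  state <- as.double(seed)
  for (i in n:2) {
    state <- (state * 1103515245 + 12345) %% 2147483648
    j <- (state %% i) + 1
    tmp <- idx[i]; idx[i] <- idx[j]; idx[j] <- tmp
  }
  idx
}

circumcircle <- function(p1, p2, p3) {
  ax <- p1[1]; ay <- p1[2]; bx <- p2[1]; by <- p2[2]; cx <- p3[1]; cy <- p3[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-12) return(NULL)
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  c(ux, uy, sqrt((ax - ux)^2 + (ay - uy)^2))
}

diameter_circle <- function(p1, p2) {
  c((p1 + p2) / 2, sqrt(sum((p1 - p2)^2)) / 2)
}

in_circle <- function(circ, p, tol = 1e-9) {
  sqrt((p[1] - circ[1])^2 + (p[2] - circ[2])^2) <= circ[3] * (1 + tol) + tol
}

#' Minimum enclosing circle of a point set
#'
#' Exact smallest circle containing all points (Welzl-style incremental
#' algorithm on a deterministic permutation, preceded by a convex hull
#' reduction).
#'
#' @param pts n x 2 matrix.
#' @return List with `center` (x, y) and `radius`.
#' @export
min_enclosing_circle <- function(pts) {
  pts <- unique(as.matrix(pts))
  if (nrow(pts) == 1) return(list(center = pts[1, ], radius = 0))
  hull <- grDevices::chull(pts)
  p <- pts[hull, , drop = FALSE]
  if (nrow(p) == 1) return(list(center = p[1, ], radius = 0))
  p <- p[lcg_permutation(nrow(p)), , drop = FALSE]
  n <- nrow(p)
  circ <- diameter_circle(p[1, ], p[2, ])
  for (i in seq_len(n)) {
    if (in_circle(circ, p[i, ])) next
    circ <- diameter_circle(p[i, ], p[1, ])
    for (j in seq_len(i - 1)) {
      if (in_circle(circ, p[j, ])) next
      circ <- diameter_circle(p[i, ], p[j, ])
      for (k in seq_len(j - 1)) {
        if (in_circle(circ, p[k, ])) next
        cc <- circumcircle(p[i, ], p[j, ], p[k, ])
        if (!is.null(cc)) circ <- cc
      }
    }
  }
  list(center = circ[1:2], radius = circ[3])
}

#' Vessel morphometry
#'
#' Computes the standard cross-section morphometrics: vessel external
#' radius (radius of the smallest circle containing the outer contour),
#' lesion cross-sectional area (tissue pixels inside the IEL), plaque
#' burden (fraction of the area inside the IEL occupied by lesion),
#' eccentricity (lumen-to-IEL centroid distance normalized to the vessel
#' radius) and mean media thickness (average nearest distance from the
#' inner to the outer media boundary, where media contours are present).
#'
#' @param geom A [vessel_geometry()].
#' @param labelmap Optional [tissue_labelmap()]; required for lesion area,
#'   plaque burden and composition fractions.
#' @return Object of class `morphometry_record`.
#' @export
morphometry <- function(geom, labelmap = NULL) {
  mec <- min_enclosing_circle(geom$outer)
  lc <- polygon_centroid(geom$lumen)
  ic <- polygon_centroid(geom$iel)
  ecc <- sqrt(sum((lc - ic)^2)) / mec$radius

  lesion_area <- NA_real_; burden <- NA_real_; comp <- NULL
  if (!is.null(labelmap)) {
    upp <- labelmap$um_per_px
    dimpx <- dim(labelmap$labels)
    pc <- pixel_centers(dimpx, upp)
    cset <- which(pc$x >= min(geom$iel[, 1]) & pc$x <= max(geom$iel[, 1]))
    rset <- which(pc$y >= min(geom$iel[, 2]) & pc$y <= max(geom$iel[, 2]))
    pts <- cbind(rep(pc$x[cset], each = length(rset)),
                 rep(pc$y[rset], times = length(cset)))
    inside <- points_in_polygon(geom$iel, pts)
    sub <- labelmap$labels[rset, cset, drop = FALSE]
    lesion_px <- sum(sub[matrix(inside, length(rset))] !=
                       TISSUE_CLASSES[["background"]])
    total_px <- sum(inside)
    lesion_area <- lesion_px * upp^2
    burden <- if (total_px > 0) lesion_px / total_px else NaN
    tissue <- labelmap$labels[labelmap$mask]
    comp <- table(factor(tissue, levels = TISSUE_CLASSES,
                         labels = names(TISSUE_CLASSES))) / max(1, length(tissue))
    comp <- as.numeric(comp[-1]) # drop background
    names(comp) <- names(TISSUE_CLASSES)[-1]
  }

  media <- NA_real_
  if (!is.null(geom$media_inner) && !is.null(geom$media_outer)) {
    d <- abs(polygon_signed_distance(geom$media_outer, geom$media_inner))
    media <- mean(d)
  }

  structure(list(radius_um = mec$radius, circle_center = mec$center,
                 lesion_area_um2 = lesion_area, plaque_burden = burden,
                 eccentricity = ecc, media_thickness_um = media,
                 composition = comp),
            class = "morphometry_record")
}

#' Positivity within a band dilated outward from the lumen
#'
#' The lumen contour is dilated by `band_um` micrometres using the signed
#' distance function: the band is the set of pixels whose signed distance
#' to the lumen boundary lies in (0, band_um], i.e. outside the lumen but
#' within the band. The fraction of positive pixels over analysable band
#' pixels is returned; excluded-region masks are honored in both numerator
#' and denominator.
#'
#' @param geom A [vessel_geometry()].
#' @param band_um Band width in micrometres (> 0).
#' @param positivity Integer raster (1/0/NA) at the geometry's pixel scale.
#' @param mask Optional logical raster of analysable pixels.
#' @return List of class `band_result`: `fraction` (NaN sentinel when the
#'   band holds no analysable pixel), `n_band`, `n_pos`, `n_band_total`.
#' @export
near_lumen_band <- function(geom, band_um, positivity, mask = NULL) {
  if (band_um <= 0) stop("band_um must be positive")
  upp <- geom$um_per_px
  dimpx <- dim(positivity)
  pc <- pixel_centers(dimpx, upp)
  cset <- which(pc$x >= min(geom$lumen[, 1]) - 2 * band_um &
                  pc$x <= max(geom$lumen[, 1]) + 2 * band_um)
  rset <- which(pc$y >= min(geom$lumen[, 2]) - 2 * band_um &
                  pc$y <= max(geom$lumen[, 2]) + 2 * band_um)
  pts <- cbind(rep(pc$x[cset], each = length(rset)),
               rep(pc$y[rset], times = length(cset)))
  d <- polygon_signed_distance(geom$lumen, pts)
  band <- matrix(d > 0 & d <= band_um, length(rset))
  pos_sub <- positivity[rset, cset, drop = FALSE]
  keep <- band & !is.na(pos_sub)
  if (!is.null(mask)) keep <- keep & mask[rset, cset, drop = FALSE]
  n <- sum(keep)
  structure(list(fraction = if (n == 0) NaN else sum(pos_sub[keep] > 0) / n,
                 n_band = n, n_pos = if (n == 0) 0L else sum(pos_sub[keep] > 0),
                 n_band_total = sum(band)),
            class = "band_result")
}

#' Trace a closed contour by shortest paths on a cost image
#'
#' Non-interactive replacement for interactive boundary tracing: given at
#' least three waypoints on the desired boundary, the minimal-cost closed
#' path through them is computed segment by segment (Dijkstra on the
#' 8-connected pixel lattice; edge cost is the mean of the two pixel costs
#' times the step length). Low cost should mark the boundary (e.g. inverse
#' gradient magnitude).
#'
#' @param cost Strictly positive cost matrix.
#' @param waypoints k x 2 matrix of waypoint coordinates in micrometres
#'   (x, y), k >= 3, in order around the contour.
#' @param um_per_px Micrometres per pixel.
#' @return Closed polygon (n x 2, micrometres) through the waypoints.
#' @export
trace_contour <- function(cost, waypoints, um_per_px = 1) {
  waypoints <- as.matrix(waypoints)
  if (nrow(waypoints) < 3) stop("at least 3 waypoints are required")
  if (any(!is.finite(cost)) || any(cost <= 0))
    stop("cost image must be strictly positive and finite")
  nr <- nrow(cost); nc <- ncol(cost)
  id <- function(r, c) (c - 1L) * nr + r
  cvec <- as.vector(cost)

  edge_set <- function(r1, c1, r2, c2, len) {
    a <- id(r1, c1); b <- id(r2, c2)
    w <- (cvec[a] + cvec[b]) / 2 * len
    list(a = a, b = b, w = w)
  }
  rs <- seq_len(nr); cs <- seq_len(nc)
  e1 <- edge_set(rep(rs[-nr], nc), rep(cs, each = nr - 1),
                 rep(rs[-1], nc), rep(cs, each = nr - 1), 1)        # down
  e2 <- edge_set(rep(rs, nc - 1), rep(cs[-nc], each = nr),
                 rep(rs, nc - 1), rep(cs[-1], each = nr), 1)        # right
  e3 <- edge_set(rep(rs[-nr], nc - 1), rep(cs[-nc], each = nr - 1),
                 rep(rs[-1], nc - 1), rep(cs[-1], each = nr - 1), sqrt(2))
  e4 <- edge_set(rep(rs[-1], nc - 1), rep(cs[-nc], each = nr - 1),
                 rep(rs[-nr], nc - 1), rep(cs[-1], each = nr - 1), sqrt(2))
  edges <- rbind(cbind(e1$a, e1$b), cbind(e2$a, e2$b),
                 cbind(e3$a, e3$b), cbind(e4$a, e4$b))
  wts <- c(e1$w, e2$w, e3$w, e4$w)
  g <- igraph::make_graph(t(edges), n = nr * nc, directed = FALSE)

  wp_c <- pmax(1L, pmin(nc, as.integer(round(waypoints[, 1] / um_per_px + 0.5))))
  wp_r <- pmax(1L, pmin(nr, as.integer(round(waypoints[, 2] / um_per_px + 0.5))))
  wp <- id(wp_r, wp_c)
  k <- length(wp)
  path_px <- integer(0)
  for (i in seq_len(k)) {
    from <- wp[i]; to <- wp[if (i == k) 1L else i + 1L]
    sp <- igraph::shortest_paths(g, from = from, to = to, weights = wts,
                                 output = "vpath")$vpath[[1]]
    if (length(sp) == 0) stop("cost graph is disconnected between waypoints")
    v <- as.integer(sp)
    path_px <- c(path_px, v[-length(v)])
  }
  rr <- ((path_px - 1L) %% nr) + 1L
  cc <- ((path_px - 1L) %/% nr) + 1L
  poly <- cbind((cc - 0.5) * um_per_px, (rr - 0.5) * um_per_px)
  orient_polygon(poly[!duplicated(poly), , drop = FALSE])
}
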