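# Plane-strain linear elasticity on the annular wall domain: quadratic
# (6-node) triangles to avoid volumetric locking at near-incompressible
# Poisson ratio, luminal pressure as a consistent edge traction, minimal
# rigid-body constraints, and Von Mises stress / equivalent deviatoric
# strain recovery per element. The iterative pre-inflation procedure
# (inflate, remesh, re-interpolate moduli) removes fixation artifacts such
# as a compressed lumen before the analysis solve.

#' Assemble a lesion-specific finite-element model
#'
#' @param mesh A [mesh_domain()] result.
#' @param modulus_pa Per-element elastic modulus vector (Pa), typically
#'   from [assign_moduli()].
#' @param poisson_ratio Poisson ratio shared by all elements.
#' @param pressure_mmhg Incremental luminal pressure in mmHg (converted at
#'   1 mmHg = 133.322 Pa), applied normal to the lumen boundary; the outer
#'   boundary is traction-free.
#' @param constraint_axis Axis along which the two rigid-body constraint
#'   nodes are picked on the outer boundary ("x": extreme-x nodes, fix both
#'   components at one and the transverse component at the other). Element
#'   stresses are insensitive to this choice because the pressure load is
#'   self-equilibrated.
#' @return Object of class `fe_model`.
#' @export
fe_model <- function(mesh, modulus_pa, poisson_ratio = 0.49,
                     pressure_mmhg = 40, constraint_axis = c("x", "y")) {
  constraint_axis <- match.arg(constraint_axis)
  stopifnot(inherits(mesh, "vessel_mesh"),
            length(modulus_pa) == nrow(mesh$tri))
  if (any(modulus_pa <= 0)) stop("all element moduli must be positive")
  structure(list(mesh = mesh, modulus_pa = as.numeric(modulus_pa),
                 poisson_ratio = poisson_ratio,
                 pressure_mmhg = pressure_mmhg,
                 pressure_pa = pressure_mmhg * MMHG_TO_PA,
                 constraint_axis = constraint_axis,
                 # reference (undeformed) coordinates of the corner nodes;
                 # identical to the mesh until pre-inflation deforms it
                 ref_coords = mesh$nodes[seq_len(mesh$n_corner), , drop = FALSE]),
            class = "fe_model")
}

#' Rule-of-mixtures element moduli from a tissue label map
#'
#' Each element's modulus is the tissue-area-fraction weighted mean of the
#' class moduli over the pixels whose centers fall inside the element;
#' background pixels are excluded from the fractions. Elements overlapping
#' only background receive the smallest class modulus (with a warning);
#' elements too small to contain any pixel center fall back to the class
#' at the nearest pixel to their centroid.
#'
#' @param mesh A `vessel_mesh`.
#' @param labelmap A [tissue_labelmap()].
#' @param materials A [material_table()].
#' @return Numeric vector of per-element moduli (Pa).
#' @export
assign_moduli <- function(mesh, labelmap, materials = material_table()) {
  upp <- labelmap$um_per_px
  counts <- tri_label_hist(mesh$nodes, mesh$tri, labelmap$labels, upp, 5L)
  emods <- materials$modulus_pa[names(TISSUE_CLASSES)[-1]]
  tissue_counts <- counts[, -1, drop = FALSE]
  ntissue <- rowSums(tissue_counts)
  ntotal <- rowSums(counts)
  E <- as.numeric(tissue_counts %*% emods) / pmax(ntissue, 1)

  bg_only <- ntotal > 0 & ntissue == 0
  if (any(bg_only)) {
    E[bg_only] <- min(emods)
    warning(sum(bg_only), " element(s) overlap only background; assigned ",
            "the smallest-modulus class")
  }
  empty <- ntotal == 0
  if (any(empty)) {
    dimpx <- dim(labelmap$labels)
    rr <- pmax(1L, pmin(dimpx[1], as.integer(round(mesh$centroids[empty, 2] / upp + 0.5))))
    cc <- pmax(1L, pmin(dimpx[2], as.integer(round(mesh$centroids[empty, 1] / upp + 0.5))))
    lab <- labelmap$labels[cbind(rr, cc)]
    Ei <- ifelse(lab > 0, emods[lab], min(emods))
    E[empty] <- Ei
  }
  E
}

constraint_dofs <- function(model) {
  mesh <- model$mesh
  loop <- mesh$outer_loop
  # pick the extreme nodes in the reference frame: stable across
  # pre-inflation iterations (picking in the current frame lets the argmax
  # flip between near-tied nodes and injects an oscillating rigid shift)
  xy <- model$ref_coords[loop, , drop = FALSE]
  if (model$constraint_axis == "x") {
    a <- loop[order(-xy[, 1], -xy[, 2])[1]]
    b <- loop[order(xy[, 1], xy[, 2])[1]]
    fixed <- c(2 * a - 1, 2 * a, 2 * b) # both at A, y at B
  } else {
    a <- loop[order(-xy[, 2], -xy[, 1])[1]]
    b <- loop[order(xy[, 2], xy[, 1])[1]]
    fixed <- c(2 * a - 1, 2 * a, 2 * b - 1) # both at A, x at B
  }
  sort(unique(fixed))
}

lumen_load_vector <- function(model) {
  mesh <- model$mesh
  p <- model$pressure_pa
  f <- numeric(2 * nrow(mesh$nodes))
  ed <- mesh$lumen_edges
  x1 <- mesh$nodes[ed[, 1], , drop = FALSE]
  x2 <- mesh$nodes[ed[, 2], , drop = FALSE]
  tv <- x2 - x1
  L <- sqrt(rowSums(tv^2))
  nrm <- cbind(tv[, 2], -tv[, 1]) / L
  mid <- (x1 + x2) / 2
  outward <- rowSums(nrm * sweep(mid, 2, mesh$center)) > 0
  nrm[!outward, ] <- -nrm[!outward, ]
  # consistent loads for a quadratic edge under constant traction:
  # 1/6, 1/6 at the vertices, 2/3 at the midside node
  for (k in seq_len(nrow(ed))) {
    fx <- p * nrm[k, 1] * L[k]; fy <- p * nrm[k, 2] * L[k]
    v1 <- ed[k, 1]; v2 <- ed[k, 2]; m <- ed[k, 3]
    f[2 * v1 - 1] <- f[2 * v1 - 1] + fx / 6
    f[2 * v1] <- f[2 * v1] + fy / 6
    f[2 * v2 - 1] <- f[2 * v2 - 1] + fx / 6
    f[2 * v2] <- f[2 * v2] + fy / 6
    f[2 * m - 1] <- f[2 * m - 1] + fx * 2 / 3
    f[2 * m] <- f[2 * m] + fy * 2 / 3
  }
  f
}

#' Solve the inflation problem
#'
#' Assembles the plane-strain stiffness matrix, applies the luminal
#' pressure as a consistent traction on the lumen edges, removes the three
#' rigid-body modes by minimal constraints on two outer-boundary nodes,
#' and solves the sparse symmetric system. Per-element Von Mises stress
#' (with the plane-strain out-of-plane stress sigma_z = nu (sigma_x +
#' sigma_y)) and equivalent deviatoric (Von Mises) strain are recovered at
#' element centroids, and stress/strain excursion fields are attached.
#'
#' @param model An [fe_model()].
#' @return Object of class `vessel_fem`: the model plus `u` (nodal
#'   displacements, micrometres), `elements` (per-element field data
#'   frame) and `equilibrium_residual` (max constraint reaction over total
#'   applied load).
#' @export
solve_inflation <- function(model) {
  stopifnot(inherits(model, "fe_model"))
  mesh <- model$mesh
  trip <- fem_stiffness_triplets(mesh$nodes, mesh$tri6, model$modulus_pa,
                                 model$poisson_ratio)
  ndof <- 2 * nrow(mesh$nodes)
  K <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$v,
                            dims = c(ndof, ndof))
  f <- lumen_load_vector(model)
  fixed <- constraint_dofs(model)
  free <- setdiff(seq_len(ndof), fixed)
  u <- numeric(ndof)
  sol <- Matrix::solve(K[free, free], f[free])
  u[free] <- as.numeric(sol)

  fields <- fem_element_fields(mesh$nodes, mesh$tri6, model$modulus_pa,
                               model$poisson_ratio, u, c(1, 1, 1) / 3)
  colnames(fields) <- c("sx", "sy", "txy", "sz", "vm_stress",
                        "ex", "ey", "vm_strain")
  reac <- as.numeric(K %*% u - f)[fixed]
  load_mag <- model$pressure_pa * polygon_perimeter(boundary_polygon(mesh, "lumen"))
  el <- data.frame(element_id = seq_len(nrow(mesh$tri)),
                   centroid_x_um = mesh$centroids[, 1],
                   centroid_y_um = mesh$centroids[, 2],
                   area_um2 = mesh$areas,
                   modulus_pa = model$modulus_pa,
                   fields)
  # excursion is undefined for an identically zero field (zero load)
  if (median(el$vm_stress) > 0) {
    el$stress_excursion <- excursion(el$vm_stress)
    el$strain_excursion <- excursion(el$vm_strain)
  } else {
    el$stress_excursion <- NA_real_
    el$strain_excursion <- NA_real_
  }

  structure(c(model, list(u = u, elements = el,
                          equilibrium_residual = max(abs(reac)) / load_mag)),
            class = c("vessel_fem", "fe_model"))
}

#' Excursion of a field relative to its median
#'
#' The lesion-relative mechanics metric: `e_i = (x_i - median(x)) /
#' median(x)`, the spatially resolved relative difference of each
#' element's value from the lesion median. The median of the raw field
#' maps to excursion 0, and the excursion is invariant under uniform
#' scaling of the raw field.
#'
#' @param x Numeric vector with positive median.
#' @return Excursion vector (dimensionless fractions).
#' @export
excursion <- function(x) {
  m <- median(x)
  if (!is.finite(m) || m <= 0)
    stop("excursion requires a field with positive median")
  (x - m) / m
}

#' Hoop (circumferential) stress at the inner wall
#'
#' Evaluates the stress tensor of each lumen-adjacent element at its lumen
#' edge midpoint and projects onto the edge tangent, giving the
#' circumferential stress at the inner wall (the quantity with a closed
#' form for a homogeneous thick-walled cylinder).
#'
#' @param fem A solved [solve_inflation()] result.
#' @return List with `per_edge` values (Pa) and their `mean`.
#' @export
inner_wall_hoop_stress <- function(fem) {
  mesh <- fem$mesh
  ed <- mesh$lumen_edges
  # element owning each lumen edge: contains both endpoints among corners
  tri <- mesh$tri
  owner <- integer(nrow(ed)); pos <- integer(nrow(ed))
  key_el <- cbind(pmin(tri[, 1], tri[, 2]) * (mesh$n_corner + 1) + pmax(tri[, 1], tri[, 2]),
                  pmin(tri[, 2], tri[, 3]) * (mesh$n_corner + 1) + pmax(tri[, 2], tri[, 3]),
                  pmin(tri[, 3], tri[, 1]) * (mesh$n_corner + 1) + pmax(tri[, 3], tri[, 1]))
  edkey <- pmin(ed[, 1], ed[, 2]) * (mesh$n_corner + 1) + pmax(ed[, 1], ed[, 2])
  for (s in 1:3) {
    hit <- match(edkey, key_el[, s])
    take <- !is.na(hit) & owner == 0L
    owner[take] <- hit[take]
    pos[take] <- s
  }
  if (any(owner == 0L)) stop("lumen edge without owning element")
  barys <- rbind(c(0.5, 0.5, 0), c(0, 0.5, 0.5), c(0.5, 0, 0.5))
  hoop <- numeric(nrow(ed))
  for (s in 1:3) {
    sel <- pos == s
    if (!any(sel)) next
    fl <- fem_element_fields(mesh$nodes, mesh$tri6, fem$modulus_pa,
                             fem$poisson_ratio, fem$u, barys[s, ])
    tv <- mesh$nodes[ed[sel, 2], , drop = FALSE] - mesh$nodes[ed[sel, 1], , drop = FALSE]
    tv <- tv / sqrt(rowSums(tv^2))
    e <- owner[sel]
    hoop[sel] <- tv[, 1]^2 * fl[e, 1] + tv[, 2]^2 * fl[e, 2] +
      2 * tv[, 1] * tv[, 2] * fl[e, 3]
  }
  list(per_edge = hoop, mean = mean(hoop))
}

#' Iterative pre-inflation artifact removal
#'
#' Finds the self-consistent conformation of the vessel under the
#' incremental luminal pressure by fixed-point iteration: each cycle
#' solves the inflation problem on the current conformation, computes the
#' new conformation as reference geometry plus the computed displacement,
#' remeshes the deformed domain (the structured mesher avoids the skewed
#' elements plain node dragging would produce), and re-interpolates both
#' the per-element moduli and the reference coordinates from the previous
#' iteration's deformed map (containing-element / barycentric lookup,
#' nearest-neighbor fallback). Because each iteration replaces rather than
#' accumulates the inflation displacement, the conformation converges
#' geometrically; fixation artifacts such as a compressed lumen distend
#' into the physiological near-circular shape within a few iterations and
#' the excursion fields stabilize. The final iteration's model is the
#' analysis model. Iteration k of the recorded history holds the solved
#' excursion fields on conformation k; records are compared by mean
#' absolute per-element change of stress/strain excursion, matched by
#' nearest centroid.
#'
#' @param model An [fe_model()].
#' @param n_iter Number of inflation iterations (default 10).
#' @param baseline_iter Reference iteration against which later iterations
#'   are additionally compared (default 10; ignored when `n_iter` is
#'   smaller).
#' @return Object of class `preinflation`: `model` (analysis model on the
#'   final geometry), `fem` (its solved state), `history` (per-iteration
#'   excursion fields), `convergence` (data frame of mean absolute
#'   excursion changes between successive iterations, in percentage
#'   points), `baseline_comparison` (same metric between `baseline_iter`
#'   and each later iteration) and `circularity` (lumen isoperimetric
#'   circularity per iteration).
#'
#' @details Because each iteration's field lives on a slightly different
#'   conformation, fields are compared in a common frame: the earlier
#'   iteration's element centroids are carried to the later iteration's
#'   conformation (reference coordinate plus current displacement) before
#'   nearest-centroid matching. Matching raw coordinates across
#'   conformations would conflate advection with change and spuriously
#'   cross material interfaces.
#' @export
preinflate <- function(model, n_iter = 10L, baseline_iter = 10L) {
  stopifnot(inherits(model, "fe_model"))
  history <- vector("list", n_iter + 1)
  circ <- numeric(n_iter + 1)
  conv <- data.frame(iter = integer(0), d_stress_excursion_pct = numeric(0),
                     d_strain_excursion_pct = numeric(0))
  basecmp <- data.frame(iter = integer(0), d_stress_excursion_pct = numeric(0),
                        d_strain_excursion_pct = numeric(0))
  cur <- model
  # earlier iterations' element centroids: reference coords (fixed) and
  # positions carried into the current conformation for matching
  tracked <- list()
  for (k in 0:n_iter) {
    fem <- solve_inflation(cur)
    history[[k + 1]] <- list(iter = k,
                             centroids = cur$mesh$centroids,
                             stress_excursion = fem$elements$stress_excursion,
                             strain_excursion = fem$elements$strain_excursion)
    circ[k + 1] <- polygon_circularity(boundary_polygon(cur$mesh, "lumen"))
    if (k >= 1) {
      d <- excursion_change(history[[k]], history[[k + 1]], tracked[[k]]$pos,
                            cur$mesh$centroids)
      conv[nrow(conv) + 1, ] <- c(k, d[1], d[2])
    }
    if (k > baseline_iter) {
      d <- excursion_change(history[[baseline_iter + 1]], history[[k + 1]],
                            tracked[[baseline_iter + 1]]$pos, cur$mesh$centroids)
      basecmp[nrow(basecmp) + 1, ] <- c(k, d[1], d[2])
    }
    if (k == n_iter) {
      final_fem <- fem
      break
    }
    Xc <- cur$ref_coords
    tri <- cur$mesh$tri
    cent_ref <- (Xc[tri[, 1], , drop = FALSE] + Xc[tri[, 2], , drop = FALSE] +
                   Xc[tri[, 3], , drop = FALSE]) / 3
    tracked[[k + 1]] <- list(X = cent_ref, pos = cur$mesh$centroids)
    # new conformation of every tracked material point: reference + current
    # displacement evaluated at its current position
    tracked <- lapply(tracked, function(tr) {
      list(X = tr$X,
           pos = tr$X + interp_displacement(tr$pos, cur$mesh, fem$u))
    })
    cur <- inflate_step(cur, fem)
  }
  structure(list(model = cur, fem = final_fem, history = history,
                 convergence = conv, baseline_comparison = basecmp,
                 circularity = circ, n_iter = n_iter,
                 baseline_iter = baseline_iter),
            class = "preinflation")
}

# Linear interpolation of a per-node field at arbitrary points:
# barycentric weights over the containing corner triangle, nearest corner
# node fallback for points that miss the mesh by rounding. `node_xy` holds
# node coordinates (rows beyond the corner triangles are ignored), `vals`
# one row per node.
interp_node_field <- function(node_xy, tri, n_corner, vals, pts) {
  hit <- point_locate(node_xy, tri, pts)
  out <- matrix(0, nrow(pts), ncol(vals))
  ok <- hit > 0L
  if (any(ok)) {
    tr <- tri[hit[ok], , drop = FALSE]
    p1 <- node_xy[tr[, 1], , drop = FALSE]
    p2 <- node_xy[tr[, 2], , drop = FALSE]
    p3 <- node_xy[tr[, 3], , drop = FALSE]
    det <- (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
      (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2])
    px <- pts[ok, 1]; py <- pts[ok, 2]
    w3 <- ((p2[, 1] - p1[, 1]) * (py - p1[, 2]) -
             (p2[, 2] - p1[, 2]) * (px - p1[, 1])) / det
    w2 <- ((px - p1[, 1]) * (p3[, 2] - p1[, 2]) -
             (py - p1[, 2]) * (p3[, 1] - p1[, 1])) / det
    w1 <- 1 - w2 - w3
    for (m in seq_len(ncol(vals)))
      out[ok, m] <- w1 * vals[tr[, 1], m] + w2 * vals[tr[, 2], m] +
        w3 * vals[tr[, 3], m]
  }
  if (any(!ok)) {
    nn <- nearest_index(node_xy[seq_len(n_corner), , drop = FALSE],
                        pts[!ok, , drop = FALSE])
    out[!ok, ] <- vals[nn, , drop = FALSE]
  }
  out
}

# Displacement field interpolation on a mesh in its own conformation.
interp_displacement <- function(pts, mesh, u) {
  n <- nrow(mesh$nodes)
  uv <- cbind(u[2 * seq_len(n) - 1], u[2 * seq_len(n)])
  interp_node_field(mesh$nodes, mesh$tri, mesh$n_corner, uv, pts)
}

# One fixed-point inflate-remesh-reinterpolate step: the new conformation
# of each material point is its reference coordinate plus the displacement
# the current solve assigns to it.
inflate_step <- function(model, fem) {
  mesh <- model$mesh
  nc <- mesh$n_corner
  disp <- cbind(fem$u[2 * seq_len(nc) - 1], fem$u[2 * seq_len(nc)])
  newpos <- model$ref_coords + disp
  # remesh directly from the deformed boundary rings: radial skew is
  # redistributed while the boundary nodes pass through exactly, so the
  # fixed-point conformation is reproduced without resampling noise
  mesh_new <- mesh_from_rings(newpos[mesh$lumen_loop, , drop = FALSE],
                              newpos[mesh$outer_loop, , drop = FALSE],
                              mesh$n_r)
  # re-interpolate moduli from the previous deformed modulus map
  # (containing element of the old mesh in its new conformation)
  hit <- point_locate(newpos, mesh$tri, mesh_new$centroids)
  miss <- hit == 0L
  if (any(miss)) {
    old_cent <- (newpos[mesh$tri[, 1], , drop = FALSE] +
                   newpos[mesh$tri[, 2], , drop = FALSE] +
                   newpos[mesh$tri[, 3], , drop = FALSE]) / 3
    hit[miss] <- nearest_index(old_cent, mesh_new$centroids[miss, , drop = FALSE])
  }
  out <- fe_model(mesh_new, model$modulus_pa[hit], model$poisson_ratio,
                  model$pressure_mmhg, model$constraint_axis)
  # reference coordinates of the new nodes, pulled back through the
  # deformed old mesh
  out$ref_coords <- interp_node_field(newpos, mesh$tri, nc, model$ref_coords,
                                      mesh_new$nodes[seq_len(mesh_new$n_corner),
                                                     , drop = FALSE])
  out
}

# Mean absolute change (percentage points) of stress and strain excursion
# between two history records, matched by nearest centroid in a common
# configuration (rec_a's centroids advected into rec_b's frame).
excursion_change <- function(rec_a, rec_b, cent_a = rec_a$centroids,
                             cent_b = rec_b$centroids) {
  idx <- nearest_index(cent_a, cent_b)
  c(stress = 100 * mean(abs(rec_b$stress_excursion - rec_a$stress_excursion[idx])),
    strain = 100 * mean(abs(rec_b$strain_excursion - rec_a$strain_excursion[idx])))
}

#' Rasterize per-element values onto the pixel grid
#'
#' Paints each pixel with the value of the element containing its center
#' (NA outside the meshed domain). Used e.g. to couple synthetic stain
#' positivity to the strain excursion field.
#'
#' @param mesh A `vessel_mesh`.
#' @param values Per-element numeric vector.
#' @param dim_px Raster size (rows, cols).
#' @param um_per_px Micrometres per pixel.
#' @return Numeric matrix.
#' @export
rasterize_element_values <- function(mesh, values, dim_px, um_per_px) {
  stopifnot(length(values) == nrow(mesh$tri))
  pc <- pixel_centers(dim_px, um_per_px)
  pts <- cbind(rep(pc$x, each = dim_px[1]), rep(pc$y, times = dim_px[2]))
  hit <- point_locate(mesh$nodes[seq_len(mesh$n_corner), , drop = FALSE],
                      mesh$tri, pts)
  out <- rep(NA_real_, nrow(pts))
  out[hit > 0] <- values[hit[hit > 0]]
  matrix(out, dim_px[1], dim_px[2])
}
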