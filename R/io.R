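# Plain-text and image I/O: contour CSVs, label-map PNG with JSON sidecar,
# a documented text mesh format, and per-element solution CSVs.

#' Write vessel contours to CSV
#'
#' Columns: contour_name, vertex_index, x_um, y_um.
#' @param geom A [vessel_geometry()].
#' @param path Output CSV path.
#' @export
write_contours_csv <- function(geom, path) {
  rows <- lapply(c("lumen", "iel", "outer", "media_inner", "media_outer"),
                 function(nm) {
                   p <- geom[[nm]]
                   if (is.null(p)) return(NULL)
                   data.frame(contour_name = nm,
                              vertex_index = seq_len(nrow(p)),
                              # full double precision so geometry
                              # round-trips bit-exactly
                              x_um = sprintf("%.17g", p[, 1]),
                              y_um = sprintf("%.17g", p[, 2]))
                 })
  df <- do.call(rbind, rows)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read vessel contours from CSV
#' @param path CSV path written by [write_contours_csv()].
#' @param um_per_px Raster scale to attach.
#' @return A [vessel_geometry()].
#' @export
read_contours_csv <- function(path, um_per_px = 1) {
  if (!file.exists(path)) stop("contour file not found: ", path)
  df <- read.csv(path)
  need <- c("contour_name", "vertex_index", "x_um", "y_um")
  if (!all(need %in% names(df)))
    stop("contour CSV must have columns ", paste(need, collapse = ", "))
  get <- function(nm) {
    sub <- df[df$contour_name == nm, ]
    if (nrow(sub) == 0) return(NULL)
    sub <- sub[order(sub$vertex_index), ]
    cbind(sub$x_um, sub$y_um)
  }
  for (nm in c("lumen", "iel", "outer"))
    if (is.null(get(nm))) stop("contour CSV is missing contour '", nm, "'")
  vessel_geometry(get("lumen"), get("iel"), get("outer"),
                  media_inner = get("media_inner"),
                  media_outer = get("media_outer"),
                  um_per_px = um_per_px)
}

#' Write a label map as PNG plus JSON sidecar
#'
#' The PNG stores class codes as a grayscale image (code/255); the sidecar
#' `<path>.json` maps integers to class names and records the scale.
#' @param labelmap A [tissue_labelmap()].
#' @param path PNG path.
#' @export
write_labelmap <- function(labelmap, path) {
  png::writePNG(labelmap$labels / 255, path)
  side <- list(classes = as.list(setNames(names(TISSUE_CLASSES),
                                          as.character(TISSUE_CLASSES))),
               um_per_px = labelmap$um_per_px)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a label map written by [write_labelmap()]
#' @param path PNG path (expects `<path>.json` sidecar).
#' @return A [tissue_labelmap()].
#' @export
read_labelmap <- function(path) {
  if (!file.exists(path)) stop("label map not found: ", path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  tissue_labelmap(round(img * 255), side$um_per_px)
}

#' Read an RGB image (PNG or TIFF)
#' @param path Image path; format chosen by extension.
#' @return rows x cols x 3 array in 0-1.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the 'tiff' package")
    tiff::readTIFF(path)
  } else if (ext == "png") {
    png::readPNG(path)
  } else {
    stop("unsupported image format: ", path)
  }
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}

#' Write a mesh in the package's plain-text format
#'
#' Format: a header line `plaquemech-mesh n_nodes n_corner n_elem n_theta n_r`,
#' then node lines `x y`, element lines of six 1-based node indices, and
#' boundary lines `lumen|outer v1 v2 mid`.
#' @param mesh A `vessel_mesh`.
#' @param path Output path.
#' @export
write_mesh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("plaquemech-mesh %d %d %d %d %d", nrow(mesh$nodes),
                     mesh$n_corner, nrow(mesh$tri6), mesh$n_theta, mesh$n_r), con)
  writeLines(sprintf("%.9g %.9g", mesh$nodes[, 1], mesh$nodes[, 2]), con)
  writeLines(apply(mesh$tri6, 1, paste, collapse = " "), con)
  writeLines(sprintf("lumen %d %d %d", mesh$lumen_edges[, 1],
                     mesh$lumen_edges[, 2], mesh$lumen_edges[, 3]), con)
  writeLines(sprintf("outer %d %d %d", mesh$outer_edges[, 1],
                     mesh$outer_edges[, 2], mesh$outer_edges[, 3]), con)
  invisible(path)
}

#' Read a mesh written by [write_mesh()]
#' @param path Mesh file path.
#' @return A `vessel_mesh`.
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("mesh file not found: ", path)
  lines <- readLines(path)
  hdr <- strsplit(lines[1], " ")[[1]]
  if (hdr[1] != "plaquemech-mesh") stop("not a plaquemech mesh file: ", path)
  nn <- as.integer(hdr[2]); ncorner <- as.integer(hdr[3])
  ne <- as.integer(hdr[4]); n_theta <- as.integer(hdr[5]); n_r <- as.integer(hdr[6])
  off <- 1
  nodes <- do.call(rbind, lapply(strsplit(lines[off + seq_len(nn)], " "),
                                 as.numeric))
  off <- off + nn
  tri6 <- do.call(rbind, lapply(strsplit(lines[off + seq_len(ne)], " "),
                                as.integer))
  off <- off + ne
  bnd <- strsplit(lines[off + seq_len(length(lines) - off)], " ")
  tag <- vapply(bnd, `[`, "", 1)
  idx <- t(vapply(bnd, function(v) as.integer(v[2:4]), integer(3)))
  tri <- tri6[, 1:3, drop = FALSE]
  sa <- tri_signed_areas(nodes, tri)
  lum <- idx[tag == "lumen", , drop = FALSE]
  out <- idx[tag == "outer", , drop = FALSE]
  colnames(lum) <- colnames(out) <- c("v1", "v2", "mid")
  centroids <- (nodes[tri[, 1], ] + nodes[tri[, 2], ] + nodes[tri[, 3], ]) / 3
  lumen_loop <- lum[, 1]
  structure(list(nodes = nodes, n_corner = ncorner, tri = tri, tri6 = tri6,
                 n_theta = n_theta, n_r = n_r,
                 center = polygon_centroid(nodes[lumen_loop, , drop = FALSE]),
                 lumen_loop = lumen_loop, outer_loop = out[, 1],
                 lumen_edges = lum, outer_edges = out,
                 areas = sa, centroids = centroids),
            class = "vessel_mesh")
}

#' Write the per-element solution table to CSV
#'
#' Columns: element_id, centroid_x_um, centroid_y_um, modulus_pa,
#' vm_stress_pa, vm_strain, stress_excursion, strain_excursion. Floats are
#' written with 6 significant digits for byte-stable outputs.
#' @param fem A solved [solve_inflation()] result.
#' @param path Output CSV path.
#' @export
write_solution_csv <- function(fem, path) {
  el <- fem$elements
  df <- data.frame(element_id = el$element_id,
                   centroid_x_um = signif(el$centroid_x_um, 6),
                   centroid_y_um = signif(el$centroid_y_um, 6),
                   modulus_pa = signif(el$modulus_pa, 6),
                   vm_stress_pa = signif(el$vm_stress, 6),
                   vm_strain = signif(el$vm_strain, 6),
                   stress_excursion = signif(el$stress_excursion, 6),
                   strain_excursion = signif(el$strain_excursion, 6))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write per-specimen staining summary CSV
#'
#' One row per stain with the standard column semantics `<stain>_Pos`
#' (positive pixel count), `<stain>_Tot` (analysable pixel count) and
#' `<stain>_Pct` (fraction; NaN when the total is zero).
#' @param stats Named list: per stain a list with `pos`, `tot`.
#' @param path Output CSV path.
#' @export
write_staining_csv <- function(stats, path) {
  df <- data.frame(stain = names(stats),
                   Pos = vapply(stats, function(s) s$pos, 1),
                   Tot = vapply(stats, function(s) s$tot, 1))
  df$Pct <- ifelse(df$Tot > 0, df$Pos / df$Tot, NaN)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
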