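# Shared fixtures and independent oracles, all generated in code.

quick_config <- function(element_budget = 800L, ...) {
  run_config(preinflate_iters = 0L, element_budget = element_budget, ...)
}

small_phantom_spec <- function(seed = 1L, ...) {
  phantom_spec(seed = seed, image_size_px = c(128L, 128L), um_per_px = 40, ...)
}

# Lame thick-walled cylinder closed forms (plane strain / plane stress give
# identical stresses; displacement is plane strain).
lame_hoop <- function(r, a, b, p) p * a^2 / (b^2 - a^2) * (1 + b^2 / r^2)
lame_radial <- function(r, a, b, p) p * a^2 / (b^2 - a^2) * (1 - b^2 / r^2)
lame_vm_plane_strain <- function(r, a, b, p, nu) {
  st <- lame_hoop(r, a, b, p)
  sr <- lame_radial(r, a, b, p)
  sz <- nu * (st + sr)
  sqrt(0.5 * ((st - sr)^2 + (sr - sz)^2 + (sz - st)^2))
}

# Brute-force minimum enclosing circle over all vertex pairs and triples
# (oracle for small point sets).
brute_min_circle <- function(pts) {
  n <- nrow(pts)
  best <- list(radius = Inf)
  check <- function(cen, rad) {
    if (rad < best$radius &&
        all(sqrt((pts[, 1] - cen[1])^2 + (pts[, 2] - cen[2])^2) <= rad + 1e-9))
      best <<- list(center = cen, radius = rad)
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    cen <- (pts[i, ] + pts[j, ]) / 2
    check(cen, sqrt(sum((pts[i, ] - pts[j, ])^2)) / 2)
  }
  if (n >= 3) {
    for (i in seq_len(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      ax <- pts[i, 1]; ay <- pts[i, 2]; bx <- pts[j, 1]; by <- pts[j, 2]
      cx <- pts[k, 1]; cy <- pts[k, 2]
      d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
      if (abs(d) < 1e-12) next
      ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
               (cx^2 + cy^2) * (ay - by)) / d
      uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
               (cx^2 + cy^2) * (bx - ax)) / d
      check(c(ux, uy), sqrt((ax - ux)^2 + (ay - uy)^2))
    }
  }
  best
}

dice_coefficient <- function(a, b, class_code) {
  na <- sum(a == class_code); nb <- sum(b == class_code)
  if (na + nb == 0) return(NA_real_)
  2 * sum(a == class_code & b == class_code) / (na + nb)
}

# Concentric-circles test labelmap: tissue annulus between r_in and r_out,
# image centered, given pixel size.
annulus_labelmap <- function(r_in, r_out, um_per_px, n_px, class = "fibrous") {
  ctr <- n_px / 2 * um_per_px
  x <- ((1:n_px) - 0.5) * um_per_px
  r <- sqrt(outer(rep(1, n_px), x - ctr)^2 + outer(x - ctr, rep(1, n_px))^2)
  lab <- matrix(0L, n_px, n_px)
  lab[r > r_in & r <= r_out] <- plaquemech:::TISSUE_CLASSES[[class]]
  tissue_labelmap(lab, um_per_px)
}
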