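# Linking excursion fields to marker positivity. Elements of the
# fine-resolution mesh are the statistical unit: each element carries its
# stress and strain excursion and a binary flag for whether any positive
# stain pixel falls inside its footprint. Elements are pooled into a
# baseline group (excursion < 0.25) plus equal-count tertiles or deciles
# of ascending excursion; a chi-squared test gates two-proportion post hoc
# comparisons of each bin against baseline with Bonferroni correction.

#' Rotate a raster about a point (nearest-neighbor)
#'
#' @param raster Matrix (integer or numeric); values outside the source
#'   after rotation become NA.
#' @param angle_deg Rotation angle, degrees, counter-clockwise in the
#'   package axis convention.
#' @param center_um Rotation center (x, y) in micrometres.
#' @param um_per_px Micrometres per pixel.
#' @return Rotated matrix of the same shape.
#' @export
rotate_raster <- function(raster, angle_deg, center_um, um_per_px) {
  if (angle_deg %% 360 == 0) return(raster)
  nr <- nrow(raster); nc <- ncol(raster)
  pc <- pixel_centers(c(nr, nc), um_per_px)
  x <- rep(pc$x, each = nr) - center_um[1]
  y <- rep(pc$y, times = nc) - center_um[2]
  a <- -angle_deg * pi / 180 # inverse map
  xs <- center_um[1] + cos(a) * x - sin(a) * y
  ys <- center_um[2] + sin(a) * x + cos(a) * y
  cs <- as.integer(round(xs / um_per_px + 0.5))
  rs <- as.integer(round(ys / um_per_px + 0.5))
  ok <- cs >= 1 & cs <= nc & rs >= 1 & rs <= nr
  out <- rep(NA, nr * nc)
  mode(out) <- mode(raster)
  out[ok] <- raster[cbind(rs[ok], cs[ok])]
  matrix(out, nr, nc)
}

#' Attach marker positivity to the elements of an excursion field
#'
#' The stain raster is rotated about the lumen centroid by the
#' registration angle, then each mesh element is marked positive iff at
#' least one positive pixel lies in its footprint (pixel centers inside
#' the corner triangle). Masked-out pixels (NA) count neither way;
#' elements whose footprint is entirely masked out are dropped.
#'
#' @param fem A solved [solve_inflation()] result.
#' @param positivity Integer raster: 1 positive, 0 negative, NA excluded.
#' @param um_per_px Micrometres per pixel of the stain raster.
#' @param rotation_deg Registration rotation from [register_rotation()].
#' @param mask Optional logical raster; FALSE pixels are excluded.
#' @return Data frame of element observations: element_id,
#'   stress_excursion, strain_excursion, positive, n_pixels.
#' @export
attach_markers <- function(fem, positivity, um_per_px, rotation_deg = 0,
                           mask = NULL) {
  pos <- positivity
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), dim(pos)))
    pos[!mask] <- NA_integer_
  }
  pos <- rotate_raster(pos, rotation_deg, fem$mesh$center, um_per_px)
  stats <- tri_marker_stats(fem$mesh$nodes, fem$mesh$tri,
                            matrix(as.integer(pos), nrow(pos)), um_per_px)
  if (all(stats[, 1] == 0L))
    stop("no overlap between the mesh extent and the stain raster")
  keep <- stats[, 2] > 0L
  if (!any(keep))
    stop("no overlap: every element footprint is masked out")
  el <- fem$elements
  data.frame(element_id = el$element_id[keep],
             stress_excursion = el$stress_excursion[keep],
             strain_excursion = el$strain_excursion[keep],
             positive = stats[keep, 3] > 0L,
             n_pixels = stats[keep, 2])
}

#' Pool element observations into baseline + equal-count excursion bins
#'
#' All elements with excursion below `baseline_cut` (including all
#' negative excursions) form the baseline group; the remaining elements
#' are sorted by ascending excursion and split into equal-count tertiles
#' or deciles, with any remainder distributed to the lowest bins.
#'
#' @param observations Data frame from [attach_markers()] (needs columns
#'   `<metric>_excursion` and `positive`).
#' @param metric "stress" or "strain".
#' @param scheme "tertile" (3 bins) or "decile" (10 bins).
#' @param baseline_cut Baseline excursion threshold (default 0.25).
#' @return Object of class `excursion_bins` with the per-bin table (bin 0
#'   = baseline), metric, scheme and membership.
#' @export
bin_by_excursion <- function(observations,
                             metric = c("strain", "stress"),
                             scheme = c("decile", "tertile"),
                             baseline_cut = 0.25) {
  metric <- match.arg(metric)
  scheme <- match.arg(scheme)
  n_bins <- if (scheme == "tertile") 3L else 10L
  e <- observations[[paste0(metric, "_excursion")]]
  pos <- observations$positive
  if (length(e) < (n_bins + 1L) * 10L)
    warning("few observations (", length(e), "): bins will be unstable")
  membership <- integer(length(e))
  above <- which(e >= baseline_cut)
  if (length(above) == 0L)
    stop("no elements with excursion above the baseline cut")
  if (length(above) < n_bins)
    stop("fewer above-baseline elements than bins")
  ord <- above[order(e[above])]
  m <- length(ord)
  sizes <- rep(m %/% n_bins, n_bins)
  rem <- m %% n_bins
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  membership[ord] <- rep(seq_len(n_bins), times = sizes)

  tab <- do.call(rbind, lapply(0:n_bins, function(b) {
    sel <- membership == b
    data.frame(bin = b, n = sum(sel), n_pos = sum(pos[sel]),
               fraction = if (sum(sel) > 0) mean(pos[sel]) else NaN,
               e_min = if (any(sel)) min(e[sel]) else NA_real_,
               e_max = if (any(sel)) max(e[sel]) else NA_real_)
  }))
  structure(list(table = tab, metric = metric, scheme = scheme,
                 n_bins = n_bins, baseline_cut = baseline_cut,
                 membership = membership),
            class = "excursion_bins")
}

two_proportion_z <- function(x1, n1, x2, n2) {
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Chi-squared association test with two-proportion post hocs
#'
#' Tests the (groups x positive/negative) contingency table (baseline plus
#' excursion bins) with a chi-squared test. Only when the chi-squared is
#' significant at `alpha` are pooled-variance two-proportion z-tests run
#' comparing each bin against baseline, with Bonferroni adjustment
#' (`p_adj = min(1, m * p_raw)`; default m = 11 for deciles, 4 for
#' tertiles).
#'
#' @param binning An [bin_by_excursion()] result.
#' @param bonferroni_m Bonferroni factor; NULL picks the scheme default.
#' @param alpha Significance level (default 0.05).
#' @return The binning object completed with `chisq` (statistic, df, p),
#'   `posthoc` (per-bin z, p_raw, p_adj, significant; NULL when the gate
#'   fails) and `alpha`.
#' @export
test_association <- function(binning, bonferroni_m = NULL, alpha = 0.05) {
  stopifnot(inherits(binning, "excursion_bins"))
  tab <- binning$table
  if (any(tab$n == 0)) stop("empty bin in contingency table")
  if (is.null(bonferroni_m))
    bonferroni_m <- if (binning$scheme == "decile") 11L else 4L
  cont <- cbind(pos = tab$n_pos, neg = tab$n - tab$n_pos)
  chis <- suppressWarnings(chisq.test(cont, correct = FALSE))
  binning$chisq <- list(statistic = unname(chis$statistic),
                        df = unname(chis$parameter),
                        p = unname(chis$p.value))
  binning$alpha <- alpha
  binning$bonferroni_m <- bonferroni_m
  if (is.finite(binning$chisq$p) && binning$chisq$p < alpha) {
    base <- tab[tab$bin == 0, ]
    rows <- lapply(seq_len(binning$n_bins), function(b) {
      r <- tab[tab$bin == b, ]
      zt <- two_proportion_z(r$n_pos, r$n, base$n_pos, base$n)
      data.frame(bin = b, z = zt$z, p_raw = zt$p,
                 p_adj = min(1, zt$p * bonferroni_m))
    })
    ph <- do.call(rbind, rows)
    ph$significant <- ph$p_adj < alpha
    binning$posthoc <- ph
  } else {
    binning$posthoc <- NULL
  }
  binning
}

#' Compare a scalar metric between lesion phenotypes
#'
#' One-way ANOVA across phenotype groups followed by Tukey's honestly
#' significant difference test on all pairwise comparisons, with an
#' additional Bonferroni factor (default the number of pairs, 6 for four
#' phenotypes) and significance flags at `alpha`.
#'
#' @param groups Named list of numeric vectors (one per phenotype; at
#'   least 2 groups with at least 2 values each).
#' @param alpha Significance level.
#' @param bonferroni_m Bonferroni factor; NULL = number of pairs.
#' @return Object of class `phenotype_comparison` with `f`, `p`, `df`,
#'   and the pairwise table.
#' @export
compare_phenotypes <- function(groups, alpha = 0.05, bonferroni_m = NULL) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, 1L) < 2)) stop("each group needs >= 2 values")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  df <- data.frame(value = unlist(groups, use.names = FALSE),
                   group = factor(rep(names(groups),
                                      vapply(groups, length, 1L)),
                                  levels = names(groups)))
  if (sd(df$value) == 0) stop("zero variance everywhere: nothing to compare")
  fit <- aov(value ~ group, data = df)
  an <- anova(fit)
  if (an["Residuals", "Sum Sq"] <= .Machine$double.eps * sum(df$value^2))
    stop("zero within-group variance: ANOVA is degenerate")
  k <- length(groups)
  if (is.null(bonferroni_m)) bonferroni_m <- choose(k, 2)
  tk <- TukeyHSD(fit)$group
  pairs <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      p_tukey = tk[, "p adj"],
                      p_adj = pmin(1, tk[, "p adj"] * bonferroni_m),
                      row.names = NULL)
  pairs$significant <- pairs$p_adj < alpha
  structure(list(f = an["group", "F value"], p = an["group", "Pr(>F)"],
                 df = c(an["group", "Df"], an["Residuals", "Df"]),
                 pairs = pairs, alpha = alpha, bonferroni_m = bonferroni_m),
            class = "phenotype_comparison")
}
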