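#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Quadratic (6-node) straight-sided triangles in plane strain.
// Node order per element: v1, v2, v3, m12, m23, m31 (barycentric
// N_i = L_i(2L_i - 1) at corners, 4 L_i L_j at midsides). With midside
// nodes at chord midpoints the geometric map is affine, so the Jacobian
// is constant per element and comes from the corner nodes alone.

static const double GP[3][3] = {
  {2.0 / 3.0, 1.0 / 6.0, 1.0 / 6.0},
  {1.0 / 6.0, 2.0 / 3.0, 1.0 / 6.0},
  {1.0 / 6.0, 1.0 / 6.0, 2.0 / 3.0}
};
static const double GW = 1.0 / 3.0;

// dN/dL1, dN/dL2 for the 6 shape functions at barycentric (L1,L2,L3)
static void shape_deriv(double L1, double L2, double L3,
                        double dN1[6], double dN2[6]) {
  dN1[0] = 4.0 * L1 - 1.0;       dN2[0] = 0.0;
  dN1[1] = 0.0;                  dN2[1] = 4.0 * L2 - 1.0;
  dN1[2] = -(4.0 * L3 - 1.0);    dN2[2] = -(4.0 * L3 - 1.0);
  dN1[3] = 4.0 * L2;             dN2[3] = 4.0 * L1;
  dN1[4] = -4.0 * L2;            dN2[4] = 4.0 * (L3 - L2);
  dN1[5] = 4.0 * (L3 - L1);      dN2[5] = -4.0 * L1;
}

// [[Rcpp::export]]
List fem_stiffness_triplets(NumericMatrix nodes, IntegerMatrix tri6,
                            NumericVector emod, double nu) {
  const int ne = tri6.nrow();
  const int per = 12 * 12;
  IntegerVector ti(ne * per), tj(ne * per);
  NumericVector tv(ne * per);

  double dN1[6], dN2[6];
  for (int e = 0; e < ne; ++e) {
    int n1 = tri6(e, 0) - 1, n2 = tri6(e, 1) - 1, n3 = tri6(e, 2) - 1;
    double x1 = nodes(n1, 0), y1 = nodes(n1, 1);
    double x2 = nodes(n2, 0), y2 = nodes(n2, 1);
    double x3 = nodes(n3, 0), y3 = nodes(n3, 1);
    double j11 = x1 - x3, j12 = x2 - x3, j21 = y1 - y3, j22 = y2 - y3;
    double detJ = j11 * j22 - j12 * j21;
    if (detJ <= 0.0) stop("inverted or degenerate element %d", e + 1);
    // inverse transpose of J
    double a11 = j22 / detJ, a12 = -j21 / detJ;
    double a21 = -j12 / detJ, a22 = j11 / detJ;

    double E = emod[e];
    double fac = E / ((1.0 + nu) * (1.0 - 2.0 * nu));
    double D11 = fac * (1.0 - nu), D12 = fac * nu, D33 = fac * (1.0 - 2.0 * nu) / 2.0;

    double Ke[12][12];
    for (int a = 0; a < 12; ++a)
      for (int b = 0; b < 12; ++b) Ke[a][b] = 0.0;

    for (int g = 0; g < 3; ++g) {
      shape_deriv(GP[g][0], GP[g][1], GP[g][2], dN1, dN2);
      double Nx[6], Ny[6];
      for (int i = 0; i < 6; ++i) {
        Nx[i] = a11 * dN1[i] + a12 * dN2[i];
        Ny[i] = a21 * dN1[i] + a22 * dN2[i];
      }
      double w = 0.5 * GW * detJ;
      // B^T D B accumulation; dof order (u1,v1,u2,v2,...)
      for (int i = 0; i < 6; ++i) {
        for (int j = 0; j < 6; ++j) {
          // uu
          Ke[2 * i][2 * j]         += w * (Nx[i] * D11 * Nx[j] + Ny[i] * D33 * Ny[j]);
          // uv
          Ke[2 * i][2 * j + 1]     += w * (Nx[i] * D12 * Ny[j] + Ny[i] * D33 * Nx[j]);
          // vu
          Ke[2 * i + 1][2 * j]     += w * (Ny[i] * D12 * Nx[j] + Nx[i] * D33 * Ny[j]);
          // vv
          Ke[2 * i + 1][2 * j + 1] += w * (Ny[i] * D11 * Ny[j] + Nx[i] * D33 * Nx[j]);
        }
      }
    }

    int dof[12];
    for (int i = 0; i < 6; ++i) {
      int nd = tri6(e, i) - 1;
      dof[2 * i] = 2 * nd + 1;      // 1-based x dof
      dof[2 * i + 1] = 2 * nd + 2;  // 1-based y dof
    }
    int off = e * per;
    int q = 0;
    for (int a = 0; a < 12; ++a)
      for (int b = 0; b < 12; ++b) {
        ti[off + q] = dof[a];
        tj[off + q] = dof[b];
        tv[off + q] = Ke[a][b];
        ++q;
      }
  }
  return List::create(_["i"] = ti, _["j"] = tj, _["v"] = tv);
}

// Per-element stress/strain recovery at one barycentric point.
// Returns ne x 8: sx, sy, txy, sz, vm_stress, ex, ey, vm_strain
// [[Rcpp::export]]
NumericMatrix fem_element_fields(NumericMatrix nodes, IntegerMatrix tri6,
                                 NumericVector emod, double nu,
                                 NumericVector u, NumericVector bary) {
  const int ne = tri6.nrow();
  NumericMatrix out(ne, 8);
  double dN1[6], dN2[6];
  double L1 = bary[0], L2 = bary[1], L3 = bary[2];
  shape_deriv(L1, L2, L3, dN1, dN2);

  for (int e = 0; e < ne; ++e) {
    int n1 = tri6(e, 0) - 1, n2 = tri6(e, 1) - 1, n3 = tri6(e, 2) - 1;
    double j11 = nodes(n1, 0) - nodes(n3, 0), j12 = nodes(n2, 0) - nodes(n3, 0);
    double j21 = nodes(n1, 1) - nodes(n3, 1), j22 = nodes(n2, 1) - nodes(n3, 1);
    double detJ = j11 * j22 - j12 * j21;
    double a11 = j22 / detJ, a12 = -j21 / detJ;
    double a21 = -j12 / detJ, a22 = j11 / detJ;

    double exx = 0.0, eyy = 0.0, gxy = 0.0;
    for (int i = 0; i < 6; ++i) {
      double Nx = a11 * dN1[i] + a12 * dN2[i];
      double Ny = a21 * dN1[i] + a22 * dN2[i];
      int nd = tri6(e, i) - 1;
      double ux = u[2 * nd], uy = u[2 * nd + 1];
      exx += Nx * ux;
      eyy += Ny * uy;
      gxy += Ny * ux + Nx * uy;
    }

    double E = emod[e];
    double fac = E / ((1.0 + nu) * (1.0 - 2.0 * nu));
    double sx = fac * ((1.0 - nu) * exx + nu * eyy);
    double sy = fac * (nu * exx + (1.0 - nu) * eyy);
    double txy = fac * (1.0 - 2.0 * nu) / 2.0 * gxy;
    double sz = nu * (sx + sy);
    double vms = std::sqrt(0.5 * ((sx - sy) * (sx - sy) + (sy - sz) * (sy - sz) +
                                  (sz - sx) * (sz - sx)) + 3.0 * txy * txy);

    // equivalent (Von Mises) strain from the deviatoric strain tensor,
    // plane strain so ezz = 0
    double tr = exx + eyy;
    double dx = exx - tr / 3.0, dy = eyy - tr / 3.0, dz = -tr / 3.0;
    double exy = gxy / 2.0;
    double vme = std::sqrt(2.0 / 3.0 * (dx * dx + dy * dy + dz * dz + 2.0 * exy * exy));

    out(e, 0) = sx; out(e, 1) = sy; out(e, 2) = txy; out(e, 3) = sz;
    out(e, 4) = vms; out(e, 5) = exx; out(e, 6) = eyy; out(e, 7) = vme;
  }
  return out;
}

static inline bool bary_inside(double x, double y,
                               double x1, double y1, double x2, double y2,
                               double x3, double y3, double tol) {
  double det = (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1);
  if (std::fabs(det) < 1e-300) return false;
  double l1 = ((x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)) / det; // weight of v3
  double l2 = ((x - x1) * (y3 - y1) - (y - y1) * (x3 - x1)) / det; // weight of v2
  double l3 = 1.0 - l1 - l2;
  return l1 >= -tol && l2 >= -tol && l3 >= -tol;
}

// Histogram of raster label values (0..nlev-1) over pixel centers inside
// each corner triangle. Pixel (row r, col c), 1-based, has center
// x = (c - 0.5) * upp, y = (r - 0.5) * upp.
// [[Rcpp::export]]
IntegerMatrix tri_label_hist(NumericMatrix xy, IntegerMatrix tri,
                             IntegerMatrix lab, double upp, int nlev) {
  const int ne = tri.nrow();
  const int nr = lab.nrow(), nc = lab.ncol();
  IntegerMatrix out(ne, nlev);
  for (int e = 0; e < ne; ++e) {
    int a = tri(e, 0) - 1, b = tri(e, 1) - 1, c = tri(e, 2) - 1;
    double x1 = xy(a, 0), y1 = xy(a, 1), x2 = xy(b, 0), y2 = xy(b, 1);
    double x3 = xy(c, 0), y3 = xy(c, 1);
    double xmin = std::min(x1, std::min(x2, x3)), xmax = std::max(x1, std::max(x2, x3));
    double ymin = std::min(y1, std::min(y2, y3)), ymax = std::max(y1, std::max(y2, y3));
    int c0 = std::max(1, (int)std::ceil(xmin / upp + 0.5));
    int c1 = std::min(nc, (int)std::floor(xmax / upp + 0.5));
    int r0 = std::max(1, (int)std::ceil(ymin / upp + 0.5));
    int r1 = std::min(nr, (int)std::floor(ymax / upp + 0.5));
    for (int r = r0; r <= r1; ++r) {
      double py = (r - 0.5) * upp;
      for (int cc = c0; cc <= c1; ++cc) {
        double px = (cc - 0.5) * upp;
        if (bary_inside(px, py, x1, y1, x2, y2, x3, y3, 1e-9)) {
          int v = lab(r - 1, cc - 1);
          if (v != NA_INTEGER && v >= 0 && v < nlev) out(e, v) += 1;
        }
      }
    }
  }
  return out;
}

// Marker footprint statistics per element. pos: 0 = negative, 1 = positive,
// NA or negative = masked-out. Returns ne x 3: n_total, n_unmasked, n_pos.
// [[Rcpp::export]]
IntegerMatrix tri_marker_stats(NumericMatrix xy, IntegerMatrix tri,
                               IntegerMatrix pos, double upp) {
  const int ne = tri.nrow();
  const int nr = pos.nrow(), nc = pos.ncol();
  IntegerMatrix out(ne, 3);
  for (int e = 0; e < ne; ++e) {
    int a = tri(e, 0) - 1, b = tri(e, 1) - 1, c = tri(e, 2) - 1;
    double x1 = xy(a, 0), y1 = xy(a, 1), x2 = xy(b, 0), y2 = xy(b, 1);
    double x3 = xy(c, 0), y3 = xy(c, 1);
    double xmin = std::min(x1, std::min(x2, x3)), xmax = std::max(x1, std::max(x2, x3));
    double ymin = std::min(y1, std::min(y2, y3)), ymax = std::max(y1, std::max(y2, y3));
    int c0 = std::max(1, (int)std::ceil(xmin / upp + 0.5));
    int c1 = std::min(nc, (int)std::floor(xmax / upp + 0.5));
    int r0 = std::max(1, (int)std::ceil(ymin / upp + 0.5));
    int r1 = std::min(nr, (int)std::floor(ymax / upp + 0.5));
    int ntot = 0, nun = 0, npos = 0;
    for (int r = r0; r <= r1; ++r) {
      double py = (r - 0.5) * upp;
      for (int cc = c0; cc <= c1; ++cc) {
        double px = (cc - 0.5) * upp;
        if (bary_inside(px, py, x1, y1, x2, y2, x3, y3, 1e-9)) {
          ++ntot;
          int v = pos(r - 1, cc - 1);
          if (v == NA_INTEGER || v < 0) continue;
          ++nun;
          if (v > 0) ++npos;
        }
      }
    }
    out(e, 0) = ntot; out(e, 1) = nun; out(e, 2) = npos;
  }
  return out;
}

// Locate each query point in a triangulation (corner triangles).
// Returns 1-based containing element index, 0 if not found.
// Uniform grid over the mesh bounding box accelerates the search.
// [[Rcpp::export]]
IntegerVector point_locate(NumericMatrix xy, IntegerMatrix tri, NumericMatrix pts) {
  const int ne = tri.nrow();
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  for (int i = 0; i < xy.nrow(); ++i) {
    xmin = std::min(xmin, xy(i, 0)); xmax = std::max(xmax, xy(i, 0));
    ymin = std::min(ymin, xy(i, 1)); ymax = std::max(ymax, xy(i, 1));
  }
  int ng = std::max(8, (int)std::sqrt((double)ne / 2.0));
  double gx = (xmax - xmin) / ng, gy = (ymax - ymin) / ng;
  if (gx <= 0) gx = 1.0;
  if (gy <= 0) gy = 1.0;
  std::vector< std::vector<int> > cells(ng * ng);
  for (int e = 0; e < ne; ++e) {
    int a = tri(e, 0) - 1, b = tri(e, 1) - 1, c = tri(e, 2) - 1;
    double txmin = std::min(xy(a, 0), std::min(xy(b, 0), xy(c, 0)));
    double txmax = std::max(xy(a, 0), std::max(xy(b, 0), xy(c, 0)));
    double tymin = std::min(xy(a, 1), std::min(xy(b, 1), xy(c, 1)));
    double tymax = std::max(xy(a, 1), std::max(xy(b, 1), xy(c, 1)));
    int i0 = std::max(0, std::min(ng - 1, (int)((txmin - xmin) / gx)));
    int i1 = std::max(0, std::min(ng - 1, (int)((txmax - xmin) / gx)));
    int j0 = std::max(0, std::min(ng - 1, (int)((tymin - ymin) / gy)));
    int j1 = std::max(0, std::min(ng - 1, (int)((tymax - ymin) / gy)));
    for (int i = i0; i <= i1; ++i)
      for (int j = j0; j <= j1; ++j)
        cells[i * ng + j].push_back(e);
  }
  const int np = pts.nrow();
  IntegerVector out(np);
  for (int p = 0; p < np; ++p) {
    double px = pts(p, 0), py = pts(p, 1);
    out[p] = 0;
    int i = std::max(0, std::min(ng - 1, (int)((px - xmin) / gx)));
    int j = std::max(0, std::min(ng - 1, (int)((py - ymin) / gy)));
    const std::vector<int>& cand = cells[i * ng + j];
    for (size_t q = 0; q < cand.size(); ++q) {
      int e = cand[q];
      int a = tri(e, 0) - 1, b = tri(e, 1) - 1, c = tri(e, 2) - 1;
      if (bary_inside(px, py, xy(a, 0), xy(a, 1), xy(b, 0), xy(b, 1),
                      xy(c, 0), xy(c, 1), 1e-9)) {
        out[p] = e + 1;
        break;
      }
    }
  }
  return out;
}

// Index (1-based) of the nearest reference point for each query point.
// [[Rcpp::export]]
IntegerVector nearest_index(NumericMatrix ref, NumericMatrix query) {
  const int nr = ref.nrow(), nq = query.nrow();
  IntegerVector out(nq);
  for (int q = 0; q < nq; ++q) {
    double best = R_PosInf;
    int bi = 0;
    double qx = query(q, 0), qy = query(q, 1);
    for (int r = 0; r < nr; ++r) {
      double dx = ref(r, 0) - qx, dy = ref(r, 1) - qy;
      double d = dx * dx + dy * dy;
      if (d < best) { best = d; bi = r + 1; }
    }
    out[q] = bi;
  }
  return out;
}

//' Test whether points lie inside a polygon
//'
//' Even-odd (ray crossing) rule on an open polygon (last vertex not
//' repeated).
//' @param poly n x 2 vertex matrix.
//' @param pts m x 2 matrix of query points.
//' @return Logical vector of length m.
//' @export
// [[Rcpp::export]]
LogicalVector points_in_polygon(NumericMatrix poly, NumericMatrix pts) {
  const int nv = poly.nrow(), np = pts.nrow();
  LogicalVector out(np);
  for (int p = 0; p < np; ++p) {
    double x = pts(p, 0), y = pts(p, 1);
    bool inside = false;
    for (int i = 0, j = nv - 1; i < nv; j = i++) {
      double xi = poly(i, 0), yi = poly(i, 1), xj = poly(j, 0), yj = poly(j, 1);
      if (((yi > y) != (yj > y)) &&
          (x < (xj - xi) * (y - yi) / (yj - yi) + xi))
        inside = !inside;
    }
    out[p] = inside;
  }
  return out;
}

//' Signed Euclidean distance from points to a polygon boundary
//'
//' Exact point-to-boundary distance, negative inside the polygon and
//' positive outside (the signed distance function of the contour).
//' @param poly n x 2 vertex matrix (open polygon).
//' @param pts m x 2 matrix of query points.
//' @return Numeric vector of signed distances.
//' @export
// [[Rcpp::export]]
NumericVector polygon_signed_distance(NumericMatrix poly, NumericMatrix pts) {
  const int nv = poly.nrow(), np = pts.nrow();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    double x = pts(p, 0), y = pts(p, 1);
    double best = R_PosInf;
    bool inside = false;
    for (int i = 0, j = nv - 1; i < nv; j = i++) {
      double xi = poly(i, 0), yi = poly(i, 1), xj = poly(j, 0), yj = poly(j, 1);
      // crossing test
      if (((yi > y) != (yj > y)) &&
          (x < (xj - xi) * (y - yi) / (yj - yi) + xi))
        inside = !inside;
      // point-segment distance
      double dx = xi - xj, dy = yi - yj;
      double L2 = dx * dx + dy * dy;
      double t = 0.0;
      if (L2 > 0.0) {
        t = ((x - xj) * dx + (y - yj) * dy) / L2;
        t = std::max(0.0, std::min(1.0, t));
      }
      double cx = xj + t * dx, cy = yj + t * dy;
      double d = (x - cx) * (x - cx) + (y - cy) * (y - cy);
      if (d < best) best = d;
    }
    out[p] = (inside ? -1.0 : 1.0) * std::sqrt(best);
  }
  return out;
}
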