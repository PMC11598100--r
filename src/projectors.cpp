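#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Ray tracing and backprojection kernels shared by the forward simulator,
// the NMAR prior projector and the FBP/FDK reconstructors.
//
// World conventions (documented in the package vignette):
//   pixel (i,j), 0-based, row 0 = top:  x = (j - (nc-1)/2)*px,
//                                       y = ((nr-1)/2 - i)*px
//   projection angle theta (degrees, CCW): detector axis e_s = (cos, sin),
//   ray direction e_r = (-sin, cos); detector bin k (0-based) sits at
//   s_k = (k - (ndet-1)/2)*pitch.

struct Grid2D {
  int nr, nc;
  double px;      // pixel size (mm)
  double x0, y0;  // lower-left corner of the grid in world coords
  Grid2D(int nr_, int nc_, double px_) : nr(nr_), nc(nc_), px(px_) {
    x0 = -0.5 * nc * px;
    y0 = -0.5 * nr * px;
  }
};

// Walk one ray through a 2D grid, calling visit(row, col, length) for every
// traversed cell.  Origin o, unit direction d, parameter range [t0, t1].
template <typename Visit>
static void traceRay2D(const Grid2D& g, double ox, double oy, double dx,
                       double dy, double t0, double t1, Visit visit) {
  const double eps = 1e-12;
  // clip to grid bounding box
  double tx0 = -INFINITY, tx1 = INFINITY, ty0 = -INFINITY, ty1 = INFINITY;
  if (std::fabs(dx) > eps) {
    tx0 = (g.x0 - ox) / dx;
    tx1 = (g.x0 + g.nc * g.px - ox) / dx;
    if (tx0 > tx1) std::swap(tx0, tx1);
  } else if (ox < g.x0 || ox > g.x0 + g.nc * g.px) {
    return;
  }
  if (std::fabs(dy) > eps) {
    ty0 = (g.y0 - oy) / dy;
    ty1 = (g.y0 + g.nr * g.px - oy) / dy;
    if (ty0 > ty1) std::swap(ty0, ty1);
  } else if (oy < g.y0 || oy > g.y0 + g.nr * g.px) {
    return;
  }
  double ta = std::max(std::max(tx0, ty0), t0);
  double tb = std::min(std::min(tx1, ty1), t1);
  if (tb - ta <= eps) return;

  double t = ta;
  // current cell from the midpoint of the first (possibly whole) segment
  double mx = ox + 0.5 * (ta + tb) * dx, my = oy + 0.5 * (ta + tb) * dy;
  int j = (int)std::floor((ox + (ta + eps) * dx - g.x0) / g.px);
  int i = (int)std::floor((oy + (ta + eps) * dy - g.y0) / g.px);
  (void)mx; (void)my;
  if (j < 0) j = 0; if (j >= g.nc) j = g.nc - 1;
  if (i < 0) i = 0; if (i >= g.nr) i = g.nr - 1;

  int stepj = (dx > eps) ? 1 : (dx < -eps ? -1 : 0);
  int stepi = (dy > eps) ? 1 : (dy < -eps ? -1 : 0);
  double tnx = INFINITY, tny = INFINITY;
  double dtx = INFINITY, dty = INFINITY;
  if (stepj != 0) {
    double xedge = g.x0 + (j + (stepj > 0 ? 1 : 0)) * g.px;
    tnx = (xedge - ox) / dx;
    dtx = g.px / std::fabs(dx);
  }
  if (stepi != 0) {
    double yedge = g.y0 + (i + (stepi > 0 ? 1 : 0)) * g.px;
    tny = (yedge - oy) / dy;
    dty = g.px / std::fabs(dy);
  }
  while (t < tb - eps) {
    double tn = std::min(std::min(tnx, tny), tb);
    double len = tn - t;
    if (len > 0) {
      // grid row index from world y (row 0 = top)
      int row = g.nr - 1 - i;
      visit(row, j, len);
    }
    if (tnx <= tny && tnx <= tb) {
      j += stepj;
      tnx += dtx;
    } else if (tny < tnx && tny <= tb) {
      i += stepi;
      tny += dty;
    }
    t = tn;
    if (j < 0 || j >= g.nc || i < 0 || i >= g.nr) break;
  }
}

// [[Rcpp::export]]
NumericVector cpp_project_labels_par2d(IntegerMatrix labels, int nmat,
                                       NumericVector angles_deg, int ndet,
                                       double px, double pitch) {
  int nr = labels.nrow(), nc = labels.ncol(), na = angles_deg.size();
  Grid2D g(nr, nc, px);
  NumericVector out(na * (double)ndet * nmat);
  out.attr("dim") = IntegerVector::create(na, ndet, nmat);
  double T = (nr + nc) * px;  // safely outside the grid
  for (int a = 0; a < na; ++a) {
    double th = angles_deg[a] * M_PI / 180.0;
    double cs = std::cos(th), sn = std::sin(th);
    for (int k = 0; k < ndet; ++k) {
      double s = (k - 0.5 * (ndet - 1)) * pitch;
      // o = s*e_s - T*e_r with e_s = (cs, sn), e_r = (-sn, cs)
      double ox = s * cs + T * sn;
      double oy = s * sn - T * cs;
      double* acc = &out[0];
      traceRay2D(g, ox, oy, -sn, cs, 0.0, 2.0 * T,
                 [&](int row, int col, double len) {
                   int m = labels(row, col);
                   if (m > 0 && m <= nmat)
                     acc[(size_t)a + (size_t)na * k +
                         (size_t)na * ndet * (m - 1)] += len;
                 });
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_project_image_par2d(NumericMatrix img,
                                      NumericVector angles_deg, int ndet,
                                      double px, double pitch) {
  int nr = img.nrow(), nc = img.ncol(), na = angles_deg.size();
  Grid2D g(nr, nc, px);
  NumericMatrix out(na, ndet);
  double T = (nr + nc) * px;
  for (int a = 0; a < na; ++a) {
    double th = angles_deg[a] * M_PI / 180.0;
    double cs = std::cos(th), sn = std::sin(th);
    for (int k = 0; k < ndet; ++k) {
      double s = (k - 0.5 * (ndet - 1)) * pitch;
      double ox = s * cs + T * sn;
      double oy = s * sn - T * cs;
      double sum = 0.0;
      traceRay2D(g, ox, oy, -sn, cs, 0.0, 2.0 * T,
                 [&](int row, int col, double len) { sum += img(row, col) * len; });
      out(a, k) = sum;
    }
  }
  return out;
}

// Pixel-driven parallel-beam backprojection with linear interpolation.
// q: filtered sinogram (nang x ndet).  Returns n x n slice (no angular
// weighting; the caller multiplies by pi/nang).
// [[Rcpp::export]]
NumericMatrix cpp_backproject_par2d(NumericMatrix q, NumericVector angles_deg,
                                    int n, double px, double pitch) {
  int na = q.nrow(), ndet = q.ncol();
  NumericMatrix out(n, n);
  std::vector<double> cs(na), sn(na);
  for (int a = 0; a < na; ++a) {
    double th = angles_deg[a] * M_PI / 180.0;
    cs[a] = std::cos(th);
    sn[a] = std::sin(th);
  }
  double c0 = 0.5 * (n - 1), d0 = 0.5 * (ndet - 1);
  for (int i = 0; i < n; ++i) {
    double y = (c0 - i) * px;
    for (int j = 0; j < n; ++j) {
      double x = (j - c0) * px;
      double sum = 0.0;
      for (int a = 0; a < na; ++a) {
        double s = x * cs[a] + y * sn[a];
        double u = s / pitch + d0;
        int k = (int)std::floor(u);
        if (k < 0 || k >= ndet - 1) continue;
        double w = u - k;
        sum += (1.0 - w) * q(a, k) + w * q(a, k + 1);
      }
      out(i, j) = sum;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// 3D Siddon tracing for the cone-beam forward simulator.

struct Grid3D {
  int nr, nc, nz;
  double px;
  double x0, y0, z0;
  Grid3D(int nr_, int nc_, int nz_, double px_)
      : nr(nr_), nc(nc_), nz(nz_), px(px_) {
    x0 = -0.5 * nc * px;
    y0 = -0.5 * nr * px;
    z0 = -0.5 * nz * px;
  }
};

template <typename Visit>
static void traceRay3D(const Grid3D& g, const double o[3], const double d[3],
                       double t0, double t1, Visit visit) {
  const double eps = 1e-12;
  double lo[3] = {g.x0, g.y0, g.z0};
  double hi[3] = {g.x0 + g.nc * g.px, g.y0 + g.nr * g.px, g.z0 + g.nz * g.px};
  double ta = t0, tb = t1;
  for (int ax = 0; ax < 3; ++ax) {
    if (std::fabs(d[ax]) > eps) {
      double u0 = (lo[ax] - o[ax]) / d[ax], u1 = (hi[ax] - o[ax]) / d[ax];
      if (u0 > u1) std::swap(u0, u1);
      ta = std::max(ta, u0);
      tb = std::min(tb, u1);
    } else if (o[ax] < lo[ax] || o[ax] > hi[ax]) {
      return;
    }
  }
  if (tb - ta <= eps) return;
  int idx[3], step[3];
  double tnext[3], dt[3];
  int nmax[3] = {g.nc, g.nr, g.nz};
  for (int ax = 0; ax < 3; ++ax) {
    idx[ax] = (int)std::floor((o[ax] + (ta + eps) * d[ax] - lo[ax]) / g.px);
    if (idx[ax] < 0) idx[ax] = 0;
    if (idx[ax] >= nmax[ax]) idx[ax] = nmax[ax] - 1;
    step[ax] = (d[ax] > eps) ? 1 : (d[ax] < -eps ? -1 : 0);
    if (step[ax] != 0) {
      double edge = lo[ax] + (idx[ax] + (step[ax] > 0 ? 1 : 0)) * g.px;
      tnext[ax] = (edge - o[ax]) / d[ax];
      dt[ax] = g.px / std::fabs(d[ax]);
    } else {
      tnext[ax] = INFINITY;
      dt[ax] = INFINITY;
    }
  }
  double t = ta;
  while (t < tb - eps) {
    int ax = 0;
    if (tnext[1] < tnext[ax]) ax = 1;
    if (tnext[2] < tnext[ax]) ax = 2;
    double tn = std::min(tnext[ax], tb);
    double len = tn - t;
    if (len > 0) {
      int row = g.nr - 1 - idx[1];
      visit(row, idx[0], idx[2], len);
    }
    if (tnext[ax] <= tb) {
      idx[ax] += step[ax];
      tnext[ax] += dt[ax];
    }
    t = tn;
    if (idx[0] < 0 || idx[0] >= g.nc || idx[1] < 0 || idx[1] >= g.nr ||
        idx[2] < 0 || idx[2] >= g.nz)
      break;
  }
}

// labels: nr x nc x nz integer array (0 = air).  Source orbits in the z = 0
// plane at radius R; flat detector at distance D from the source, pitch in
// real-detector mm.  Returns (nv, nu, nmat, nang) path lengths.
// [[Rcpp::export]]
NumericVector cpp_project_labels_cone3d(IntegerVector labels, int nr, int nc,
                                        int nz, int nmat,
                                        NumericVector angles_deg, int nu,
                                        int nv, double px, double R, double D,
                                        double pitch) {
  Grid3D g(nr, nc, nz, px);
  int na = angles_deg.size();
  NumericVector out((double)nv * nu * nmat * na);
  out.attr("dim") = IntegerVector::create(nv, nu, nmat, na);
  const int* lab = INTEGER(labels);
  double* acc = REAL(out);
  for (int a = 0; a < na; ++a) {
    double th = angles_deg[a] * M_PI / 180.0;
    double cs = std::cos(th), sn = std::sin(th);
    // e_r = (-sn, cs, 0), e_s = (cs, sn, 0); source at -R*e_r
    double S[3] = {R * sn, -R * cs, 0.0};
    for (int r = 0; r < nv; ++r) {
      double v = (0.5 * (nv - 1) - r) * pitch;
      for (int k = 0; k < nu; ++k) {
        double u = (k - 0.5 * (nu - 1)) * pitch;
        double P[3] = {S[0] + D * (-sn) + u * cs, S[1] + D * cs + u * sn, v};
        double d[3] = {P[0] - S[0], P[1] - S[1], P[2] - S[2]};
        double norm = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
        for (int ax = 0; ax < 3; ++ax) d[ax] /= norm;
        traceRay3D(g, S, d, 0.0, 2.0 * norm,
                   [&](int row, int col, int slice, double len) {
                     int m = lab[row + (size_t)nr * col + (size_t)nr * nc * slice];
                     if (m > 0 && m <= nmat)
                       acc[r + (size_t)nv * k + (size_t)nv * nu * (m - 1) +
                           (size_t)nv * nu * nmat * a] += len;
                   });
      }
    }
  }
  return out;
}

// FDK voxel-driven backprojection on the virtual (isocentre) detector.
// q: cosine-weighted, ramp-filtered projections (nv x nu x nang) sampled at
// virtual pitch; returns (n, n, nzv) volume of unweighted sums of
// (R^2 / l^2) * q(u', v'); the caller multiplies by dbeta/2.
// [[Rcpp::export]]
NumericVector cpp_fdk_backproject(NumericVector q, int nv, int nu,
                                  NumericVector angles_deg, int n, int nzv,
                                  double px, double R, double vpitch) {
  int na = angles_deg.size();
  NumericVector out((double)n * n * nzv);
  out.attr("dim") = IntegerVector::create(n, n, nzv);
  const double* Q = REAL(q);
  double* O = REAL(out);
  double c0 = 0.5 * (n - 1), z0 = 0.5 * (nzv - 1);
  double u0 = 0.5 * (nu - 1), v0 = 0.5 * (nv - 1);
  for (int a = 0; a < na; ++a) {
    double th = angles_deg[a] * M_PI / 180.0;
    double cs = std::cos(th), sn = std::sin(th);
    const double* Qa = Q + (size_t)nv * nu * a;
    for (int sl = 0; sl < nzv; ++sl) {
      double z = (sl - z0) * px;
      for (int j = 0; j < n; ++j) {
        double x = (j - c0) * px;
        for (int i = 0; i < n; ++i) {
          double y = (c0 - i) * px;
          double l = R + (-sn) * x + cs * y;  // distance along central ray
          if (l < 1e-6) continue;
          double up = R * (x * cs + y * sn) / l;
          double vp = R * z / l;
          double uu = up / vpitch + u0;
          double vv = v0 - vp / vpitch;  // row 0 = top
          int ku = (int)std::floor(uu), kv = (int)std::floor(vv);
          if (ku < 0 || ku >= nu - 1 || kv < 0 || kv >= nv - 1) continue;
          double wu = uu - ku, wv = vv - kv;
          double val = (1 - wv) * ((1 - wu) * Qa[kv + (size_t)nv * ku] +
                                   wu * Qa[kv + (size_t)nv * (ku + 1)]) +
                       wv * ((1 - wu) * Qa[kv + 1 + (size_t)nv * ku] +
                             wu * Qa[kv + 1 + (size_t)nv * (ku + 1)]);
          O[i + (size_t)n * j + (size_t)n * n * sl] += (R * R) / (l * l) * val;
        }
      }
    }
  }
  return out;
}

// Zero-padded "same" separable convolution: k applied along columns then rows.
// k must have odd length.
// [[Rcpp::export]]
NumericMatrix cpp_sepconv(NumericMatrix x, NumericVector k) {
  int nr = x.nrow(), nc = x.ncol(), m = k.size(), h = m / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  // along rows (vertical)
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double s = 0.0;
      int a0 = std::max(0, h - i), a1 = std::min(m, nr + h - i);
      for (int a = a0; a < a1; ++a) s += k[a] * x(i + a - h, j);
      tmp(i, j) = s;
    }
  }
  // along columns (horizontal)
  for (int j = 0; j < nc; ++j) {
    int a0 = std::max(0, h - j), a1 = std::min(m, nc + h - j);
    for (int i = 0; i < nr; ++i) {
      double s = 0.0;
      for (int a = a0; a < a1; ++a) s += k[a] * tmp(i, j + a - h);
      out(i, j) = s;
    }
  }
  return out;
}

// Exact dense convolution of a sparse image with the radial kernel w(d) =
// d^-p (w(0) = 0): the oracle the pyramid filters are fitted against.
// [[Rcpp::export]]
NumericMatrix cpp_radial_convolve(NumericMatrix x, double p) {
  int nr = x.nrow(), nc = x.ncol();
  NumericMatrix out(nr, nc);
  std::vector<int> si, sj;
  std::vector<double> sv;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (x(i, j) != 0.0) {
        si.push_back(i);
        sj.push_back(j);
        sv.push_back(x(i, j));
      }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double s = 0.0;
      for (size_t t = 0; t < sv.size(); ++t) {
        double di = i - si[t], dj = j - sj[t];
        double d2 = di * di + dj * dj;
        if (d2 > 0) s += sv[t] * std::pow(d2, -0.5 * p);
      }
      out(i, j) = s;
    }
  return out;
}
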