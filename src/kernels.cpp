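// Low-level 3D image kernels: trilinear/nearest resampling under the
// pull-back convention, displacement-field algebra (composition, fixed-point
// inversion, scaling-and-squaring), Jacobian determinants, separable Gaussian
// smoothing, cubic B-spline lattice evaluation/projection, exact Euclidean
// distance transforms, and binary 3D morphology / connected components.
//
// Conventions shared with the R layer:
//   - arrays are column-major with dims (d1, d2, d3); vector fields append a
//     trailing component dimension (d1, d2, d3, 3);
//   - physical coordinate of voxel (i, j, k) (0-based here) is
//     origin + c(i, j, k) * spacing, in mm;
//   - displacement fields map fixed-grid points x to moving-space points
//     x + u(x); intensity samples outside the moving domain read as `fill`,
//     vector samples outside the domain are edge-clamped.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
#include <limits>
using namespace Rcpp;

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Trilinear interpolation of a scalar array at continuous 0-based index
// coordinates; out-of-domain reads return `fill`.
static double sample_linear(const double* a, int d1, int d2, int d3,
                            double x, double y, double z, double fill) {
  if (x < 0 || y < 0 || z < 0 || x > d1 - 1 || y > d2 - 1 || z > d3 - 1)
    return fill;
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  if (i0 == d1 - 1) i0--;
  if (j0 == d2 - 1) j0--;
  if (k0 == d3 - 1) k0--;
  if (i0 < 0) i0 = 0;
  if (j0 < 0) j0 = 0;
  if (k0 < 0) k0 = 0;
  double fx = x - i0, fy = y - j0, fz = z - k0;
  const R_xlen_t s1 = 1, s2 = d1, s3 = (R_xlen_t)d1 * d2;
  const double* p = a + i0 * s1 + j0 * s2 + k0 * s3;
  double c00 = p[0] * (1 - fx) + p[s1] * fx;
  double c10 = p[s2] * (1 - fx) + p[s2 + s1] * fx;
  double c01 = p[s3] * (1 - fx) + p[s3 + s1] * fx;
  double c11 = p[s3 + s2] * (1 - fx) + p[s3 + s2 + s1] * fx;
  return (c00 * (1 - fy) + c10 * fy) * (1 - fz) +
         (c01 * (1 - fy) + c11 * fy) * fz;
}

static double sample_nearest(const double* a, int d1, int d2, int d3,
                             double x, double y, double z, double fill) {
  int i = (int)std::floor(x + 0.5), j = (int)std::floor(y + 0.5),
      k = (int)std::floor(z + 0.5);
  if (i < 0 || j < 0 || k < 0 || i >= d1 || j >= d2 || k >= d3) return fill;
  return a[i + (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k)];
}

// Edge-clamped trilinear sample (used for vector components so that field
// algebra near the boundary stays stable).
static inline double sample_clamped(const double* a, int d1, int d2, int d3,
                                    double x, double y, double z) {
  return sample_linear(a, d1, d2, d3, clampd(x, 0, d1 - 1),
                       clampd(y, 0, d2 - 1), clampd(z, 0, d3 - 1), 0.0);
}

// [[Rcpp::export(name = ".C_warp")]]
NumericVector C_warp(NumericVector vol, IntegerVector vdim,
                     NumericVector vspacing, NumericVector vorigin,
                     NumericVector field, IntegerVector fdim,
                     NumericVector fspacing, NumericVector forigin,
                     int nearest, double fill) {
  const int d1 = fdim[0], d2 = fdim[1], d3 = fdim[2];
  const int m1 = vdim[0], m2 = vdim[1], m3 = vdim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  NumericVector out(n);
  const double *v = REAL(vol), *u = REAL(field);
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        R_xlen_t idx = i + (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k);
        double px = forigin[0] + i * fspacing[0] + u[idx];
        double py = forigin[1] + j * fspacing[1] + u[idx + n];
        double pz = forigin[2] + k * fspacing[2] + u[idx + 2 * n];
        double x = (px - vorigin[0]) / vspacing[0];
        double y = (py - vorigin[1]) / vspacing[1];
        double z = (pz - vorigin[2]) / vspacing[2];
        out[idx] = nearest ? sample_nearest(v, m1, m2, m3, x, y, z, fill)
                           : sample_linear(v, m1, m2, m3, x, y, z, fill);
      }
  return out;
}

// Composition under pull-back warping: result(x) = inner(x) + outer(x + u_inner(x)),
// so that warping by the result equals warping by `outer` then by `inner`.
// Both fields share one grid.
// [[Rcpp::export(name = ".C_compose")]]
NumericVector C_compose(NumericVector outer, NumericVector inner,
                        IntegerVector dim, NumericVector spacing) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  NumericVector out(3 * n);
  const double *uo = REAL(outer), *ui = REAL(inner);
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        R_xlen_t idx = i + (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k);
        double x = i + ui[idx] / spacing[0];
        double y = j + ui[idx + n] / spacing[1];
        double z = k + ui[idx + 2 * n] / spacing[2];
        for (int c = 0; c < 3; ++c)
          out[idx + c * n] = ui[idx + c * n] +
            sample_clamped(uo + c * n, d1, d2, d3, x, y, z);
      }
  return out;
}

// Fixed-point inversion: u_inv(x) <- -u(x + u_inv(x)); iterate until the
// largest update falls below tol (mm) or max_iter is hit.  Returns the
// inverse with attributes `residual` (last max update, mm) and `converged`.
// [[Rcpp::export(name = ".C_invert")]]
NumericVector C_invert(NumericVector field, IntegerVector dim,
                       NumericVector spacing, double tol, int max_iter) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  NumericVector inv(3 * n);
  std::vector<double> nxt(3 * n);
  const double* u = REAL(field);
  double resid = R_PosInf;
  bool conv = false;
  for (int it = 0; it < max_iter; ++it) {
    resid = 0.0;
    double* vi = REAL(inv);
    for (int k = 0; k < d3; ++k)
      for (int j = 0; j < d2; ++j)
        for (int i = 0; i < d1; ++i) {
          R_xlen_t idx = i + (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k);
          double x = i + vi[idx] / spacing[0];
          double y = j + vi[idx + n] / spacing[1];
          double z = k + vi[idx + 2 * n] / spacing[2];
          for (int c = 0; c < 3; ++c) {
            double val = -sample_clamped(u + c * n, d1, d2, d3, x, y, z);
            double dchg = std::fabs(val - vi[idx + c * n]);
            if (dchg > resid) resid = dchg;
            nxt[idx + c * n] = val;
          }
        }
    std::copy(nxt.begin(), nxt.end(), REAL(inv));
    if (resid < tol) { conv = true; break; }
  }
  inv.attr("residual") = resid;
  inv.attr("converged") = conv;
  return inv;
}

// det(I + grad u) with central differences in the interior and one-sided
// differences at the boundary; derivatives are taken w.r.t. physical mm.
// [[Rcpp::export(name = ".C_jacdet")]]
NumericVector C_jacdet(NumericVector field, IntegerVector dim,
                       NumericVector spacing) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  NumericVector out(n);
  const double* u = REAL(field);
  const R_xlen_t st[3] = {1, (R_xlen_t)d1, (R_xlen_t)d1 * d2};
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        R_xlen_t idx = i + (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k);
        double J[3][3];
        int pos[3] = {i, j, k};
        int dmax[3] = {d1, d2, d3};
        for (int ax = 0; ax < 3; ++ax) {  // derivative axis
          R_xlen_t hi = idx, lo = idx;
          double den;
          if (pos[ax] == 0) { hi = idx + st[ax]; den = spacing[ax]; }
          else if (pos[ax] == dmax[ax] - 1) { lo = idx - st[ax]; den = spacing[ax]; }
          else { hi = idx + st[ax]; lo = idx - st[ax]; den = 2.0 * spacing[ax]; }
          for (int c = 0; c < 3; ++c)
            J[c][ax] = (u[hi + c * n] - u[lo + c * n]) / den;
        }
        for (int c = 0; c < 3; ++c) J[c][c] += 1.0;
        out[idx] = J[0][0] * (J[1][1] * J[2][2] - J[1][2] * J[2][1]) -
                   J[0][1] * (J[1][0] * J[2][2] - J[1][2] * J[2][0]) +
                   J[0][2] * (J[1][0] * J[2][1] - J[1][1] * J[2][0]);
      }
  return out;
}

// Separable Gaussian smoothing with reflected boundaries; sigma per axis in
// voxels, radius 4*sigma.  sigma <= 0 skips the axis.
// [[Rcpp::export(name = ".C_gauss3d")]]
NumericVector C_gauss3d(NumericVector arr, IntegerVector dim,
                        NumericVector sigma) {
  const int d[3] = {dim[0], dim[1], dim[2]};
  const R_xlen_t n = (R_xlen_t)d[0] * d[1] * d[2];
  NumericVector out = clone(arr);
  std::vector<double> tmp(n);
  const R_xlen_t st[3] = {1, (R_xlen_t)d[0], (R_xlen_t)d[0] * d[1]};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int r = (int)std::ceil(4.0 * s);
    std::vector<double> w(2 * r + 1);
    double tot = 0;
    for (int t = -r; t <= r; ++t) {
      w[t + r] = std::exp(-0.5 * t * t / (s * s));
      tot += w[t + r];
    }
    for (double& x : w) x /= tot;
    double* src = REAL(out);
    // iterate over all lines along ax
    int o1 = (ax + 1) % 3, o2 = (ax + 2) % 3;
    for (int b = 0; b < d[o2]; ++b)
      for (int a = 0; a < d[o1]; ++a) {
        R_xlen_t base = a * st[o1] + b * st[o2];
        int len = d[ax];
        for (int p = 0; p < len; ++p) {
          double acc = 0;
          for (int t = -r; t <= r; ++t) {
            int q = p + t;
            // reflect (whole-sample symmetric)
            while (q < 0 || q >= len) {
              if (q < 0) q = -q;
              if (q >= len) q = 2 * (len - 1) - q;
            }
            acc += w[t + r] * src[base + q * st[ax]];
          }
          tmp[base + p * st[ax]] = acc;
        }
      }
    std::copy(tmp.begin(), tmp.end(), REAL(out));
  }
  return out;
}

// ---- cubic B-spline lattice ------------------------------------------------
// Control point m (0-based) along an axis sits at voxel coordinate
// (m - 1) * delta, so one ring of control points lies outside the image on
// each side.  Given voxel x in [0, D-1]: i = floor(x/delta), local u = x/delta - i,
// supported control indices are i .. i+3 in lattice numbering.

static void bspline_w(double t, int deriv, double* w) {
  if (deriv == 0) {
    double s = 1 - t;
    w[0] = s * s * s / 6.0;
    w[1] = (3 * t * t * t - 6 * t * t + 4) / 6.0;
    w[2] = (-3 * t * t * t + 3 * t * t + 3 * t + 1) / 6.0;
    w[3] = t * t * t / 6.0;
  } else if (deriv == 1) {
    double s = 1 - t;
    w[0] = -s * s / 2.0;
    w[1] = (9 * t * t - 12 * t) / 6.0;
    w[2] = (-9 * t * t + 6 * t + 3) / 6.0;
    w[3] = t * t / 2.0;
  } else {  // second derivative
    w[0] = 1 - t;
    w[1] = 3 * t - 2;
    w[2] = 1 - 3 * t;
    w[3] = t;
  }
}

// Evaluate a coefficient lattice (nc1, nc2, nc3, ncomp) on a dense grid of
// dims gdim, control spacing delta (voxels per axis), derivative order per
// axis in {0, 1, 2}.  Derivatives are returned w.r.t. voxel units divided by
// `scale` per axis (pass spacing to get mm derivatives).
// [[Rcpp::export(name = ".C_bspline_eval")]]
NumericVector C_bspline_eval(NumericVector coef, IntegerVector cdim,
                             IntegerVector gdim, NumericVector delta,
                             IntegerVector deriv, NumericVector scale) {
  const int d1 = gdim[0], d2 = gdim[1], d3 = gdim[2];
  const int c1 = cdim[0], c2 = cdim[1], c3 = cdim[2], nc = cdim[3];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  const R_xlen_t cn = (R_xlen_t)c1 * c2 * c3;
  NumericVector out(n * nc);
  const double* cf = REAL(coef);
  // per-axis weight tables
  std::vector<std::vector<double>> W(3);
  std::vector<std::vector<int>> I(3);
  const int dd[3] = {d1, d2, d3};
  for (int ax = 0; ax < 3; ++ax) {
    W[ax].resize(4 * dd[ax]);
    I[ax].resize(dd[ax]);
    double fac = 1.0;
    for (int q = 0; q < deriv[ax]; ++q) fac /= (delta[ax] * scale[ax]);
    for (int p = 0; p < dd[ax]; ++p) {
      double xc = p / delta[ax];
      int i = (int)std::floor(xc);
      double t = xc - i;
      I[ax][p] = i;  // lattice support starts at i (0-based lattice index)
      bspline_w(t, deriv[ax], &W[ax][4 * p]);
      for (int l = 0; l < 4; ++l) W[ax][4 * p + l] *= fac;
    }
  }
  for (int k = 0; k < d3; ++k) {
    const double* wz = &W[2][4 * k];
    int kz = I[2][k];
    for (int j = 0; j < d2; ++j) {
      const double* wy = &W[1][4 * j];
      int jy = I[1][j];
      for (int i = 0; i < d1; ++i) {
        const double* wx = &W[0][4 * i];
        int ix = I[0][i];
        R_xlen_t idx = i + (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k);
        for (int c = 0; c < nc; ++c) {
          double acc = 0;
          for (int lz = 0; lz < 4; ++lz) {
            int mz = kz + lz;
            if (mz >= c3) mz = c3 - 1;
            double wzz = wz[lz];
            for (int ly = 0; ly < 4; ++ly) {
              int my = jy + ly;
              if (my >= c2) my = c2 - 1;
              double wyz = wy[ly] * wzz;
              R_xlen_t off = (R_xlen_t)c1 * (my + (R_xlen_t)c2 * mz) + c * cn;
              for (int lx = 0; lx < 4; ++lx) {
                int mx = ix + lx;
                if (mx >= c1) mx = c1 - 1;
                acc += wx[lx] * wyz * cf[mx + off];
              }
            }
          }
          out[idx + c * n] = acc;
        }
      }
    }
  }
  return out;
}

// Transpose of C_bspline_eval: scatter a dense (gdim, ncomp) array into
// lattice-coefficient space with the same weights.  Used for chain-rule
// gradients (image force and bending energy).
// [[Rcpp::export(name = ".C_bspline_project")]]
NumericVector C_bspline_project(NumericVector dense, IntegerVector cdim,
                                IntegerVector gdim, NumericVector delta,
                                IntegerVector deriv, NumericVector scale) {
  const int d1 = gdim[0], d2 = gdim[1], d3 = gdim[2];
  const int c1 = cdim[0], c2 = cdim[1], c3 = cdim[2], nc = cdim[3];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  const R_xlen_t cn = (R_xlen_t)c1 * c2 * c3;
  NumericVector out(cn * nc);
  const double* dn = REAL(dense);
  std::vector<std::vector<double>> W(3);
  std::vector<std::vector<int>> I(3);
  const int dd[3] = {d1, d2, d3};
  for (int ax = 0; ax < 3; ++ax) {
    W[ax].resize(4 * dd[ax]);
    I[ax].resize(dd[ax]);
    double fac = 1.0;
    for (int q = 0; q < deriv[ax]; ++q) fac /= (delta[ax] * scale[ax]);
    for (int p = 0; p < dd[ax]; ++p) {
      double xc = p / delta[ax];
      int i = (int)std::floor(xc);
      double t = xc - i;
      I[ax][p] = i;
      bspline_w(t, deriv[ax], &W[ax][4 * p]);
      for (int l = 0; l < 4; ++l) W[ax][4 * p + l] *= fac;
    }
  }
  double* o = REAL(out);
  for (int k = 0; k < d3; ++k) {
    const double* wz = &W[2][4 * k];
    int kz = I[2][k];
    for (int j = 0; j < d2; ++j) {
      const double* wy = &W[1][4 * j];
      int jy = I[1][j];
      for (int i = 0; i < d1; ++i) {
        const double* wx = &W[0][4 * i];
        int ix = I[0][i];
        R_xlen_t idx = i + (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k);
        for (int c = 0; c < nc; ++c) {
          double val = dn[idx + c * n];
          if (val == 0) continue;
          for (int lz = 0; lz < 4; ++lz) {
            int mz = kz + lz;
            if (mz >= c3) mz = c3 - 1;
            double wzz = wz[lz] * val;
            for (int ly = 0; ly < 4; ++ly) {
              int my = jy + ly;
              if (my >= c2) my = c2 - 1;
              double wyz = wy[ly] * wzz;
              R_xlen_t off = (R_xlen_t)c1 * (my + (R_xlen_t)c2 * mz) + c * cn;
              for (int lx = 0; lx < 4; ++lx) {
                int mx = ix + lx;
                if (mx >= c1) mx = c1 - 1;
                o[mx + off] += wx[lx] * wyz;
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// ---- exact Euclidean distance transform (Felzenszwalb & Huttenlocher) ------
// 1D squared-distance transform over samples at positions p * w; +inf
// entries (no source on that sample) are compacted away before building the
// lower envelope of parabolas.
static void edt1d(const std::vector<double>& f, std::vector<double>& dout,
                  int nsamp, double w) {
  const double inf = std::numeric_limits<double>::infinity();
  std::vector<int> fin;
  fin.reserve(nsamp);
  for (int q = 0; q < nsamp; ++q)
    if (f[q] < inf) fin.push_back(q);
  if (fin.empty()) {
    std::fill(dout.begin(), dout.begin() + nsamp, inf);
    return;
  }
  int m = (int)fin.size();
  std::vector<int> v(m);
  std::vector<double> z(m + 1);
  int kk = 0;
  v[0] = fin[0];
  z[0] = -inf;
  z[1] = inf;
  for (int qi = 1; qi < m; ++qi) {
    int q = fin[qi];
    double pq = q * w;
    double s;
    while (true) {
      double pv = v[kk] * w;
      s = ((f[q] + pq * pq) - (f[v[kk]] + pv * pv)) / (2 * pq - 2 * pv);
      if (s <= z[kk] && kk > 0) { --kk; } else break;
    }
    if (s <= z[kk]) {  // kk == 0 and new parabola dominates everywhere left
      v[kk] = q;
    } else {
      ++kk;
      v[kk] = q;
      z[kk] = s;
    }
    z[kk + 1] = inf;
  }
  kk = 0;
  for (int q = 0; q < nsamp; ++q) {
    double pq = q * w;
    while (z[kk + 1] < pq) ++kk;
    double pv = v[kk] * w, d = pq - pv;
    dout[q] = d * d + f[v[kk]];
  }
}

// Squared EDT of a binary mask (distance in mm to the nearest nonzero voxel),
// anisotropic spacing.
// [[Rcpp::export(name = ".C_edt")]]
NumericVector C_edt(IntegerVector mask, IntegerVector dim,
                    NumericVector spacing) {
  const int d[3] = {dim[0], dim[1], dim[2]};
  const R_xlen_t n = (R_xlen_t)d[0] * d[1] * d[2];
  const double inf = std::numeric_limits<double>::infinity();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : inf;
  const R_xlen_t st[3] = {1, (R_xlen_t)d[0], (R_xlen_t)d[0] * d[1]};
  std::vector<double> line, dl;
  for (int ax = 0; ax < 3; ++ax) {
    int len = d[ax];
    line.resize(len);
    dl.resize(len);
    int o1 = (ax + 1) % 3, o2 = (ax + 2) % 3;
    for (int b = 0; b < d[o2]; ++b)
      for (int a = 0; a < d[o1]; ++a) {
        R_xlen_t base = a * st[o1] + b * st[o2];
        bool allinf = true;
        for (int p = 0; p < len; ++p) {
          line[p] = out[base + p * st[ax]];
          if (line[p] != inf) allinf = false;
        }
        if (allinf) continue;
        edt1d(line, dl, len, spacing[ax]);
        for (int p = 0; p < len; ++p) out[base + p * st[ax]] = dl[p];
      }
  }
  return out;
}

// 6-connected component labelling; returns integer labels 1..ncomp by
// decreasing size (label 1 = largest component).
// [[Rcpp::export(name = ".C_label6")]]
IntegerVector C_label6(IntegerVector mask, IntegerVector dim) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  IntegerVector lab(n);
  std::vector<R_xlen_t> sizes;
  std::vector<R_xlen_t> stack;
  int cur = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++cur;
    R_xlen_t sz = 0;
    stack.push_back(s);
    lab[s] = cur;
    while (!stack.empty()) {
      R_xlen_t p = stack.back();
      stack.pop_back();
      ++sz;
      int i = (int)(p % d1), j = (int)((p / d1) % d2), k = (int)(p / ((R_xlen_t)d1 * d2));
      const int di[6] = {-1, 1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, -1, 1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, -1, 1};
      for (int t = 0; t < 6; ++t) {
        int ii = i + di[t], jj = j + dj[t], kk2 = k + dk[t];
        if (ii < 0 || jj < 0 || kk2 < 0 || ii >= d1 || jj >= d2 || kk2 >= d3)
          continue;
        R_xlen_t q = ii + (R_xlen_t)d1 * (jj + (R_xlen_t)d2 * kk2);
        if (mask[q] && !lab[q]) { lab[q] = cur; stack.push_back(q); }
      }
    }
    sizes.push_back(sz);
  }
  // relabel by decreasing size
  std::vector<int> order(cur);
  for (int c = 0; c < cur; ++c) order[c] = c;
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return sizes[a] > sizes[b]; });
  std::vector<int> remap(cur + 1, 0);
  for (int r = 0; r < cur; ++r) remap[order[r] + 1] = r + 1;
  for (R_xlen_t s = 0; s < n; ++s)
    if (lab[s]) lab[s] = remap[lab[s]];
  return lab;
}

// Binary dilation (op = 1) or erosion (op = 0) with a 3x3x3 box element.
// [[Rcpp::export(name = ".C_morph_box")]]
IntegerVector C_morph_box(IntegerVector mask, IntegerVector dim, int op) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  IntegerVector out(n);
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        R_xlen_t idx = i + (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k);
        int val = op ? 0 : 1;
        for (int dz = -1; dz <= 1 && (op ? !val : val); ++dz)
          for (int dy = -1; dy <= 1 && (op ? !val : val); ++dy)
            for (int dx = -1; dx <= 1 && (op ? !val : val); ++dx) {
              int ii = i + dx, jj = j + dy, kk = k + dz;
              int m;
              if (ii < 0 || jj < 0 || kk < 0 || ii >= d1 || jj >= d2 || kk >= d3)
                m = 0;  // outside counts as background
              else
                m = mask[ii + (R_xlen_t)d1 * (jj + (R_xlen_t)d2 * kk)] ? 1 : 0;
              if (op) { if (m) val = 1; }
              else { if (!m) val = 0; }
            }
        out[idx] = val;
      }
  return out;
}

// Brute-force nearest neighbours: for each row of A (n x 3) the index
// (1-based) of the closest row of B (m x 3).
// [[Rcpp::export(name = ".C_nn_index")]]
IntegerVector C_nn_index(NumericMatrix A, NumericMatrix B) {
  int na = A.nrow(), nb = B.nrow();
  IntegerVector out(na);
  for (int i = 0; i < na; ++i) {
    double best = R_PosInf;
    int bi = 0;
    double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    for (int j = 0; j < nb; ++j) {
      double dx = ax - B(j, 0), dy = ay - B(j, 1), dz = az - B(j, 2);
      double d = dx * dx + dy * dy + dz * dz;
      if (d < best) { best = d; bi = j; }
    }
    out[i] = bi + 1;
  }
  return out;
}
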