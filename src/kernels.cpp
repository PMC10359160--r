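#if defined(__GNUC__) && !defined(__clang__)
// the convolution kernels dominate training time; ask for aggressive
// optimization regardless of the site-wide -O level
#pragma GCC optimize("O3", "unroll-loops")
#endif

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// voxel index helpers: arrays are stored column-major, x fastest, as (X, Y, Z[, C])
static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// ---------------------------------------------------------------------------
// Trilinear / nearest sampling with replicate boundary.
// Query coordinates are 0-based voxel coordinates.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_sample3d(NumericVector src, IntegerVector dims,
                           NumericVector qx, NumericVector qy, NumericVector qz,
                           bool linear) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const R_xlen_t n = qx.size();
  NumericVector out(n);
  const double *s = src.begin();
  const double *px = qx.begin(), *py = qy.begin(), *pz = qz.begin();
  double *o = out.begin();
  const R_xlen_t XY = (R_xlen_t)X * Y;
  if (!linear) {
    for (R_xlen_t i = 0; i < n; ++i) {
      int x = clampi((int)std::lround(px[i]), 0, X - 1);
      int y = clampi((int)std::lround(py[i]), 0, Y - 1);
      int z = clampi((int)std::lround(pz[i]), 0, Z - 1);
      o[i] = s[x + (R_xlen_t)X * y + XY * z];
    }
    return out;
  }
  for (R_xlen_t i = 0; i < n; ++i) {
    double cx = px[i], cy = py[i], cz = pz[i];
    if (cx < 0) cx = 0; if (cx > X - 1) cx = X - 1;
    if (cy < 0) cy = 0; if (cy > Y - 1) cy = Y - 1;
    if (cz < 0) cz = 0; if (cz > Z - 1) cz = Z - 1;
    int x0 = (int)std::floor(cx); if (x0 > X - 2) x0 = X - 2; if (X == 1) x0 = 0;
    int y0 = (int)std::floor(cy); if (y0 > Y - 2) y0 = Y - 2; if (Y == 1) y0 = 0;
    int z0 = (int)std::floor(cz); if (z0 > Z - 2) z0 = Z - 2; if (Z == 1) z0 = 0;
    double fx = cx - x0, fy = cy - y0, fz = cz - z0;
    const double *base = s + x0 + (R_xlen_t)X * y0 + XY * z0;
    double c000 = base[0],      c100 = base[1];
    double c010 = base[X],      c110 = base[X + 1];
    double c001 = base[XY],     c101 = base[XY + 1];
    double c011 = base[XY + X], c111 = base[XY + X + 1];
    double c00 = c000 + fx * (c100 - c000);
    double c10 = c010 + fx * (c110 - c010);
    double c01 = c001 + fx * (c101 - c001);
    double c11 = c011 + fx * (c111 - c011);
    double c0 = c00 + fy * (c10 - c00);
    double c1 = c01 + fy * (c11 - c01);
    o[i] = c0 + fz * (c1 - c0);
  }
  return out;
}

// Trilinear sample + analytic gradient w.r.t. the query coordinate (per voxel unit).
// Outside the domain the sample is clamped and the gradient along the clamped axis is 0.
// [[Rcpp::export]]
List cpp_sample3d_grad(NumericVector src, IntegerVector dims,
                       NumericVector qx, NumericVector qy, NumericVector qz) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const R_xlen_t n = qx.size();
  NumericVector val(n), gx(n), gy(n), gz(n);
  const double *s = src.begin();
  const R_xlen_t XY = (R_xlen_t)X * Y;
  for (R_xlen_t i = 0; i < n; ++i) {
    double cx = qx[i], cy = qy[i], cz = qz[i];
    bool inx = (cx > 0 && cx < X - 1), iny = (cy > 0 && cy < Y - 1), inz = (cz > 0 && cz < Z - 1);
    if (cx < 0) cx = 0; if (cx > X - 1) cx = X - 1;
    if (cy < 0) cy = 0; if (cy > Y - 1) cy = Y - 1;
    if (cz < 0) cz = 0; if (cz > Z - 1) cz = Z - 1;
    int x0 = (int)std::floor(cx); if (x0 > X - 2) x0 = X - 2;
    int y0 = (int)std::floor(cy); if (y0 > Y - 2) y0 = Y - 2;
    int z0 = (int)std::floor(cz); if (z0 > Z - 2) z0 = Z - 2;
    double fx = cx - x0, fy = cy - y0, fz = cz - z0;
    const double *base = s + x0 + (R_xlen_t)X * y0 + XY * z0;
    double c000 = base[0],      c100 = base[1];
    double c010 = base[X],      c110 = base[X + 1];
    double c001 = base[XY],     c101 = base[XY + 1];
    double c011 = base[XY + X], c111 = base[XY + X + 1];
    double gx00 = c100 - c000, gx10 = c110 - c010, gx01 = c101 - c001, gx11 = c111 - c011;
    double c00 = c000 + fx * gx00, c10 = c010 + fx * gx10;
    double c01 = c001 + fx * gx01, c11 = c011 + fx * gx11;
    double c0 = c00 + fy * (c10 - c00);
    double c1 = c01 + fy * (c11 - c01);
    val[i] = c0 + fz * (c1 - c0);
    double dgx0 = gx00 + fy * (gx10 - gx00);
    double dgx1 = gx01 + fy * (gx11 - gx01);
    gx[i] = inx ? (dgx0 + fz * (dgx1 - dgx0)) : 0.0;
    double dy0 = c10 - c00, dy1 = c11 - c01;
    gy[i] = iny ? (dy0 + fz * (dy1 - dy0)) : 0.0;
    gz[i] = inz ? (c1 - c0) : 0.0;
  }
  return List::create(_["value"] = val, _["gx"] = gx, _["gy"] = gy, _["gz"] = gz);
}

// Min/max of the 8 interpolation corners used at each query point (the local
// convex hull of trilinear interpolation).
// [[Rcpp::export]]
List cpp_sample3d_hull(NumericVector src, IntegerVector dims,
                       NumericVector qx, NumericVector qy, NumericVector qz) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const R_xlen_t n = qx.size();
  NumericVector lo(n), hi(n);
  const double *s = src.begin();
  const R_xlen_t XY = (R_xlen_t)X * Y;
  for (R_xlen_t i = 0; i < n; ++i) {
    double cx = qx[i], cy = qy[i], cz = qz[i];
    if (cx < 0) cx = 0; if (cx > X - 1) cx = X - 1;
    if (cy < 0) cy = 0; if (cy > Y - 1) cy = Y - 1;
    if (cz < 0) cz = 0; if (cz > Z - 1) cz = Z - 1;
    int x0 = (int)std::floor(cx); if (x0 > X - 2) x0 = X - 2;
    int y0 = (int)std::floor(cy); if (y0 > Y - 2) y0 = Y - 2;
    int z0 = (int)std::floor(cz); if (z0 > Z - 2) z0 = Z - 2;
    const double *base = s + x0 + (R_xlen_t)X * y0 + XY * z0;
    double mn = base[0], mx = base[0];
    const R_xlen_t off[8] = {0, 1, X, X + 1, XY, XY + 1, XY + X, XY + X + 1};
    for (int k = 1; k < 8; ++k) {
      double v = base[off[k]];
      if (v < mn) mn = v;
      if (v > mx) mx = v;
    }
    lo[i] = mn; hi[i] = mx;
  }
  return List::create(_["lo"] = lo, _["hi"] = hi);
}

// Scaling-and-squaring exponential of a stationary velocity field.
// v: (X, Y, Z, 3) in mm; spacing in mm; returns the displacement field.
// [[Rcpp::export]]
NumericVector cpp_integrate_velocity(NumericVector v, IntegerVector dims,
                                     NumericVector spacing, int n_steps) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const R_xlen_t V = (R_xlen_t)X * Y * Z;
  NumericVector u(clone(v));
  const double scale = std::pow(2.0, -n_steps);
  for (R_xlen_t i = 0; i < 3 * V; ++i) u[i] *= scale;
  std::vector<double> nu(3 * V);
  const R_xlen_t XY = (R_xlen_t)X * Y;
  const double isp[3] = {1.0 / spacing[0], 1.0 / spacing[1], 1.0 / spacing[2]};
  for (int s = 0; s < n_steps; ++s) {
    const double *pu = u.begin();
    R_xlen_t i = 0;
    for (int z = 0; z < Z; ++z)
      for (int y = 0; y < Y; ++y)
        for (int x = 0; x < X; ++x, ++i) {
          double cx = x + pu[i] * isp[0];
          double cy = y + pu[i + V] * isp[1];
          double cz = z + pu[i + 2 * V] * isp[2];
          if (cx < 0) cx = 0; if (cx > X - 1) cx = X - 1;
          if (cy < 0) cy = 0; if (cy > Y - 1) cy = Y - 1;
          if (cz < 0) cz = 0; if (cz > Z - 1) cz = Z - 1;
          int x0 = (int)cx; if (x0 > X - 2) x0 = X - 2;
          int y0 = (int)cy; if (y0 > Y - 2) y0 = Y - 2;
          int z0 = (int)cz; if (z0 > Z - 2) z0 = Z - 2;
          const double fx = cx - x0, fy = cy - y0, fz = cz - z0;
          const R_xlen_t b = x0 + (R_xlen_t)X * y0 + XY * z0;
          for (int c = 0; c < 3; ++c) {
            const double *sc = pu + c * V + b;
            double c00 = sc[0] + fx * (sc[1] - sc[0]);
            double c10 = sc[X] + fx * (sc[X + 1] - sc[X]);
            double c01 = sc[XY] + fx * (sc[XY + 1] - sc[XY]);
            double c11 = sc[XY + X] + fx * (sc[XY + X + 1] - sc[XY + X]);
            double c0 = c00 + fy * (c10 - c00);
            double c1 = c01 + fy * (c11 - c01);
            nu[c * V + i] = pu[c * V + i] + c0 + fz * (c1 - c0);
          }
        }
    std::copy(nu.begin(), nu.end(), u.begin());
  }
  u.attr("dim") = IntegerVector::create(X, Y, Z, 3);
  return u;
}

// ---------------------------------------------------------------------------
// 3x3x3 convolution, zero padding 1, stride 1.
// x: (X, Y, Z, Cin); w: (3, 3, 3, Cin, Cout); b: (Cout); y: (X, Y, Z, Cout)
// Shift-and-accumulate formulation: each kernel tap is a contiguous axpy row.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_conv3_forward(NumericVector x, IntegerVector dims, int cin,
                                NumericVector w, NumericVector b, int cout) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const R_xlen_t XY = (R_xlen_t)X * Y, V = XY * Z;
  NumericVector y((R_xlen_t)V * cout);
  const double *px = x.begin(), *pw = w.begin(), *pb = b.begin();
  double *py = y.begin();
  for (int co = 0; co < cout; ++co) {
    double *yc = py + V * co;
    const double bco = pb[co];
    for (R_xlen_t i = 0; i < V; ++i) yc[i] = bco;
    for (int ci = 0; ci < cin; ++ci) {
      const double *xc = px + V * ci;
      for (int kz = -1; kz <= 1; ++kz)
      for (int ky = -1; ky <= 1; ++ky)
      for (int kx = -1; kx <= 1; ++kx) {
        const double wv = pw[(kx + 1) + 3 * ((ky + 1) + 3 * ((kz + 1) + 3 * (ci + (R_xlen_t)cin * co)))];
        if (wv == 0.0) continue;
        const int z0 = std::max(0, -kz), z1 = std::min(Z, Z - kz);
        const int y0 = std::max(0, -ky), y1 = std::min(Y, Y - ky);
        const int x0 = std::max(0, -kx), x1 = std::min(X, X - kx);
        for (int z = z0; z < z1; ++z) {
          for (int yy = y0; yy < y1; ++yy) {
            double *__restrict__ dst = yc + (R_xlen_t)X * yy + XY * z;
            const double *__restrict__ srcr = xc + (R_xlen_t)X * (yy + ky) + XY * (z + kz) + kx;
            for (int xx = x0; xx < x1; ++xx) dst[xx] += wv * srcr[xx];
          }
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(X, Y, Z, cout);
  return y;
}

// [[Rcpp::export]]
List cpp_conv3_backward(NumericVector x, IntegerVector dims, int cin,
                        NumericVector w, int cout, NumericVector gy,
                        bool need_gx = true) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const R_xlen_t XY = (R_xlen_t)X * Y, V = XY * Z;
  NumericVector gx(need_gx ? (R_xlen_t)V * cin : 0), gw(w.size()), gb(cout);
  const double *px = x.begin(), *pw = w.begin(), *pgy = gy.begin();
  double *pgx = gx.begin(), *pgw = gw.begin(), *pgb = gb.begin();
  for (int co = 0; co < cout; ++co) {
    const double *gyc = pgy + V * co;
    double acc = 0.0;
    for (R_xlen_t i = 0; i < V; ++i) acc += gyc[i];
    pgb[co] = acc;
    for (int ci = 0; ci < cin; ++ci) {
      const double *xc = px + V * ci;
      double *gxc = need_gx ? pgx + V * ci : nullptr;
      for (int kz = -1; kz <= 1; ++kz)
      for (int ky = -1; ky <= 1; ++ky)
      for (int kx = -1; kx <= 1; ++kx) {
        const R_xlen_t widx = (kx + 1) + 3 * ((ky + 1) + 3 * ((kz + 1) + 3 * (ci + (R_xlen_t)cin * co)));
        const double wv = pw[widx];
        const int z0 = std::max(0, -kz), z1 = std::min(Z, Z - kz);
        const int y0 = std::max(0, -ky), y1 = std::min(Y, Y - ky);
        const int x0 = std::max(0, -kx), x1 = std::min(X, X - kx);
        double wacc = 0.0;
        for (int z = z0; z < z1; ++z) {
          for (int yy = y0; yy < y1; ++yy) {
            const double *__restrict__ g = gyc + (R_xlen_t)X * yy + XY * z;
            const double *__restrict__ srcr = xc + (R_xlen_t)X * (yy + ky) + XY * (z + kz) + kx;
            if (need_gx) {
              double *__restrict__ gsr = gxc + (R_xlen_t)X * (yy + ky) + XY * (z + kz) + kx;
              for (int xx = x0; xx < x1; ++xx) {
                wacc += g[xx] * srcr[xx];
                gsr[xx] += wv * g[xx];
              }
            } else {
              for (int xx = x0; xx < x1; ++xx) wacc += g[xx] * srcr[xx];
            }
          }
        }
        pgw[widx] = wacc;
      }
    }
  }
  if (need_gx) gx.attr("dim") = IntegerVector::create(X, Y, Z, cin);
  gw.attr("dim") = w.attr("dim");
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Per-channel normalization over spatial dims (batch of one): forward.
// [[Rcpp::export]]
List cpp_norm_fwd(NumericVector x, int nspatial, int C,
                  NumericVector gamma, NumericVector beta, double eps) {
  const R_xlen_t n = nspatial;
  NumericVector y(x.size()), xhat(x.size()), istd(C);
  const double *px = x.begin();
  double *py = y.begin(), *ph = xhat.begin();
  for (int c = 0; c < C; ++c) {
    const double *xc = px + n * c;
    double mu = 0, v = 0;
    for (R_xlen_t i = 0; i < n; ++i) mu += xc[i];
    mu /= n;
    for (R_xlen_t i = 0; i < n; ++i) { double d = xc[i] - mu; v += d * d; }
    v /= n;
    const double is = 1.0 / std::sqrt(v + eps);
    istd[c] = is;
    const double g = gamma[c], b = beta[c];
    double *yc = py + n * c, *hc = ph + n * c;
    for (R_xlen_t i = 0; i < n; ++i) {
      const double h = (xc[i] - mu) * is;
      hc[i] = h;
      yc[i] = g * h + b;
    }
  }
  y.attr("dim") = x.attr("dim");
  return List::create(_["y"] = y, _["xhat"] = xhat, _["istd"] = istd);
}

// [[Rcpp::export]]
List cpp_norm_bwd(NumericVector gy, NumericVector xhat, NumericVector istd,
                  NumericVector gamma, int nspatial, int C) {
  const R_xlen_t n = nspatial;
  NumericVector gx(gy.size()), ggamma(C), gbeta(C);
  const double *pg = gy.begin(), *ph = xhat.begin();
  double *px = gx.begin();
  for (int c = 0; c < C; ++c) {
    const double *gc = pg + n * c, *hc = ph + n * c;
    double *xc = px + n * c;
    double m1 = 0, m2 = 0, sg = 0, sh = 0;
    for (R_xlen_t i = 0; i < n; ++i) {
      sg += gc[i];
      sh += gc[i] * hc[i];
    }
    ggamma[c] = sh;
    gbeta[c] = sg;
    const double gam = gamma[c];
    m1 = gam * sg / n;
    m2 = gam * sh / n;
    const double is = istd[c];
    for (R_xlen_t i = 0; i < n; ++i)
      xc[i] = is * (gam * gc[i] - m1 - hc[i] * m2);
  }
  gx.attr("dim") = gy.attr("dim");
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}

// Curvature smoothness of a 3-component field: mean over interior voxels of
// the summed squared 6-neighbor Laplacian, plus its gradient w.r.t. the field
// (adjoint stencil applied to the interior residual, zero padding outside).
// [[Rcpp::export]]
List cpp_curvature_grad(NumericVector v, IntegerVector dims,
                        NumericVector spacing) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const R_xlen_t XY = (R_xlen_t)X * Y, V = XY * Z;
  const double wx = 1.0 / (spacing[0] * spacing[0]);
  const double wy = 1.0 / (spacing[1] * spacing[1]);
  const double wz = 1.0 / (spacing[2] * spacing[2]);
  const double w0 = -2.0 * (wx + wy + wz);
  const double n_int = (double)(X - 2) * (Y - 2) * (Z - 2);
  NumericVector grad(3 * V);
  std::vector<double> lap(V);
  double value = 0.0;
  for (int c = 0; c < 3; ++c) {
    const double *pv = v.begin() + c * V;
    std::fill(lap.begin(), lap.end(), 0.0);
    for (int z = 1; z < Z - 1; ++z)
      for (int y = 1; y < Y - 1; ++y) {
        const R_xlen_t row = (R_xlen_t)X * y + XY * z;
        for (int x = 1; x < X - 1; ++x) {
          const R_xlen_t i = row + x;
          const double l = w0 * pv[i] + wx * (pv[i - 1] + pv[i + 1]) +
                           wy * (pv[i - X] + pv[i + X]) +
                           wz * (pv[i - XY] + pv[i + XY]);
          lap[i] = l;
          value += l * l;
        }
      }
    double *pg = grad.begin() + c * V;
    const double s = 2.0 / n_int;
    for (int z = 1; z < Z - 1; ++z)
      for (int y = 1; y < Y - 1; ++y) {
        const R_xlen_t row = (R_xlen_t)X * y + XY * z;
        for (int x = 1; x < X - 1; ++x) {
          const R_xlen_t i = row + x;
          const double l = s * lap[i];
          pg[i] += w0 * l;
          pg[i - 1] += wx * l; pg[i + 1] += wx * l;
          pg[i - X] += wy * l; pg[i + X] += wy * l;
          pg[i - XY] += wz * l; pg[i + XY] += wz * l;
        }
      }
  }
  grad.attr("dim") = IntegerVector::create(X, Y, Z, 3);
  return List::create(_["value"] = value / n_int, _["grad"] = grad);
}

// ---------------------------------------------------------------------------
// Largest 6-connected component of a binary volume.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
LogicalVector cpp_largest_component(LogicalVector mask, IntegerVector dims) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const R_xlen_t XY = (R_xlen_t)X * Y, V = XY * Z;
  std::vector<int> label(V, 0);
  const int *m = LOGICAL(mask);
  int next = 0;
  R_xlen_t bestCount = 0;
  int bestLab = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t seed = 0; seed < V; ++seed) {
    if (!m[seed] || label[seed]) continue;
    ++next;
    R_xlen_t count = 0;
    stack.clear();
    stack.push_back(seed);
    label[seed] = next;
    while (!stack.empty()) {
      R_xlen_t p = stack.back();
      stack.pop_back();
      ++count;
      int x = (int)(p % X), y = (int)((p / X) % Y), z = (int)(p / XY);
      const int nx[6] = {x - 1, x + 1, x, x, x, x};
      const int ny[6] = {y, y, y - 1, y + 1, y, y};
      const int nz[6] = {z, z, z, z, z - 1, z + 1};
      for (int k = 0; k < 6; ++k) {
        if (nx[k] < 0 || nx[k] >= X || ny[k] < 0 || ny[k] >= Y || nz[k] < 0 || nz[k] >= Z) continue;
        R_xlen_t q = nx[k] + (R_xlen_t)X * ny[k] + XY * nz[k];
        if (m[q] && !label[q]) {
          label[q] = next;
          stack.push_back(q);
        }
      }
    }
    if (count > bestCount) { bestCount = count; bestLab = next; }
  }
  LogicalVector out(V);
  int *po = LOGICAL(out);
  for (R_xlen_t i = 0; i < V; ++i) po[i] = (label[i] == bestLab);
  out.attr("dim") = dims;
  return out;
}

// Binary dilation (or erosion via complement in R) with explicit voxel offsets.
// [[Rcpp::export]]
LogicalVector cpp_dilate(LogicalVector mask, IntegerVector dims, IntegerMatrix offsets) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const R_xlen_t XY = (R_xlen_t)X * Y, V = XY * Z;
  const int *m = LOGICAL(mask);
  LogicalVector out(V);
  int *po = LOGICAL(out);
  const int no = offsets.nrow();
  for (R_xlen_t p = 0; p < V; ++p) {
    if (!m[p]) continue;
    int x = (int)(p % X), y = (int)((p / X) % Y), z = (int)(p / XY);
    for (int k = 0; k < no; ++k) {
      int xx = x + offsets(k, 0), yy = y + offsets(k, 1), zz = z + offsets(k, 2);
      if (xx < 0 || xx >= X || yy < 0 || yy >= Y || zz < 0 || zz >= Z) continue;
      po[xx + (R_xlen_t)X * yy + XY * zz] = 1;
    }
  }
  out.attr("dim") = dims;
  return out;
}

// Fill holes per axial (z) slice: background 4-connected flood from the slice
// border; unreached background becomes foreground.
// [[Rcpp::export]]
LogicalVector cpp_fill_slices(LogicalVector mask, IntegerVector dims) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const R_xlen_t XY = (R_xlen_t)X * Y;
  const int *m = LOGICAL(mask);
  LogicalVector out(clone(mask));
  int *po = LOGICAL(out);
  std::vector<char> reach(XY);
  std::vector<int> stack;
  for (int z = 0; z < Z; ++z) {
    const int *ms = m + XY * z;
    std::fill(reach.begin(), reach.end(), 0);
    stack.clear();
    for (int x = 0; x < X; ++x) {
      for (int y : {0, Y - 1}) {
        int p = x + X * y;
        if (!ms[p] && !reach[p]) { reach[p] = 1; stack.push_back(p); }
      }
    }
    for (int y = 0; y < Y; ++y) {
      for (int x : {0, X - 1}) {
        int p = x + X * y;
        if (!ms[p] && !reach[p]) { reach[p] = 1; stack.push_back(p); }
      }
    }
    while (!stack.empty()) {
      int p = stack.back();
      stack.pop_back();
      int x = p % X, y = p / X;
      const int nx[4] = {x - 1, x + 1, x, x};
      const int ny[4] = {y, y, y - 1, y + 1};
      for (int k = 0; k < 4; ++k) {
        if (nx[k] < 0 || nx[k] >= X || ny[k] < 0 || ny[k] >= Y) continue;
        int q = nx[k] + X * ny[k];
        if (!ms[q] && !reach[q]) { reach[q] = 1; stack.push_back(q); }
      }
    }
    int *os = po + XY * z;
    for (int p = 0; p < (int)XY; ++p)
      if (!ms[p] && !reach[p]) os[p] = 1;
  }
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Exact symmetric Hausdorff distance between two point sets (mm coordinates),
// directed max-min with the classic early-break pruning.
// ---------------------------------------------------------------------------

static double directed_hd2(const double *ax, const double *ay, const double *az, R_xlen_t na,
                           const double *bx, const double *by, const double *bz, R_xlen_t nb) {
  double worst2 = 0.0;
  for (R_xlen_t i = 0; i < na; ++i) {
    double best2 = R_PosInf;
    const double x = ax[i], y = ay[i], z = az[i];
    for (R_xlen_t j = 0; j < nb; ++j) {
      double dx = x - bx[j], dy = y - by[j], dz = z - bz[j];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best2) {
        best2 = d2;
        if (best2 <= worst2) break;  // this point cannot raise the maximum
      }
    }
    if (best2 > worst2) worst2 = best2;
  }
  return worst2;
}

// [[Rcpp::export]]
double cpp_hausdorff(NumericVector ax, NumericVector ay, NumericVector az,
                     NumericVector bx, NumericVector by, NumericVector bz) {
  double d2 = std::max(
    directed_hd2(ax.begin(), ay.begin(), az.begin(), ax.size(),
                 bx.begin(), by.begin(), bz.begin(), bx.size()),
    directed_hd2(bx.begin(), by.begin(), bz.begin(), bx.size(),
                 ax.begin(), ay.begin(), az.begin(), ax.size()));
  return std::sqrt(d2);
}
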