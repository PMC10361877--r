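#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
#include <limits>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// separable 1-D parabola envelope applied per axis with physical spacing so
// anisotropic grids give true mm distances.
// ---------------------------------------------------------------------------

static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n, double h) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double qq = q * h;
    double s;
    while (true) {
      double vv = v[k] * h;
      s = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) / (2.0 * qq - 2.0 * vv);
      if (s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qq = q * h;
    while (z[k + 1] < qq) ++k;
    double vv = v[k] * h;
    d[q] = (qq - vv) * (qq - vv) + f[v[k]];
  }
}

// Squared distance (mm^2) from every voxel to the nearest TRUE voxel.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dim,
                         NumericVector spacing) {
  // large finite sentinel: infinities make the parabola intersection NaN
  const double INF = 1e20;
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x (stride 1)
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; ++i) f[i] = out[base + i];
      dt1d(f, d, v, z, nx, spacing[0]);
      for (int i = 0; i < nx; ++i) out[base + i] = d[i];
    }
  // pass along y (stride nx)
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * ny * k;
      for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)nx * j];
      dt1d(f, d, v, z, ny, spacing[1]);
      for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)nx * j] = d[j];
    }
  // pass along z (stride nx*ny)
  R_xlen_t sz = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * j;
      for (int k = 0; k < nz; ++k) f[k] = out[base + sz * k];
      dt1d(f, d, v, z, nz, spacing[2]);
      for (int k = 0; k < nz; ++k) out[base + sz * k] = d[k];
    }
  return out;
}

// ---------------------------------------------------------------------------
// Grid sampling. Voxel (0,0,0) center sits at `origin` (mm); continuous index
// c = (p - origin) / spacing. Points outside the voxel-center hull get `fill`.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_sample_trilinear(NumericVector vol, IntegerVector dim,
                                   NumericVector spacing, NumericVector origin,
                                   NumericMatrix pts, double fill) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = pts.nrow();
  NumericVector out(n);
  R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  for (R_xlen_t r = 0; r < n; ++r) {
    double cx = (pts(r, 0) - origin[0]) / spacing[0];
    double cy = (pts(r, 1) - origin[1]) / spacing[1];
    double cz = (pts(r, 2) - origin[2]) / spacing[2];
    // tolerate round-off at the voxel-center hull boundary
    const double tol = 1e-6;
    if (cx < -tol || cy < -tol || cz < -tol ||
        cx > nx - 1 + tol || cy > ny - 1 + tol || cz > nz - 1 + tol) {
      out[r] = fill;
      continue;
    }
    if (cx < 0) cx = 0;
    if (cy < 0) cy = 0;
    if (cz < 0) cz = 0;
    if (cx > nx - 1) cx = nx - 1;
    if (cy > ny - 1) cy = ny - 1;
    if (cz > nz - 1) cz = nz - 1;
    int ix = (int)std::floor(cx), iy = (int)std::floor(cy), iz = (int)std::floor(cz);
    if (ix == nx - 1) --ix;
    if (iy == ny - 1) --iy;
    if (iz == nz - 1) --iz;
    if (nx == 1) ix = 0;
    if (ny == 1) iy = 0;
    if (nz == 1) iz = 0;
    double fx = cx - ix, fy = cy - iy, fz = cz - iz;
    R_xlen_t b = ix + sy * iy + sz * iz;
    int dx = (nx > 1) ? 1 : 0;
    R_xlen_t dy = (ny > 1) ? sy : 0, dz = (nz > 1) ? sz : 0;
    double v000 = vol[b], v100 = vol[b + dx];
    double v010 = vol[b + dy], v110 = vol[b + dx + dy];
    double v001 = vol[b + dz], v101 = vol[b + dx + dz];
    double v011 = vol[b + dy + dz], v111 = vol[b + dx + dy + dz];
    double c00 = v000 * (1 - fx) + v100 * fx;
    double c10 = v010 * (1 - fx) + v110 * fx;
    double c01 = v001 * (1 - fx) + v101 * fx;
    double c11 = v011 * (1 - fx) + v111 * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[r] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_sample_nearest(NumericVector vol, IntegerVector dim,
                                 NumericVector spacing, NumericVector origin,
                                 NumericMatrix pts, double fill) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = pts.nrow();
  NumericVector out(n);
  R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  for (R_xlen_t r = 0; r < n; ++r) {
    double cx = (pts(r, 0) - origin[0]) / spacing[0];
    double cy = (pts(r, 1) - origin[1]) / spacing[1];
    double cz = (pts(r, 2) - origin[2]) / spacing[2];
    long ix = (long)std::lround(cx), iy = (long)std::lround(cy), iz = (long)std::lround(cz);
    if (ix < 0 || iy < 0 || iz < 0 || ix >= nx || iy >= ny || iz >= nz) {
      out[r] = fill;
      continue;
    }
    out[r] = vol[ix + sy * iy + sz * iz];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Siddon/Amanatides-Woo exact voxel traversal: line integral of a
// piecewise-constant voxel field along the segment p0 -> p1 (mm * value).
// Voxel boundaries lie half a spacing beyond the voxel centers; space outside
// the grid contributes zero.
// ---------------------------------------------------------------------------

static double ray_integral_one(const double* vol, const int* dim,
                               const double* spacing, const double* origin,
                               const double* p0, const double* p1) {
  double d[3], lo[3], hi[3];
  double L = 0.0;
  for (int a = 0; a < 3; ++a) {
    d[a] = p1[a] - p0[a];
    L += d[a] * d[a];
    lo[a] = origin[a] - 0.5 * spacing[a];
    hi[a] = origin[a] + (dim[a] - 0.5) * spacing[a];
  }
  L = std::sqrt(L);
  if (L <= 0) return 0.0;

  // clip [0,1] to the grid box
  double t0 = 0.0, t1 = 1.0;
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(d[a]) < 1e-12) {
      if (p0[a] < lo[a] || p0[a] > hi[a]) return 0.0;
    } else {
      double ta = (lo[a] - p0[a]) / d[a];
      double tb = (hi[a] - p0[a]) / d[a];
      if (ta > tb) std::swap(ta, tb);
      if (ta > t0) t0 = ta;
      if (tb < t1) t1 = tb;
    }
  }
  if (t1 <= t0) return 0.0;

  // starting voxel just inside
  double eps = 1e-10;
  double tc = t0 + eps;
  int idx[3], step[3];
  double tmax[3], tdelta[3];
  const double INF = std::numeric_limits<double>::infinity();
  for (int a = 0; a < 3; ++a) {
    double p = p0[a] + tc * d[a];
    int i = (int)std::floor((p - lo[a]) / spacing[a]);
    if (i < 0) i = 0;
    if (i >= dim[a]) i = dim[a] - 1;
    idx[a] = i;
    if (d[a] > 1e-12) {
      step[a] = 1;
      tmax[a] = ((lo[a] + (i + 1) * spacing[a]) - p0[a]) / d[a];
      tdelta[a] = spacing[a] / d[a];
    } else if (d[a] < -1e-12) {
      step[a] = -1;
      tmax[a] = ((lo[a] + i * spacing[a]) - p0[a]) / d[a];
      tdelta[a] = -spacing[a] / d[a];
    } else {
      step[a] = 0;
      tmax[a] = INF;
      tdelta[a] = INF;
    }
  }

  R_xlen_t sy = dim[0], sz = (R_xlen_t)dim[0] * dim[1];
  double acc = 0.0;
  double tprev = t0;
  while (tprev < t1 - 1e-12) {
    int amin = 0;
    if (tmax[1] < tmax[amin]) amin = 1;
    if (tmax[2] < tmax[amin]) amin = 2;
    double tnext = std::min(tmax[amin], t1);
    double val = vol[idx[0] + sy * idx[1] + sz * idx[2]];
    acc += val * (tnext - tprev) * L;
    tprev = tnext;
    if (tmax[amin] >= t1) break;
    idx[amin] += step[amin];
    if (idx[amin] < 0 || idx[amin] >= dim[amin]) break;
    tmax[amin] += tdelta[amin];
  }
  return acc;
}

// [[Rcpp::export]]
NumericVector cpp_ray_integral(NumericVector vol, IntegerVector dim,
                               NumericVector spacing, NumericVector origin,
                               NumericMatrix P0, NumericMatrix P1) {
  R_xlen_t n = P0.nrow();
  NumericVector out(n);
  int dm[3] = {dim[0], dim[1], dim[2]};
  double sp[3] = {spacing[0], spacing[1], spacing[2]};
  double og[3] = {origin[0], origin[1], origin[2]};
  for (R_xlen_t r = 0; r < n; ++r) {
    double p0[3] = {P0(r, 0), P0(r, 1), P0(r, 2)};
    double p1[3] = {P1(r, 0), P1(r, 1), P1(r, 2)};
    out[r] = ray_integral_one(REAL(vol), dm, sp, og, p0, p1);
  }
  return out;
}

// ---------------------------------------------------------------------------
// 6-connected component labeling of a binary 3-D mask (BFS, labels 1..k,
// background 0).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n);
  R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t c = q.front();
      q.pop();
      int k = (int)(c / sz);
      R_xlen_t rem = c - (R_xlen_t)k * sz;
      int j = (int)(rem / sy);
      int i = (int)(rem - (R_xlen_t)j * sy);
      const int di[6] = {-1, 1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, -1, 1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, -1, 1};
      for (int t = 0; t < 6; ++t) {
        int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        R_xlen_t nb = ii + sy * jj + sz * kk;
        if (mask[nb] && lab[nb] == 0) {
          lab[nb] = next;
          q.push(nb);
        }
      }
    }
  }
  return lab;
}
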