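#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Grids are plain R 3-D arrays (column-major, dim = c(nx, ny, nz)).
// Voxel centre i (0-based) sits at world = origin + i * spacing; the grid
// occupies the half-open box [origin - spacing/2, origin + (dim - 1/2) * spacing).

static inline double trilinear_sample(const double* g, int nx, int ny, int nz,
                                      double ix, double iy, double iz, bool& ok) {
  // ix/iy/iz are continuous 0-based voxel indices
  if (ix < 0 || iy < 0 || iz < 0 || ix > nx - 1 || iy > ny - 1 || iz > nz - 1) {
    ok = false;
    return 0.0;
  }
  ok = true;
  int x0 = (int)std::floor(ix), y0 = (int)std::floor(iy), z0 = (int)std::floor(iz);
  if (x0 == nx - 1) x0--;
  if (y0 == ny - 1) y0--;
  if (z0 == nz - 1) z0--;
  if (x0 < 0) x0 = 0;
  if (y0 < 0) y0 = 0;
  if (z0 < 0) z0 = 0;
  double fx = ix - x0, fy = iy - y0, fz = iz - z0;
  const int sx = 1, sy = nx, sz = nx * ny;
  const double* p = g + x0 * sx + y0 * sy + z0 * sz;
  double c00 = p[0] * (1 - fx) + p[sx] * fx;
  double c10 = p[sy] * (1 - fx) + p[sy + sx] * fx;
  double c01 = p[sz] * (1 - fx) + p[sz + sx] * fx;
  double c11 = p[sy + sz] * (1 - fx) + p[sy + sz + sx] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// clip segment src -> dst (parametrised t in [0,1]) against the grid box;
// returns false when the segment misses the box entirely
static inline bool clip_to_box(const double src[3], const double dst[3],
                               const double lo[3], const double hi[3],
                               double& t0, double& t1) {
  t0 = 0.0;
  t1 = 1.0;
  for (int a = 0; a < 3; ++a) {
    double d = dst[a] - src[a];
    if (std::fabs(d) < 1e-12) {
      if (src[a] < lo[a] || src[a] > hi[a]) return false;
    } else {
      double ta = (lo[a] - src[a]) / d;
      double tb = (hi[a] - src[a]) / d;
      if (ta > tb) std::swap(ta, tb);
      t0 = std::max(t0, ta);
      t1 = std::min(t1, tb);
      if (t0 > t1) return false;
    }
  }
  return true;
}

// water-equivalent depth along src -> point, uniform sub-voxel stepping
static double ray_depth_one(const double* red, int nx, int ny, int nz,
                            const double spacing[3], const double origin[3],
                            const double src[3], const double pt[3], double step) {
  double lo[3], hi[3];
  int dims[3] = {nx, ny, nz};
  for (int a = 0; a < 3; ++a) {
    lo[a] = origin[a] - 0.5 * spacing[a];
    hi[a] = origin[a] + (dims[a] - 0.5) * spacing[a];
  }
  double t0, t1;
  if (!clip_to_box(src, pt, lo, hi, t0, t1)) return 0.0;
  double dvec[3] = {pt[0] - src[0], pt[1] - src[1], pt[2] - src[2]};
  double seglen = std::sqrt(dvec[0] * dvec[0] + dvec[1] * dvec[1] + dvec[2] * dvec[2]);
  double raylen = seglen * (t1 - t0);
  if (raylen <= 0) return 0.0;
  int nstep = (int)std::ceil(raylen / step);
  if (nstep < 1) nstep = 1;
  double dt = (t1 - t0) / nstep;
  double dlen = raylen / nstep;
  double depth = 0.0;
  for (int s = 0; s < nstep; ++s) {
    double tm = t0 + (s + 0.5) * dt; // midpoint rule
    double w[3];
    for (int a = 0; a < 3; ++a) w[a] = src[a] + tm * dvec[a];
    // clamp to centre lattice for sampling near the half-voxel rim
    double ix = (w[0] - origin[0]) / spacing[0];
    double iy = (w[1] - origin[1]) / spacing[1];
    double iz = (w[2] - origin[2]) / spacing[2];
    ix = std::min(std::max(ix, 0.0), (double)(nx - 1));
    iy = std::min(std::max(iy, 0.0), (double)(ny - 1));
    iz = std::min(std::max(iz, 0.0), (double)(nz - 1));
    bool ok;
    depth += trilinear_sample(red, nx, ny, nz, ix, iy, iz, ok) * dlen;
  }
  return depth;
}

// [[Rcpp::export]]
NumericVector cpp_ray_depth(NumericVector red, IntegerVector dim,
                            NumericVector spacing, NumericVector origin,
                            NumericVector source, NumericMatrix pts, double step) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double sp[3] = {spacing[0], spacing[1], spacing[2]};
  double orig[3] = {origin[0], origin[1], origin[2]};
  double src[3] = {source[0], source[1], source[2]};
  int n = pts.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double pt[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    out[i] = ray_depth_one(REAL(red), nx, ny, nz, sp, orig, src, pt, step);
  }
  return out;
}

// Superposes n_beams exponential-attenuation beams with rectangular jaw
// apertures (half-widths w1/w2 about the central axis, sigmoid penumbra of
// width sigma) onto every voxel.  dirs/e1s/e2s are per-beam orthonormal
// frames; sources are per-beam world points.
// [[Rcpp::export]]
NumericVector cpp_beam_dose(NumericVector red, IntegerVector dim,
                            NumericVector spacing, NumericVector origin,
                            NumericMatrix sources, NumericMatrix e1s,
                            NumericMatrix e2s, NumericVector w1, NumericVector w2,
                            NumericVector iso, double sigma, double mu, double step) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double sp[3] = {spacing[0], spacing[1], spacing[2]};
  double orig[3] = {origin[0], origin[1], origin[2]};
  int nb = sources.nrow();
  NumericVector out((R_xlen_t)nx * ny * nz);
  const double inv_sig = 1.0 / std::max(sigma, 1e-6);
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        double pt[3] = {orig[0] + i * sp[0], orig[1] + j * sp[1], orig[2] + k * sp[2]};
        double rel[3] = {pt[0] - iso[0], pt[1] - iso[1], pt[2] - iso[2]};
        double acc = 0.0;
        for (int b = 0; b < nb; ++b) {
          double l1 = rel[0] * e1s(b, 0) + rel[1] * e1s(b, 1) + rel[2] * e1s(b, 2);
          double l2 = rel[0] * e2s(b, 0) + rel[1] * e2s(b, 1) + rel[2] * e2s(b, 2);
          // logistic-edge jaw transmission in each lateral axis
          double a1 = 1.0 / (1.0 + std::exp(-(w1[b] - std::fabs(l1)) * inv_sig));
          double a2 = 1.0 / (1.0 + std::exp(-(w2[b] - std::fabs(l2)) * inv_sig));
          double w = a1 * a2;
          if (w < 1e-6) continue;
          double src[3] = {sources(b, 0), sources(b, 1), sources(b, 2)};
          double dep = ray_depth_one(REAL(red), nx, ny, nz, sp, orig, src, pt, step);
          acc += w * std::exp(-mu * dep);
        }
        out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = acc;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_trilinear(NumericVector grid, IntegerVector dim, NumericVector spacing,
                   NumericVector origin, NumericMatrix pts, double fill) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = pts.nrow();
  NumericVector out(n);
  int n_out = 0;
  for (int i = 0; i < n; ++i) {
    double ix = (pts(i, 0) - origin[0]) / spacing[0];
    double iy = (pts(i, 1) - origin[1]) / spacing[1];
    double iz = (pts(i, 2) - origin[2]) / spacing[2];
    bool ok;
    double v = trilinear_sample(REAL(grid), nx, ny, nz, ix, iy, iz, ok);
    if (!ok) {
      out[i] = fill;
      n_out++;
    } else {
      out[i] = v;
    }
  }
  return List::create(_["values"] = out, _["n_outside"] = n_out);
}

// Global gamma index.  offsets (mm) must be sorted by ascending Euclidean
// norm so the distance term alone permits early exit.
// [[Rcpp::export]]
NumericVector cpp_gamma(NumericVector ref, NumericVector eval, IntegerVector dim,
                        NumericVector spacing, NumericVector origin,
                        LogicalVector roi, double dose_tol_abs, double dta,
                        double cutoff_abs, NumericMatrix offsets) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  int K = offsets.nrow();
  std::vector<double> dist2(K);
  for (int k = 0; k < K; ++k) {
    double dx = offsets(k, 0), dy = offsets(k, 1), dz = offsets(k, 2);
    double d = std::sqrt(dx * dx + dy * dy + dz * dz) / dta;
    dist2[k] = d * d;
  }
  NumericVector out(n, NA_REAL);
  double inv_tol = 1.0 / dose_tol_abs;
  for (int kz = 0; kz < nz; ++kz) {
    for (int jy = 0; jy < ny; ++jy) {
      for (int ix = 0; ix < nx; ++ix) {
        R_xlen_t idx = ix + (R_xlen_t)nx * (jy + (R_xlen_t)ny * kz);
        if (!roi[idx]) continue;
        double rv = ref[idx];
        if (rv < cutoff_abs) continue;
        double wx = origin[0] + ix * spacing[0];
        double wy = origin[1] + jy * spacing[1];
        double wz = origin[2] + kz * spacing[2];
        double gmin = R_PosInf;
        for (int k = 0; k < K; ++k) {
          if (dist2[k] >= gmin) break;
          double px = (wx + offsets(k, 0) - origin[0]) / spacing[0];
          double py = (wy + offsets(k, 1) - origin[1]) / spacing[1];
          double pz = (wz + offsets(k, 2) - origin[2]) / spacing[2];
          bool ok;
          double ev = trilinear_sample(REAL(eval), nx, ny, nz, px, py, pz, ok);
          if (!ok) continue;
          double dd = (ev - rv) * inv_tol;
          double g = dist2[k] + dd * dd;
          if (g < gmin) gmin = g;
        }
        out[idx] = std::sqrt(gmin);
      }
    }
  }
  return out;
}
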