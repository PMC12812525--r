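// Low-level voxel kernels: separable Gaussian smoothing, trilinear/NN warps,
// displacement-field composition/inversion, a multi-channel demons step,
// morphology helpers, and texture-matrix counting. All grids are column-major
// (R order), voxel indices 0-based, displacements stored in mm.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <array>
#include <map>
#include <algorithm>

using namespace Rcpp;

static inline int reflect(int i, int n) {
  // reflect-101 boundary
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * (n - 1) - i;
  }
  return i;
}

static std::vector<double> gauss_kernel(double sigma) {
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double &v : k) v /= s;
  return k;
}

static void smooth_axis(std::vector<double> &a, int nx, int ny, int nz,
                        int axis, double sigma) {
  if (sigma <= 0) return;
  std::vector<double> k = gauss_kernel(sigma);
  int r = ((int)k.size() - 1) / 2;
  std::vector<double> out(a.size());
  int n[3] = {nx, ny, nz};
  long sx = 1, sy = nx, sz = (long)nx * ny;
  long stride[3] = {sx, sy, sz};
  long st = stride[axis];
  int  na = n[axis];
  const double *kp = k.data();
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        long idx = x + sy * y + sz * z;
        int pos = (axis == 0) ? x : (axis == 1 ? y : z);
        double acc = 0.0;
        if (pos >= r && pos + r < na) {  // interior fast path
          const double *ap = &a[idx - (long)r * st];
          for (int j = 0; j <= 2 * r; ++j, ap += st) acc += kp[j] * *ap;
        } else {
          for (int j = -r; j <= r; ++j) {
            int p = reflect(pos + j, na);
            acc += kp[j + r] * a[idx + (long)(p - pos) * st];
          }
        }
        out[idx] = acc;
      }
  a.swap(out);
}

// [[Rcpp::export]]
NumericVector cpp_gaussian_smooth(NumericVector vol, IntegerVector dim,
                                  NumericVector sigma_vox) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long n = (long)nx * ny * nz;
  long nchan = vol.size() / n;
  NumericVector out(vol.size());
  for (long c = 0; c < nchan; ++c) {
    std::vector<double> a(n);
    for (long i = 0; i < n; ++i) a[i] = vol[c * n + i];
    for (int ax = 0; ax < 3; ++ax) smooth_axis(a, nx, ny, nz, ax, sigma_vox[ax]);
    for (long i = 0; i < n; ++i) out[c * n + i] = a[i];
  }
  out.attr("dim") = vol.attr("dim");
  return out;
}

static inline double trilin(const double *v, int nx, int ny, int nz,
                            double x, double y, double z) {
  // clamp to the valid cell range; callers decide out-of-domain policy
  if (x < 0) x = 0; if (x > nx - 1) x = nx - 1;
  if (y < 0) y = 0; if (y > ny - 1) y = ny - 1;
  if (z < 0) z = 0; if (z > nz - 1) z = nz - 1;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  if (x0 > nx - 2) x0 = std::max(0, nx - 2);
  if (y0 > ny - 2) y0 = std::max(0, ny - 2);
  if (z0 > nz - 2) z0 = std::max(0, nz - 2);
  int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
      z1 = std::min(z0 + 1, nz - 1);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  long sy = nx, sz = (long)nx * ny;
#define V(i, j, k) v[(i) + sy * (j) + sz * (k)]
  double c00 = V(x0, y0, z0) * (1 - fx) + V(x1, y0, z0) * fx;
  double c10 = V(x0, y1, z0) * (1 - fx) + V(x1, y1, z0) * fx;
  double c01 = V(x0, y0, z1) * (1 - fx) + V(x1, y0, z1) * fx;
  double c11 = V(x0, y1, z1) * (1 - fx) + V(x1, y1, z1) * fx;
#undef V
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// round half toward the origin (fixed cross-platform tie rule)
static inline int round_half_origin(double v) {
  double av = std::fabs(v);
  double r = std::floor(av + 0.5);
  if (av + 0.5 == r) r -= 1.0;  // exact half: toward origin
  return (v < 0) ? -(int)r : (int)r;
}

// Map an output voxel through (optional) displacement then (optional) affine:
// p = x * spacing; q = p + u(x); s = A q + t; sample input at s / spacing.
// [[Rcpp::export]]
IntegerVector cpp_warp_nn(IntegerVector labels, IntegerVector dim,
                          NumericVector spacing, NumericMatrix A,
                          NumericVector t, Nullable<NumericVector> disp_) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long n = (long)nx * ny * nz;
  IntegerVector out(n);
  const double *u = nullptr;
  NumericVector disp;
  if (disp_.isNotNull()) { disp = disp_.get(); u = REAL(disp); }
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  double a00 = A(0, 0), a01 = A(0, 1), a02 = A(0, 2), t0 = t[0];
  double a10 = A(1, 0), a11 = A(1, 1), a12 = A(1, 2), t1 = t[1];
  double a20 = A(2, 0), a21 = A(2, 1), a22 = A(2, 2), t2 = t[2];
  long i = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x, ++i) {
        double q0 = x * sx, q1 = y * sy, q2 = z * sz;
        if (u) { q0 += u[i]; q1 += u[i + n]; q2 += u[i + 2 * n]; }
        double s0 = a00 * q0 + a01 * q1 + a02 * q2 + t0;
        double s1 = a10 * q0 + a11 * q1 + a12 * q2 + t1;
        double s2 = a20 * q0 + a21 * q1 + a22 * q2 + t2;
        int vx = round_half_origin(s0 / sx);
        int vy = round_half_origin(s1 / sy);
        int vz = round_half_origin(s2 / sz);
        if (vx < 0 || vx >= nx || vy < 0 || vy >= ny || vz < 0 || vz >= nz)
          out[i] = 0;
        else
          out[i] = labels[vx + (long)nx * vy + (long)nx * ny * vz];
      }
  out.attr("dim") = dim;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_warp_lin(NumericVector vol, IntegerVector dim,
                           NumericVector spacing, NumericMatrix A,
                           NumericVector t, Nullable<NumericVector> disp_,
                           double outside) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long n = (long)nx * ny * nz;
  NumericVector out(n);
  const double *u = nullptr;
  NumericVector disp;
  if (disp_.isNotNull()) { disp = disp_.get(); u = REAL(disp); }
  const double *v = REAL(vol);
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  double a00 = A(0, 0), a01 = A(0, 1), a02 = A(0, 2), t0 = t[0];
  double a10 = A(1, 0), a11 = A(1, 1), a12 = A(1, 2), t1 = t[1];
  double a20 = A(2, 0), a21 = A(2, 1), a22 = A(2, 2), t2 = t[2];
  long i = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x, ++i) {
        double q0 = x * sx, q1 = y * sy, q2 = z * sz;
        if (u) { q0 += u[i]; q1 += u[i + n]; q2 += u[i + 2 * n]; }
        double s0 = (a00 * q0 + a01 * q1 + a02 * q2 + t0) / sx;
        double s1 = (a10 * q0 + a11 * q1 + a12 * q2 + t1) / sy;
        double s2 = (a20 * q0 + a21 * q1 + a22 * q2 + t2) / sz;
        if (s0 < -0.5 || s0 > nx - 0.5 || s1 < -0.5 || s1 > ny - 0.5 ||
            s2 < -0.5 || s2 > nz - 0.5)
          out[i] = outside;
        else
          out[i] = trilin(v, nx, ny, nz, s0, s1, s2);
      }
  out.attr("dim") = dim;
  return out;
}

// Sample a displacement field (mm, on-grid) at physical offsets v (mm):
// result(x) = u(x + v(x)); used for composition and inversion.
static void sample_disp(const double *u, int nx, int ny, int nz,
                        const double *sp, const double *v, double *out) {
  long n = (long)nx * ny * nz;
  long i = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x, ++i) {
        double px = x + v[i] / sp[0];
        double py = y + v[i + n] / sp[1];
        double pz = z + v[i + 2 * n] / sp[2];
        for (int c = 0; c < 3; ++c)
          out[i + c * n] = trilin(u + c * n, nx, ny, nz, px, py, pz);
      }
}

// w(x) = v(x) + u(x + v(x))  (apply v first, then u)
// [[Rcpp::export]]
NumericVector cpp_compose_disp(NumericVector u, NumericVector v,
                               IntegerVector dim, NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long n = (long)nx * ny * nz;
  NumericVector w(3 * n);
  std::vector<double> uv(3 * n);
  sample_disp(REAL(u), nx, ny, nz, REAL(spacing), REAL(v), uv.data());
  for (long i = 0; i < 3 * n; ++i) w[i] = v[i] + uv[i];
  w.attr("dim") = u.attr("dim");
  return w;
}

// Fixed-point inversion: u_inv <- -u(x + u_inv(x)); returns field + residual
// [[Rcpp::export]]
List cpp_invert_disp(NumericVector u, IntegerVector dim, NumericVector spacing,
                     int max_iter, double tol_mm) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long n = (long)nx * ny * nz;
  NumericVector inv(3 * n);
  std::vector<double> tmp(3 * n);
  double resid = R_PosInf;
  for (int it = 0; it < max_iter; ++it) {
    sample_disp(REAL(u), nx, ny, nz, REAL(spacing), REAL(inv), tmp.data());
    double mx = 0.0;
    for (long i = 0; i < n; ++i) {
      double d0 = -tmp[i] - inv[i];
      double d1 = -tmp[i + n] - inv[i + n];
      double d2 = -tmp[i + 2 * n] - inv[i + 2 * n];
      double m = std::sqrt(d0 * d0 + d1 * d1 + d2 * d2);
      if (m > mx) mx = m;
      inv[i] = -tmp[i];
      inv[i + n] = -tmp[i + n];
      inv[i + 2 * n] = -tmp[i + 2 * n];
    }
    resid = mx;
    if (mx < tol_mm) break;
  }
  // residual of the achieved inverse: r(x) = u_inv(x) + u(x + u_inv(x))
  sample_disp(REAL(u), nx, ny, nz, REAL(spacing), REAL(inv), tmp.data());
  NumericVector rmag(n);
  for (long i = 0; i < n; ++i) {
    double d0 = tmp[i] + inv[i];
    double d1 = tmp[i + n] + inv[i + n];
    double d2 = tmp[i + 2 * n] + inv[i + 2 * n];
    rmag[i] = std::sqrt(d0 * d0 + d1 * d1 + d2 * d2);
  }
  inv.attr("dim") = u.attr("dim");
  return List::create(_["inverse"] = inv, _["residual_mm"] = rmag,
                      _["update_mm"] = resid);
}

// [[Rcpp::export]]
NumericVector cpp_jacobian_det(NumericVector u, IntegerVector dim,
                               NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long n = (long)nx * ny * nz;
  NumericVector det(n);
  const double *U = REAL(u);
  long sy = nx, sz = (long)nx * ny;
  long i = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x, ++i) {
        double J[3][3];
        for (int c = 0; c < 3; ++c) {
          const double *uc = U + c * n;
          int xm = std::max(x - 1, 0), xp = std::min(x + 1, nx - 1);
          int ym = std::max(y - 1, 0), yp = std::min(y + 1, ny - 1);
          int zm = std::max(z - 1, 0), zp = std::min(z + 1, nz - 1);
          J[c][0] = (uc[xp + sy * y + sz * z] - uc[xm + sy * y + sz * z]) /
                    ((xp - xm) * spacing[0]);
          J[c][1] = (uc[x + sy * yp + sz * z] - uc[x + sy * ym + sz * z]) /
                    ((yp - ym) * spacing[1]);
          J[c][2] = (uc[x + sy * y + sz * zp] - uc[x + sy * y + sz * zm]) /
                    ((zp - zm) * spacing[2]);
        }
        for (int c = 0; c < 3; ++c) J[c][c] += 1.0;
        det[i] = J[0][0] * (J[1][1] * J[2][2] - J[1][2] * J[2][1]) -
                 J[0][1] * (J[1][0] * J[2][2] - J[1][2] * J[2][0]) +
                 J[0][2] * (J[1][0] * J[2][1] - J[1][1] * J[2][0]);
      }
  det.attr("dim") = dim;
  return det;
}

// Multi-channel demons on pre-smoothed one-hot probability channels.
// mov/fix: (nx*ny*nz*nc); ignore: nx*ny*nz (1 = exclude from similarity).
// Returns the displacement field (mm) and the per-iteration mean squared
// channel mismatch outside the ignore mask.
// [[Rcpp::export]]
List cpp_demons(NumericVector mov, NumericVector fix, IntegerVector dim,
                NumericVector spacing, IntegerVector ignore,
                NumericVector init_disp, int n_iter, double sigma_update_vox,
                double sigma_field_vox, double max_step_mm) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long n = (long)nx * ny * nz;
  long nc = mov.size() / n;
  std::vector<double> u(REAL(init_disp), REAL(init_disp) + 3 * n);
  std::vector<double> force(3 * n), warped(n), grad(3);
  NumericVector trace(n_iter);
  const double *M = REAL(mov), *F = REAL(fix);
  const int *ig = INTEGER(ignore);
  long sy = nx, sz = (long)nx * ny;
  double spx = spacing[0], spy = spacing[1], spz = spacing[2];
  double alpha2 = 1.0; // demons normalisation (mm^-2 scale ~ 1)
  for (int it = 0; it < n_iter; ++it) {
    std::fill(force.begin(), force.end(), 0.0);
    double sse = 0.0; long cnt = 0;
    for (long c = 0; c < nc; ++c) {
      const double *Mc = M + c * n, *Fc = F + c * n;
      // warp channel
      long i = 0;
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
          for (int x = 0; x < nx; ++x, ++i) {
            double px = x + u[i] / spx;
            double py = y + u[i + n] / spy;
            double pz = z + u[i + 2 * n] / spz;
            warped[i] = trilin(Mc, nx, ny, nz, px, py, pz);
          }
      // demons force from warped channel
      i = 0;
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
          for (int x = 0; x < nx; ++x, ++i) {
            double diff = Fc[i] - warped[i];
            if (ig[i]) continue;
            sse += diff * diff;
            int xm = std::max(x - 1, 0), xp = std::min(x + 1, nx - 1);
            int ym = std::max(y - 1, 0), yp = std::min(y + 1, ny - 1);
            int zm = std::max(z - 1, 0), zp = std::min(z + 1, nz - 1);
            double gx = (warped[xp + sy * y + sz * z] -
                         warped[xm + sy * y + sz * z]) / ((xp - xm) * spx);
            double gy = (warped[x + sy * yp + sz * z] -
                         warped[x + sy * ym + sz * z]) / ((yp - ym) * spy);
            double gz = (warped[x + sy * y + sz * zp] -
                         warped[x + sy * y + sz * zm]) / ((zp - zm) * spz);
            double g2 = gx * gx + gy * gy + gz * gz;
            double den = g2 + alpha2 * diff * diff;
            if (den < 1e-12) continue;
            double s = diff / den;
            force[i] += s * gx;
            force[i + n] += s * gy;
            force[i + 2 * n] += s * gz;
          }
    }
    for (long i = 0; i < n; ++i) if (!ig[i]) ++cnt;
    trace[it] = (cnt > 0) ? sse / ((double)cnt * nc) : 0.0;
    // smooth the update, cap the step, add, then smooth the field
    for (int c = 0; c < 3; ++c) {
      std::vector<double> fc(force.begin() + c * n, force.begin() + (c + 1) * n);
      for (int ax = 0; ax < 3; ++ax)
        smooth_axis(fc, nx, ny, nz, ax, sigma_update_vox);
      std::copy(fc.begin(), fc.end(), force.begin() + c * n);
    }
    double mx = 0.0;
    for (long i = 0; i < n; ++i) {
      double m = std::sqrt(force[i] * force[i] + force[i + n] * force[i + n] +
                           force[i + 2 * n] * force[i + 2 * n]);
      if (m > mx) mx = m;
    }
    double scale = (mx > 1e-12) ? std::min(1.0, max_step_mm / mx) : 0.0;
    for (long i = 0; i < 3 * n; ++i) u[i] += scale * force[i];
    if (sigma_field_vox > 0) {
      for (int c = 0; c < 3; ++c) {
        std::vector<double> uc(u.begin() + c * n, u.begin() + (c + 1) * n);
        for (int ax = 0; ax < 3; ++ax)
          smooth_axis(uc, nx, ny, nz, ax, sigma_field_vox);
        std::copy(uc.begin(), uc.end(), u.begin() + c * n);
      }
    }
  }
  NumericVector out(3 * n);
  std::copy(u.begin(), u.end(), out.begin());
  out.attr("dim") = IntegerVector::create(nx, ny, nz, 3);
  return List::create(_["disp"] = out, _["trace"] = trace);
}

// Linear resampling between grids; voxel centers mapped proportionally.
// [[Rcpp::export]]
NumericVector cpp_resample_lin(NumericVector vol, IntegerVector in_dim,
                               IntegerVector out_dim) {
  int nx = in_dim[0], ny = in_dim[1], nz = in_dim[2];
  int ox = out_dim[0], oy = out_dim[1], oz = out_dim[2];
  NumericVector out((long)ox * oy * oz);
  const double *v = REAL(vol);
  double fx = (ox > 1) ? (double)(nx - 1) / (ox - 1) : 0.0;
  double fy = (oy > 1) ? (double)(ny - 1) / (oy - 1) : 0.0;
  double fz = (oz > 1) ? (double)(nz - 1) / (oz - 1) : 0.0;
  long i = 0;
  for (int z = 0; z < oz; ++z)
    for (int y = 0; y < oy; ++y)
      for (int x = 0; x < ox; ++x, ++i)
        out[i] = trilin(v, nx, ny, nz, x * fx, y * fy, z * fz);
  out.attr("dim") = out_dim;
  return out;
}

// Binary dilation with an ellipsoidal structuring element (voxel radii).
// [[Rcpp::export]]
IntegerVector cpp_dilate(IntegerVector mask, IntegerVector dim,
                         NumericVector rad_vox) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long n = (long)nx * ny * nz;
  IntegerVector out(n);
  int rx = (int)std::floor(rad_vox[0]), ry = (int)std::floor(rad_vox[1]),
      rz = (int)std::floor(rad_vox[2]);
  std::vector<std::array<int, 3>> offs;
  for (int dz = -rz; dz <= rz; ++dz)
    for (int dy = -ry; dy <= ry; ++dy)
      for (int dx = -rx; dx <= rx; ++dx) {
        double d = 0.0;
        if (rad_vox[0] > 0) d += (double)dx * dx / (rad_vox[0] * rad_vox[0]);
        else if (dx != 0) continue;
        if (rad_vox[1] > 0) d += (double)dy * dy / (rad_vox[1] * rad_vox[1]);
        else if (dy != 0) continue;
        if (rad_vox[2] > 0) d += (double)dz * dz / (rad_vox[2] * rad_vox[2]);
        else if (dz != 0) continue;
        if (d <= 1.0) offs.push_back({dx, dy, dz});
      }
  long i = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x, ++i) {
        if (!mask[i]) continue;
        for (auto &o : offs) {
          int px = x + o[0], py = y + o[1], pz = z + o[2];
          if (px < 0 || px >= nx || py < 0 || py >= ny || pz < 0 || pz >= nz)
            continue;
          out[px + (long)nx * py + (long)nx * ny * pz] = 1;
        }
      }
  out.attr("dim") = dim;
  return out;
}

// Fill label==0 voxels inside region with the modal non-zero 26-neighbour
// label, iterating until stable (or max sweeps).
// [[Rcpp::export]]
IntegerVector cpp_fill_background(IntegerVector labels, IntegerVector dim,
                                  IntegerVector region, int max_sweeps) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long n = (long)nx * ny * nz;
  IntegerVector cur = clone(labels);
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    bool changed = false;
    IntegerVector nxt = clone(cur);
    long i = 0;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x, ++i) {
          if (!region[i] || cur[i] != 0) continue;
          std::map<int, int> cnt;
          for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                if (!dx && !dy && !dz) continue;
                int px = x + dx, py = y + dy, pz = z + dz;
                if (px < 0 || px >= nx || py < 0 || py >= ny || pz < 0 ||
                    pz >= nz)
                  continue;
                int l = cur[px + (long)nx * py + (long)nx * ny * pz];
                if (l > 0) cnt[l]++;
              }
          if (!cnt.empty()) {
            int best = 0, bc = -1;
            for (auto &kv : cnt)
              if (kv.second > bc) { bc = kv.second; best = kv.first; }
            nxt[i] = best;
            changed = true;
          }
        }
    cur = nxt;
    if (!changed) break;
  }
  cur.attr("dim") = dim;
  return cur;
}

// Number of 26-connected components of a binary mask.
// [[Rcpp::export]]
int cpp_n_components(IntegerVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long n = (long)nx * ny * nz;
  std::vector<char> vis(n, 0);
  int comps = 0;
  std::vector<long> stack;
  for (long s = 0; s < n; ++s) {
    if (!mask[s] || vis[s]) continue;
    ++comps;
    stack.clear();
    stack.push_back(s);
    vis[s] = 1;
    while (!stack.empty()) {
      long i = stack.back();
      stack.pop_back();
      int x = i % nx, y = (i / nx) % ny, z = i / ((long)nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int px = x + dx, py = y + dy, pz = z + dz;
            if (px < 0 || px >= nx || py < 0 || py >= ny || pz < 0 || pz >= nz)
              continue;
            long j = px + (long)nx * py + (long)nx * ny * pz;
            if (mask[j] && !vis[j]) { vis[j] = 1; stack.push_back(j); }
          }
    }
  }
  return comps;
}

static const int DIRS13[13][3] = {
    {1, 0, 0}, {0, 1, 0}, {0, 0, 1}, {1, 1, 0}, {1, -1, 0}, {1, 0, 1},
    {1, 0, -1}, {0, 1, 1}, {0, 1, -1}, {1, 1, 1}, {1, 1, -1}, {1, -1, 1},
    {1, -1, -1}};

// Raw directed co-occurrence counts: nlev x nlev x 13 (not symmetrised).
// [[Rcpp::export]]
NumericVector cpp_glcm(IntegerVector disc, IntegerVector mask,
                       IntegerVector dim, int nlev) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out((long)nlev * nlev * 13);
  long i = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x, ++i) {
        if (!mask[i]) continue;
        int a = disc[i];
        for (int d = 0; d < 13; ++d) {
          int px = x + DIRS13[d][0], py = y + DIRS13[d][1],
              pz = z + DIRS13[d][2];
          if (px < 0 || px >= nx || py < 0 || py >= ny || pz < 0 || pz >= nz)
            continue;
          long j = px + (long)nx * py + (long)nx * ny * pz;
          if (!mask[j]) continue;
          int b = disc[j];
          out[(a - 1) + (long)nlev * (b - 1) + (long)nlev * nlev * d] += 1.0;
        }
      }
  out.attr("dim") = IntegerVector::create(nlev, nlev, 13);
  return out;
}

// Run-length counts: nlev x maxrun x 13.
// [[Rcpp::export]]
NumericVector cpp_glrlm(IntegerVector disc, IntegerVector mask,
                        IntegerVector dim, int nlev, int maxrun) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out((long)nlev * maxrun * 13);
  for (int d = 0; d < 13; ++d) {
    int ux = DIRS13[d][0], uy = DIRS13[d][1], uz = DIRS13[d][2];
    long i = 0;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x, ++i) {
          if (!mask[i]) continue;
          int g = disc[i];
          // run start: predecessor outside mask / grid or different level
          int bx = x - ux, by = y - uy, bz = z - uz;
          bool start = true;
          if (bx >= 0 && bx < nx && by >= 0 && by < ny && bz >= 0 && bz < nz) {
            long j = bx + (long)nx * by + (long)nx * ny * bz;
            if (mask[j] && disc[j] == g) start = false;
          }
          if (!start) continue;
          int len = 1;
          int cx = x + ux, cy = y + uy, cz = z + uz;
          while (cx >= 0 && cx < nx && cy >= 0 && cy < ny && cz >= 0 &&
                 cz < nz) {
            long j = cx + (long)nx * cy + (long)nx * ny * cz;
            if (!mask[j] || disc[j] != g) break;
            ++len;
            cx += ux; cy += uy; cz += uz;
          }
          if (len > maxrun) len = maxrun;
          out[(g - 1) + (long)nlev * (len - 1) + (long)nlev * maxrun * d] += 1.0;
        }
  }
  out.attr("dim") = IntegerVector::create(nlev, maxrun, 13);
  return out;
}

// Size-zone counts as a (level, size) pair list; 26-connected zones.
// [[Rcpp::export]]
IntegerMatrix cpp_glszm(IntegerVector disc, IntegerVector mask,
                        IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long n = (long)nx * ny * nz;
  std::vector<char> vis(n, 0);
  std::vector<std::pair<int, int>> zones;
  std::vector<long> stack;
  for (long s = 0; s < n; ++s) {
    if (!mask[s] || vis[s]) continue;
    int g = disc[s];
    int size = 0;
    stack.clear();
    stack.push_back(s);
    vis[s] = 1;
    while (!stack.empty()) {
      long i = stack.back();
      stack.pop_back();
      ++size;
      int x = i % nx, y = (i / nx) % ny, z = i / ((long)nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int px = x + dx, py = y + dy, pz = z + dz;
            if (px < 0 || px >= nx || py < 0 || py >= ny || pz < 0 || pz >= nz)
              continue;
            long j = px + (long)nx * py + (long)nx * ny * pz;
            if (mask[j] && !vis[j] && disc[j] == g) {
              vis[j] = 1;
              stack.push_back(j);
            }
          }
    }
    zones.push_back({g, size});
  }
  IntegerMatrix out(zones.size(), 2);
  for (size_t k = 0; k < zones.size(); ++k) {
    out(k, 0) = zones[k].first;
    out(k, 1) = zones[k].second;
  }
  return out;
}

// Dependence counts: nlev x 27 ((dependence 0..26) + 1 columns).
// [[Rcpp::export]]
NumericMatrix cpp_gldm(IntegerVector disc, IntegerVector mask,
                       IntegerVector dim, int nlev, int alpha) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix out(nlev, 27);
  long i = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x, ++i) {
        if (!mask[i]) continue;
        int g = disc[i], dep = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              int px = x + dx, py = y + dy, pz = z + dz;
              if (px < 0 || px >= nx || py < 0 || py >= ny || pz < 0 ||
                  pz >= nz)
                continue;
              long j = px + (long)nx * py + (long)nx * ny * pz;
              if (mask[j] && std::abs(disc[j] - g) <= alpha) ++dep;
            }
        out(g - 1, dep) += 1.0;
      }
  return out;
}

// Indices (0-based) of mask voxels with at least one 6-neighbour outside.
// [[Rcpp::export]]
IntegerVector cpp_boundary_idx(IntegerVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<int> res;
  long i = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x, ++i) {
        if (!mask[i]) continue;
        bool b = false;
        const int N6[6][3] = {{1, 0, 0}, {-1, 0, 0}, {0, 1, 0},
                              {0, -1, 0}, {0, 0, 1}, {0, 0, -1}};
        for (int k = 0; k < 6 && !b; ++k) {
          int px = x + N6[k][0], py = y + N6[k][1], pz = z + N6[k][2];
          if (px < 0 || px >= nx || py < 0 || py >= ny || pz < 0 || pz >= nz)
            b = true;
          else if (!mask[px + (long)nx * py + (long)nx * ny * pz])
            b = true;
        }
        if (b) res.push_back((int)i);
      }
  return wrap(res);
}
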