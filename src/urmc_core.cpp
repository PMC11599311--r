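#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

// All volumes are column-major (x fastest), world coords in mm from FOV
// center, origin = world position of the center of voxel [1,1,1].

static inline int vidx(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// Trilinear gather at continuous 0-based index (fx,fy,fz); 0 outside.
// Points in the outer half-voxel rim are clamped (nearest extension), so a
// voxel's value extends over its full physical extent; beyond that -> 0.
static inline bool tri_setup(double& f, int n, int& i0, int& i1, double& d) {
  if (f < -0.5 || f > n - 0.5) return false;
  if (f < 0) f = 0;
  if (f > n - 1) f = n - 1;
  i0 = (int)std::floor(f);
  if (i0 > n - 2) i0 = n > 1 ? n - 2 : 0;
  i1 = i0 + 1 < n ? i0 + 1 : i0;
  d = f - i0;
  return true;
}

static inline double tri_gather(const double* a, int nx, int ny, int nz,
                                double fx, double fy, double fz) {
  int i0, i1, j0, j1, k0, k1;
  double dx, dy, dz;
  if (!tri_setup(fx, nx, i0, i1, dx) || !tri_setup(fy, ny, j0, j1, dy) ||
      !tri_setup(fz, nz, k0, k1, dz))
    return 0.0;
  double c000 = a[vidx(i0, j0, k0, nx, ny)],     c100 = a[vidx(i1, j0, k0, nx, ny)];
  double c010 = a[vidx(i0, j1, k0, nx, ny)],     c110 = a[vidx(i1, j1, k0, nx, ny)];
  double c001 = a[vidx(i0, j0, k1, nx, ny)],     c101 = a[vidx(i1, j0, k1, nx, ny)];
  double c011 = a[vidx(i0, j1, k1, nx, ny)],     c111 = a[vidx(i1, j1, k1, nx, ny)];
  double c00 = c000 * (1 - dx) + c100 * dx, c10 = c010 * (1 - dx) + c110 * dx;
  double c01 = c001 * (1 - dx) + c101 * dx, c11 = c011 * (1 - dx) + c111 * dx;
  double c0 = c00 * (1 - dy) + c10 * dy, c1 = c01 * (1 - dy) + c11 * dy;
  return c0 * (1 - dz) + c1 * dz;
}

// Trilinear scatter (adjoint of tri_gather): adds val with the same weights.
static inline void tri_scatter(double* a, int nx, int ny, int nz,
                               double fx, double fy, double fz, double val) {
  int i0, i1, j0, j1, k0, k1;
  double dx, dy, dz;
  if (!tri_setup(fx, nx, i0, i1, dx) || !tri_setup(fy, ny, j0, j1, dy) ||
      !tri_setup(fz, nz, k0, k1, dz))
    return;
  a[vidx(i0, j0, k0, nx, ny)] += val * (1 - dx) * (1 - dy) * (1 - dz);
  a[vidx(i1, j0, k0, nx, ny)] += val * dx * (1 - dy) * (1 - dz);
  a[vidx(i0, j1, k0, nx, ny)] += val * (1 - dx) * dy * (1 - dz);
  a[vidx(i1, j1, k0, nx, ny)] += val * dx * dy * (1 - dz);
  a[vidx(i0, j0, k1, nx, ny)] += val * (1 - dx) * (1 - dy) * dz;
  a[vidx(i1, j0, k1, nx, ny)] += val * dx * (1 - dy) * dz;
  a[vidx(i0, j1, k1, nx, ny)] += val * (1 - dx) * dy * dz;
  a[vidx(i1, j1, k1, nx, ny)] += val * dx * dy * dz;
}

// Clip the segment p + t*u, t in [t0,t1], to the grid bounding box
// (half-voxel margin beyond voxel centers). Returns false if no overlap.
static inline bool clip_to_grid(double px, double py, double pz,
                                double ux, double uy, double uz,
                                const IntegerVector& dim,
                                const NumericVector& spacing,
                                const NumericVector& origin,
                                double& t0, double& t1) {
  double p[3] = {px, py, pz}, u[3] = {ux, uy, uz};
  for (int a = 0; a < 3; ++a) {
    double lo = origin[a] - 0.5 * spacing[a];
    double hi = origin[a] + (dim[a] - 0.5) * spacing[a];
    if (std::fabs(u[a]) < 1e-12) {
      if (p[a] < lo || p[a] > hi) return false;
    } else {
      double ta = (lo - p[a]) / u[a], tb = (hi - p[a]) / u[a];
      if (ta > tb) std::swap(ta, tb);
      if (ta > t0) t0 = ta;
      if (tb < t1) t1 = tb;
      if (t0 >= t1) return false;
    }
  }
  return true;
}

// Intersect emission point + direction with the scanner cylinder.
// Returns accept flag, detector endpoints, true TOF offset (mm toward det2)
// and the attenuation line integral along the full chord.
// [[Rcpp::export]]
List cpp_project_events(NumericMatrix pts, NumericMatrix dirs,
                        double ring_radius, double axial_half,
                        NumericVector mu, IntegerVector dim,
                        NumericVector spacing, NumericVector origin,
                        double step) {
  int n = pts.nrow();
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const double* muv = mu.begin();
  LogicalVector accept(n);
  NumericMatrix det1(n, 3), det2(n, 3);
  NumericVector offset(n), attn(n);
  double R2 = ring_radius * ring_radius;
  for (int e = 0; e < n; ++e) {
    accept[e] = false;
    double px = pts(e, 0), py = pts(e, 1), pz = pts(e, 2);
    double ux = dirs(e, 0), uy = dirs(e, 1), uz = dirs(e, 2);
    double a = ux * ux + uy * uy;
    if (a < 1e-12) continue;  // axial LOR never hits the ring
    double b = 2.0 * (px * ux + py * uy);
    double c = px * px + py * py - R2;
    double disc = b * b - 4.0 * a * c;
    if (disc <= 0) continue;  // emission outside ring (should not happen)
    double sq = std::sqrt(disc);
    double t1 = (-b - sq) / (2.0 * a), t2 = (-b + sq) / (2.0 * a);
    double z1 = pz + t1 * uz, z2 = pz + t2 * uz;
    if (std::fabs(z1) > axial_half || std::fabs(z2) > axial_half) continue;
    det1(e, 0) = px + t1 * ux; det1(e, 1) = py + t1 * uy; det1(e, 2) = z1;
    det2(e, 0) = px + t2 * ux; det2(e, 1) = py + t2 * uy; det2(e, 2) = z2;
    offset[e] = -(t1 + t2) / 2.0;  // emission at t=0, midpoint at (t1+t2)/2
    // attenuation along the chord det1 -> det2, clipped to the mu grid
    double ta = t1, tb = t2, integ = 0.0, ds = step;
    if (clip_to_grid(px, py, pz, ux, uy, uz, dim, spacing, origin, ta, tb)) {
      double L = tb - ta;
      int K = (int)std::ceil(L / step);
      ds = L / K;
      for (int k = 0; k < K; ++k) {
        double t = ta + (k + 0.5) * ds;
        double fx = (px + t * ux - origin[0]) / spacing[0];
        double fy = (py + t * uy - origin[1]) / spacing[1];
        double fz = (pz + t * uz - origin[2]) / spacing[2];
        integ += tri_gather(muv, nx, ny, nz, fx, fy, fz);
      }
    }
    attn[e] = integ * ds * 0.1;  // mu is 1/cm, ds in mm
    accept[e] = true;
  }
  return List::create(_["accept"] = accept, _["det1"] = det1, _["det2"] = det2,
                      _["offset"] = offset, _["attn"] = attn);
}

// Line integral of mu (1/cm) between paired points a, b (mm); returns unitless
// optical depth per row.
// [[Rcpp::export]]
NumericVector cpp_line_integral(NumericMatrix a, NumericMatrix b,
                                NumericVector mu, IntegerVector dim,
                                NumericVector spacing, NumericVector origin,
                                double step) {
  int n = a.nrow();
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const double* muv = mu.begin();
  NumericVector out(n);
  for (int e = 0; e < n; ++e) {
    double ax = a(e, 0), ay = a(e, 1), az = a(e, 2);
    double dx = b(e, 0) - ax, dy = b(e, 1) - ay, dz = b(e, 2) - az;
    double L = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (L <= 0) { out[e] = 0.0; continue; }
    double ux = dx / L, uy = dy / L, uz = dz / L;
    double ta = 0.0, tb = L, integ = 0.0, ds = step;
    if (clip_to_grid(ax, ay, az, ux, uy, uz, dim, spacing, origin, ta, tb)) {
      int K = (int)std::ceil((tb - ta) / step);
      ds = (tb - ta) / K;
      for (int k = 0; k < K; ++k) {
        double t = ta + (k + 0.5) * ds;
        double fx = (ax + t * ux - origin[0]) / spacing[0];
        double fy = (ay + t * uy - origin[1]) / spacing[1];
        double fz = (az + t * uz - origin[2]) / spacing[2];
        integ += tri_gather(muv, nx, ny, nz, fx, fy, fz);
      }
    }
    out[e] = integ * ds * 0.1;
  }
  return out;
}

// Shared sampling scheme for the TOF-weighted projector so the forward and
// backward operators are exact adjoints: samples at fixed steps along the
// chord, restricted to +-trunc sigma around the TOF position, Gaussian pdf
// weighted.
struct TofRay {
  double ox, oy, oz;   // det1
  double dx, dy, dz;   // unit direction det1->det2
  double lo, hi;       // sampling range (mm along chord from det1)
};

static inline bool tof_ray_setup(const double* d1, const double* d2,
                                 double off, double sigma, double trunc,
                                 TofRay& r) {
  double dx = d2[0] - d1[0], dy = d2[1] - d1[1], dz = d2[2] - d1[2];
  double L = std::sqrt(dx * dx + dy * dy + dz * dz);
  if (L <= 0) return false;
  r.ox = d1[0]; r.oy = d1[1]; r.oz = d1[2];
  r.dx = dx / L; r.dy = dy / L; r.dz = dz / L;
  double tq = L / 2.0 + off;  // TOF position along chord
  r.lo = std::max(0.0, tq - trunc * sigma);
  r.hi = std::min(L, tq + trunc * sigma);
  return r.hi > r.lo;
}

// [[Rcpp::export]]
NumericVector cpp_tof_forward(NumericMatrix det1, NumericMatrix det2,
                              NumericVector offset, NumericVector img,
                              IntegerVector dim, NumericVector spacing,
                              NumericVector origin, double sigma,
                              double step, double trunc) {
  int n = det1.nrow();
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const double* a = img.begin();
  NumericVector out(n);
  double norm = 1.0 / (sigma * std::sqrt(2.0 * M_PI));
  for (int e = 0; e < n; ++e) {
    double d1[3] = {det1(e, 0), det1(e, 1), det1(e, 2)};
    double d2[3] = {det2(e, 0), det2(e, 1), det2(e, 2)};
    TofRay r;
    if (!tof_ray_setup(d1, d2, offset[e], sigma, trunc, r)) { out[e] = 0.0; continue; }
    double L = std::sqrt((d2[0]-d1[0])*(d2[0]-d1[0]) + (d2[1]-d1[1])*(d2[1]-d1[1]) +
                         (d2[2]-d1[2])*(d2[2]-d1[2]));
    double tq = L / 2.0 + offset[e];
    int K = (int)std::ceil((r.hi - r.lo) / step);
    double ds = (r.hi - r.lo) / K, acc = 0.0;
    for (int k = 0; k < K; ++k) {
      double t = r.lo + (k + 0.5) * ds;
      double w = norm * std::exp(-0.5 * (t - tq) * (t - tq) / (sigma * sigma)) * ds;
      double fx = (r.ox + t * r.dx - origin[0]) / spacing[0];
      double fy = (r.oy + t * r.dy - origin[1]) / spacing[1];
      double fz = (r.oz + t * r.dz - origin[2]) / spacing[2];
      acc += w * tri_gather(a, nx, ny, nz, fx, fy, fz);
    }
    out[e] = acc;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_tof_backward(NumericMatrix det1, NumericMatrix det2,
                               NumericVector offset, NumericVector vals,
                               IntegerVector dim, NumericVector spacing,
                               NumericVector origin, double sigma,
                               double step, double trunc) {
  int n = det1.nrow();
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  double* a = out.begin();
  double norm = 1.0 / (sigma * std::sqrt(2.0 * M_PI));
  for (int e = 0; e < n; ++e) {
    if (vals[e] == 0.0) continue;
    double d1[3] = {det1(e, 0), det1(e, 1), det1(e, 2)};
    double d2[3] = {det2(e, 0), det2(e, 1), det2(e, 2)};
    TofRay r;
    if (!tof_ray_setup(d1, d2, offset[e], sigma, trunc, r)) continue;
    double L = std::sqrt((d2[0]-d1[0])*(d2[0]-d1[0]) + (d2[1]-d1[1])*(d2[1]-d1[1]) +
                         (d2[2]-d1[2])*(d2[2]-d1[2]));
    double tq = L / 2.0 + offset[e];
    int K = (int)std::ceil((r.hi - r.lo) / step);
    double ds = (r.hi - r.lo) / K;
    for (int k = 0; k < K; ++k) {
      double t = r.lo + (k + 0.5) * ds;
      double w = norm * std::exp(-0.5 * (t - tq) * (t - tq) / (sigma * sigma)) * ds;
      double fx = (r.ox + t * r.dx - origin[0]) / spacing[0];
      double fy = (r.oy + t * r.dy - origin[1]) / spacing[1];
      double fz = (r.oz + t * r.dz - origin[2]) / spacing[2];
      tri_scatter(a, nx, ny, nz, fx, fy, fz, vals[e] * w);
    }
  }
  return out;
}

// Plain (non-TOF) backprojection of weighted LORs, for the Monte-Carlo
// sensitivity image.
// [[Rcpp::export]]
NumericVector cpp_sens_backproject(NumericMatrix e1, NumericMatrix e2,
                                   NumericVector w, IntegerVector dim,
                                   NumericVector spacing, NumericVector origin,
                                   double step) {
  int n = e1.nrow();
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  double* a = out.begin();
  for (int e = 0; e < n; ++e) {
    double ax = e1(e, 0), ay = e1(e, 1), az = e1(e, 2);
    double dx = e2(e, 0) - ax, dy = e2(e, 1) - ay, dz = e2(e, 2) - az;
    double L = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (L <= 0) continue;
    double ux = dx / L, uy = dy / L, uz = dz / L;
    double ta = 0.0, tb = L;
    if (!clip_to_grid(ax, ay, az, ux, uy, uz, dim, spacing, origin, ta, tb))
      continue;
    int K = (int)std::ceil((tb - ta) / step);
    double ds = (tb - ta) / K;
    for (int k = 0; k < K; ++k) {
      double t = ta + (k + 0.5) * ds;
      double fx = (ax + t * ux - origin[0]) / spacing[0];
      double fy = (ay + t * uy - origin[1]) / spacing[1];
      double fz = (az + t * uz - origin[2]) / spacing[2];
      tri_scatter(a, nx, ny, nz, fx, fy, fz, w[e] * ds);
    }
  }
  return out;
}

// Separable Gaussian smoothing, truncated at 3 sigma, edge-renormalized.
// [[Rcpp::export]]
NumericVector cpp_gauss_smooth(NumericVector arr, IntegerVector dim,
                               NumericVector sigma_vox) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  std::vector<double> cur(arr.begin(), arr.end()), nxt(ntot);
  int n[3] = {nx, ny, nz};
  int stride[3] = {1, nx, nx * ny};
  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma_vox[axis];
    if (s <= 0) continue;
    int hw = (int)std::ceil(3.0 * s);
    std::vector<double> ker(2 * hw + 1);
    for (int k = -hw; k <= hw; ++k)
      ker[k + hw] = std::exp(-0.5 * k * k / (s * s));
    int na = n[axis], st = stride[axis];
    // iterate over all lines along `axis`
    int nb = (axis == 0) ? ny : nx;
    int nc = (axis == 2) ? ny : nz;
    int stb = (axis == 0) ? stride[1] : stride[0];
    int stc = (axis == 2) ? stride[1] : stride[2];
    for (int c = 0; c < nc; ++c) {
      for (int b = 0; b < nb; ++b) {
        R_xlen_t base = (R_xlen_t)b * stb + (R_xlen_t)c * stc;
        for (int i = 0; i < na; ++i) {
          double acc = 0.0, wsum = 0.0;
          int klo = std::max(-hw, -i), khi = std::min(hw, na - 1 - i);
          for (int k = klo; k <= khi; ++k) {
            double w = ker[k + hw];
            acc += w * cur[base + (R_xlen_t)(i + k) * st];
            wsum += w;
          }
          nxt[base + (R_xlen_t)i * st] = acc / wsum;
        }
      }
    }
    cur.swap(nxt);
  }
  return NumericVector(cur.begin(), cur.end());
}

// Pulling warp on the native grid: out(v) = img sampled at world(v) + d(v).
// [[Rcpp::export]]
NumericVector cpp_warp_pull(NumericVector img, IntegerVector dim,
                            NumericVector spacing, NumericVector origin,
                            NumericVector fx, NumericVector fy,
                            NumericVector fz) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  const double* a = img.begin();
  R_xlen_t v = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++v) {
        double wx = origin[0] + i * spacing[0] + fx[v];
        double wy = origin[1] + j * spacing[1] + fy[v];
        double wz = origin[2] + k * spacing[2] + fz[v];
        out[v] = tri_gather(a, nx, ny, nz,
                            (wx - origin[0]) / spacing[0],
                            (wy - origin[1]) / spacing[1],
                            (wz - origin[2]) / spacing[2]);
      }
  return out;
}

// Resample a volume onto a new regular grid (trilinear, 0 outside).
// [[Rcpp::export]]
NumericVector cpp_resample_grid(NumericVector img, IntegerVector dim,
                                NumericVector spacing, NumericVector origin,
                                IntegerVector odim, NumericVector ospacing,
                                NumericVector oorigin) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int mx = odim[0], my = odim[1], mz = odim[2];
  NumericVector out((R_xlen_t)mx * my * mz);
  const double* a = img.begin();
  R_xlen_t v = 0;
  for (int k = 0; k < mz; ++k)
    for (int j = 0; j < my; ++j)
      for (int i = 0; i < mx; ++i, ++v) {
        double fx = (oorigin[0] + i * ospacing[0] - origin[0]) / spacing[0];
        double fy = (oorigin[1] + j * ospacing[1] - origin[1]) / spacing[1];
        double fz = (oorigin[2] + k * ospacing[2] - origin[2]) / spacing[2];
        out[v] = tri_gather(a, nx, ny, nz, fx, fy, fz);
      }
  return out;
}

// Trilinear samples at arbitrary world coordinates.
// [[Rcpp::export]]
NumericVector cpp_sample_world(NumericVector img, IntegerVector dim,
                               NumericVector spacing, NumericVector origin,
                               NumericMatrix coords) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = coords.nrow();
  NumericVector out(n);
  const double* a = img.begin();
  for (int e = 0; e < n; ++e)
    out[e] = tri_gather(a, nx, ny, nz,
                        (coords(e, 0) - origin[0]) / spacing[0],
                        (coords(e, 1) - origin[1]) / spacing[1],
                        (coords(e, 2) - origin[2]) / spacing[2]);
  return out;
}

// 6-connected component labelling of a binary mask.
// [[Rcpp::export]]
IntegerVector cpp_label3d(IntegerVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(ntot);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < ntot; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int i = v % nx, j = (v / nx) % ny, k = v / ((R_xlen_t)nx * ny);
      const int di[6] = {1, -1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, 1, -1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, 1, -1};
      for (int q = 0; q < 6; ++q) {
        int ii = i + di[q], jj = j + dj[q], kk = k + dk[q];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        R_xlen_t w = vidx(ii, jj, kk, nx, ny);
        if (mask[w] && !lab[w]) { lab[w] = next; stack.push_back(w); }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}

// Fill interior holes: background flood-filled from the volume boundary;
// unreached background voxels become foreground.
// [[Rcpp::export]]
IntegerVector cpp_fill_holes(IntegerVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  std::vector<char> outside(ntot, 0);
  std::vector<R_xlen_t> stack;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (i == 0 || j == 0 || k == 0 || i == nx - 1 || j == ny - 1 || k == nz - 1) {
          R_xlen_t v = vidx(i, j, k, nx, ny);
          if (!mask[v] && !outside[v]) { outside[v] = 1; stack.push_back(v); }
        }
      }
  while (!stack.empty()) {
    R_xlen_t v = stack.back(); stack.pop_back();
    int i = v % nx, j = (v / nx) % ny, k = v / ((R_xlen_t)nx * ny);
    const int di[6] = {1, -1, 0, 0, 0, 0};
    const int dj[6] = {0, 0, 1, -1, 0, 0};
    const int dk[6] = {0, 0, 0, 0, 1, -1};
    for (int q = 0; q < 6; ++q) {
      int ii = i + di[q], jj = j + dj[q], kk = k + dk[q];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
        continue;
      R_xlen_t w = vidx(ii, jj, kk, nx, ny);
      if (!mask[w] && !outside[w]) { outside[w] = 1; stack.push_back(w); }
    }
  }
  IntegerVector out(ntot);
  for (R_xlen_t v = 0; v < ntot; ++v) out[v] = (mask[v] || !outside[v]) ? 1 : 0;
  return out;
}
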