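#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// All kernels share one grid convention: voxel indices are 0-based,
// world = origin + index * spacing, data stored column-major (x fastest).

static inline double trilinear_at(const double* d,
                                  const int nx, const int ny, const int nz,
                                  const double ix, const double iy, const double iz,
                                  const double bg, bool* inside) {
  if (ix < 0.0 || iy < 0.0 || iz < 0.0 ||
      ix > nx - 1.0 || iy > ny - 1.0 || iz > nz - 1.0) {
    if (inside) *inside = false;
    return bg;
  }
  if (inside) *inside = true;
  int x0 = (int)std::floor(ix), y0 = (int)std::floor(iy), z0 = (int)std::floor(iz);
  if (x0 == nx - 1) x0--;
  if (y0 == ny - 1) y0--;
  if (z0 == nz - 1) z0--;
  if (x0 < 0) x0 = 0;
  if (y0 < 0) y0 = 0;
  if (z0 < 0) z0 = 0;
  const double fx = ix - x0, fy = iy - y0, fz = iz - z0;
  const R_xlen_t sxy = (R_xlen_t)nx * ny;
  const double* p = d + (R_xlen_t)z0 * sxy + (R_xlen_t)y0 * nx + x0;
  const double c000 = p[0],          c100 = p[1];
  const double c010 = p[nx],         c110 = p[nx + 1];
  const double c001 = p[sxy],        c101 = p[sxy + 1];
  const double c011 = p[sxy + nx],   c111 = p[sxy + nx + 1];
  const double c00 = c000 + fx * (c100 - c000);
  const double c10 = c010 + fx * (c110 - c010);
  const double c01 = c001 + fx * (c101 - c001);
  const double c11 = c011 + fx * (c111 - c011);
  const double c0 = c00 + fy * (c10 - c00);
  const double c1 = c01 + fy * (c11 - c01);
  return c0 + fz * (c1 - c0);
}

// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector data, IntegerVector dim,
                            NumericVector spacing, NumericVector origin,
                            NumericMatrix pts, double background) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double* d = REAL(data);
  const R_xlen_t n = pts.nrow();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double ix = (pts(i, 0) - origin[0]) / spacing[0];
    const double iy = (pts(i, 1) - origin[1]) / spacing[1];
    const double iz = (pts(i, 2) - origin[2]) / spacing[2];
    out[i] = trilinear_at(d, nx, ny, nz, ix, iy, iz, background, nullptr);
  }
  return out;
}

// Index-space affine for the rigid map x_mov = R (x_ref - center) + center
// + t: moving index = A * fixed index + b, precomputed once so the per-
// voxel work is an incremental vector add (no divisions in the hot loop).
struct IdxAffine {
  double a[3][3];
  double b[3];
};

static IdxAffine make_idx_affine(const NumericMatrix& rot,
                                 const NumericVector& trans,
                                 const NumericVector& center,
                                 const NumericVector& fspacing,
                                 const NumericVector& forigin,
                                 const NumericVector& mspacing,
                                 const NumericVector& morigin) {
  IdxAffine A;
  for (int r = 0; r < 3; ++r) {
    double off = 0.0;
    for (int c = 0; c < 3; ++c) {
      A.a[r][c] = rot(r, c) * fspacing[c] / mspacing[r];
      off += rot(r, c) * (forigin[c] - center[c]);
    }
    A.b[r] = (off + center[r] + trans[r] - morigin[r]) / mspacing[r];
  }
  return A;
}

// Resample `moving` on the grid of a reference volume through a rigid map
// x_mov = R (x_ref - center) + center + t (all world mm).
// [[Rcpp::export]]
NumericVector cpp_resample_rigid(NumericVector mdata, IntegerVector mdim,
                                 NumericVector mspacing, NumericVector morigin,
                                 IntegerVector rdim, NumericVector rspacing,
                                 NumericVector rorigin, NumericMatrix rot,
                                 NumericVector trans, NumericVector center,
                                 double background) {
  const int nx = rdim[0], ny = rdim[1], nz = rdim[2];
  const int mx = mdim[0], my = mdim[1], mz = mdim[2];
  const double* d = REAL(mdata);
  NumericVector out((R_xlen_t)nx * ny * nz);
  double* o = REAL(out);
  const IdxAffine A = make_idx_affine(rot, trans, center, rspacing, rorigin,
                                      mspacing, morigin);
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      double ix = A.a[0][1] * j + A.a[0][2] * k + A.b[0];
      double iy = A.a[1][1] * j + A.a[1][2] * k + A.b[1];
      double iz = A.a[2][1] * j + A.a[2][2] * k + A.b[2];
      for (int i = 0; i < nx; ++i, ++idx,
           ix += A.a[0][0], iy += A.a[1][0], iz += A.a[2][0]) {
        o[idx] = trilinear_at(d, mx, my, mz, ix, iy, iz, background, nullptr);
      }
    }
  return out;
}

// Mean squared error between `fixed` and `moving` mapped through the rigid
// transform, over fixed voxels (subsampled by `stride`) whose mapped
// position falls inside the moving volume.  Returns c(mse, n_overlap).
// [[Rcpp::export]]
NumericVector cpp_rigid_mse(NumericVector fdata, IntegerVector fdim,
                            NumericVector fspacing, NumericVector forigin,
                            NumericVector mdata, IntegerVector mdim,
                            NumericVector mspacing, NumericVector morigin,
                            NumericMatrix rot, NumericVector trans,
                            NumericVector center, int stride) {
  const int nx = fdim[0], ny = fdim[1], nz = fdim[2];
  const int mx = mdim[0], my = mdim[1], mz = mdim[2];
  const double* fd = REAL(fdata);
  const double* md = REAL(mdata);
  const IdxAffine A = make_idx_affine(rot, trans, center, fspacing, forigin,
                                      mspacing, morigin);
  double acc = 0.0;
  R_xlen_t n = 0;
  const R_xlen_t sxy = (R_xlen_t)nx * ny;
  for (int k = 0; k < nz; k += stride)
    for (int j = 0; j < ny; j += stride) {
      const R_xlen_t row = (R_xlen_t)k * sxy + (R_xlen_t)j * nx;
      double ix = A.a[0][1] * j + A.a[0][2] * k + A.b[0];
      double iy = A.a[1][1] * j + A.a[1][2] * k + A.b[1];
      double iz = A.a[2][1] * j + A.a[2][2] * k + A.b[2];
      const double sx = A.a[0][0] * stride, sy = A.a[1][0] * stride,
                   sz = A.a[2][0] * stride;
      for (int i = 0; i < nx; i += stride, ix += sx, iy += sy, iz += sz) {
        bool inside = false;
        const double v = trilinear_at(md, mx, my, mz, ix, iy, iz, 0.0, &inside);
        if (inside) {
          const double diff = fd[row + i] - v;
          acc += diff * diff;
          ++n;
        }
      }
    }
  return NumericVector::create(n > 0 ? acc / n : R_PosInf, (double)n);
}

// Separable convolution with the same 1-D kernel along all three axes.
// Replicate (nearest) boundary handling so constant volumes are preserved.
static void conv_axis(const std::vector<double>& in, std::vector<double>& out,
                      const int nx, const int ny, const int nz,
                      const NumericVector& kernel, const int axis) {
  const int kn = kernel.size();
  const int kh = kn / 2;
  const R_xlen_t sxy = (R_xlen_t)nx * ny;
  const int n_axis = axis == 0 ? nx : (axis == 1 ? ny : nz);
  const R_xlen_t step = axis == 0 ? 1 : (axis == 1 ? nx : sxy);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const int pos = axis == 0 ? i : (axis == 1 ? j : k);
        const R_xlen_t base = (R_xlen_t)k * sxy + (R_xlen_t)j * nx + i;
        double acc = 0.0;
        for (int t = 0; t < kn; ++t) {
          int p = pos + t - kh;
          if (p < 0) p = 0;
          if (p >= n_axis) p = n_axis - 1;
          acc += kernel[t] * in[base + (R_xlen_t)(p - pos) * step];
        }
        out[base] = acc;
      }
}

// [[Rcpp::export]]
NumericVector cpp_separable_blur(NumericVector data, IntegerVector dim,
                                 NumericVector kernel) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> a(REAL(data), REAL(data) + n), b(n);
  conv_axis(a, b, nx, ny, nz, kernel, 0);
  conv_axis(b, a, nx, ny, nz, kernel, 1);
  conv_axis(a, b, nx, ny, nz, kernel, 2);
  NumericVector out(n);
  std::copy(b.begin(), b.end(), REAL(out));
  return out;
}

// Convolution with a 1-D kernel along a single axis (0, 1, or 2).
// [[Rcpp::export]]
NumericVector cpp_blur_axis(NumericVector data, IntegerVector dim,
                            NumericVector kernel, int axis) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> a(REAL(data), REAL(data) + n), b(n);
  conv_axis(a, b, nx, ny, nz, kernel, axis);
  NumericVector out(n);
  std::copy(b.begin(), b.end(), REAL(out));
  return out;
}

// Block-mean downsampling by a factor of 2 along each axis (partial edge
// blocks average whatever voxels they cover).
// [[Rcpp::export]]
NumericVector cpp_downsample2(NumericVector data, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int ox = (nx + 1) / 2, oy = (ny + 1) / 2, oz = (nz + 1) / 2;
  const double* d = REAL(data);
  NumericVector out((R_xlen_t)ox * oy * oz);
  double* o = REAL(out);
  const R_xlen_t sxy = (R_xlen_t)nx * ny;
  R_xlen_t idx = 0;
  for (int k = 0; k < oz; ++k)
    for (int j = 0; j < oy; ++j)
      for (int i = 0; i < ox; ++i, ++idx) {
        double acc = 0.0;
        int cnt = 0;
        for (int dz = 0; dz < 2; ++dz) {
          const int z = 2 * k + dz;
          if (z >= nz) continue;
          for (int dy = 0; dy < 2; ++dy) {
            const int y = 2 * j + dy;
            if (y >= ny) continue;
            for (int dx = 0; dx < 2; ++dx) {
              const int x = 2 * i + dx;
              if (x >= nx) continue;
              acc += d[(R_xlen_t)z * sxy + (R_xlen_t)y * nx + x];
              ++cnt;
            }
          }
        }
        o[idx] = acc / cnt;
      }
  return out;
}

// 6-connected component labelling of a binary mask.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const int* m = LOGICAL(mask);
  IntegerVector lab(n, 0);
  int* l = INTEGER(lab);
  const R_xlen_t sxy = (R_xlen_t)nx * ny;
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!m[s] || l[s]) continue;
    l[s] = ++next;
    q.push(s);
    while (!q.empty()) {
      const R_xlen_t c = q.front();
      q.pop();
      const int z = (int)(c / sxy);
      const int y = (int)((c - (R_xlen_t)z * sxy) / nx);
      const int x = (int)(c - (R_xlen_t)z * sxy - (R_xlen_t)y * nx);
      const int dx[6] = {-1, 1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, -1, 1, 0, 0};
      const int dz[6] = {0, 0, 0, 0, -1, 1};
      for (int t = 0; t < 6; ++t) {
        const int xx = x + dx[t], yy = y + dy[t], zz = z + dz[t];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
          continue;
        const R_xlen_t cc = (R_xlen_t)zz * sxy + (R_xlen_t)yy * nx + xx;
        if (m[cc] && !l[cc]) {
          l[cc] = next;
          q.push(cc);
        }
      }
    }
  }
  return lab;
}
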