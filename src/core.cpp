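#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Index convention throughout: 0-based voxel indices; world position of
// voxel (i,j,k) is origin + spacing * (i,j,k). Point matrices are 3 x N.

static inline int reflect_index(int i, int n) {
  // mirror boundary (no repeated edge sample beyond single reflection cycle)
  if (n == 1) return 0;
  int period = 2 * n - 2;
  i = ((i % period) + period) % period;
  return (i < n) ? i : period - i;
}

// Trilinear / nearest sampling of a 3D volume at 0-based continuous voxel
// coordinates. Points with any coordinate outside [0, dim-1] return
// `background`. mode: 0 = trilinear, 1 = nearest.
// [[Rcpp::export]]
NumericVector cpp_sample_volume(NumericVector data, IntegerVector dim,
                                NumericMatrix pts, int mode,
                                double background) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = pts.ncol();
  NumericVector out(n);
  const double *d = data.begin();
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  for (R_xlen_t p = 0; p < n; ++p) {
    double x = pts(0, p), y = pts(1, p), z = pts(2, p);
    if (!(x >= 0.0 && x <= nx - 1.0 && y >= 0.0 && y <= ny - 1.0 &&
          z >= 0.0 && z <= nz - 1.0)) {
      out[p] = background;
      continue;
    }
    if (mode == 1) {
      int ix = (int)std::lround(x), iy = (int)std::lround(y),
          iz = (int)std::lround(z);
      out[p] = d[ix * sx + iy * sy + iz * sz];
    } else {
      int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
          z0 = (int)std::floor(z);
      if (x0 == nx - 1) x0--;
      if (y0 == ny - 1) y0--;
      if (z0 == nz - 1) z0--;
      if (x0 < 0) x0 = 0;
      if (y0 < 0) y0 = 0;
      if (z0 < 0) z0 = 0;
      double fx = x - x0, fy = y - y0, fz = z - z0;
      const double *base = d + x0 * sx + y0 * sy + z0 * sz;
      double c00 = base[0] * (1 - fx) + base[sx] * fx;
      double c10 = base[sy] * (1 - fx) + base[sy + sx] * fx;
      double c01 = base[sz] * (1 - fx) + base[sz + sx] * fx;
      double c11 = base[sz + sy] * (1 - fx) + base[sz + sy + sx] * fx;
      double c0 = c00 * (1 - fy) + c10 * fy;
      double c1 = c01 * (1 - fy) + c11 * fy;
      out[p] = c0 * (1 - fz) + c1 * fz;
    }
  }
  return out;
}

// Separable Gaussian blur with per-axis sigma in voxels; mirror boundary;
// output dimensions identical to the input (no down-sampling anywhere).
// [[Rcpp::export]]
NumericVector cpp_gaussian_blur(NumericVector data, IntegerVector dim,
                                NumericVector sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector cur = clone(data);
  NumericVector tmp(data.size());
  const int n_ax[3] = {nx, ny, nz};
  const R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.5 * s);
    std::vector<double> k(2 * r + 1);
    double ksum = 0.0;
    for (int i = -r; i <= r; ++i) {
      k[i + r] = std::exp(-0.5 * (double)i * i / (s * s));
      ksum += k[i + r];
    }
    for (double &w : k) w /= ksum;
    const int n = n_ax[ax];
    const R_xlen_t st = stride[ax];
    // iterate over all lines along axis `ax`
    const int na = n_ax[(ax + 1) % 3], nb = n_ax[(ax + 2) % 3];
    const R_xlen_t sa = stride[(ax + 1) % 3], sb = stride[(ax + 2) % 3];
    for (int b = 0; b < nb; ++b) {
      for (int a = 0; a < na; ++a) {
        const R_xlen_t off = a * sa + b * sb;
        for (int i = 0; i < n; ++i) {
          double acc = 0.0;
          for (int j = -r; j <= r; ++j) {
            int ii = reflect_index(i + j, n);
            acc += k[j + r] * cur[off + ii * st];
          }
          tmp[off + i * st] = acc;
        }
      }
    }
    std::swap(cur, tmp);
  }
  return cur;
}

// Central-difference intensity gradient in 1/mm units (one-sided at edges).
// Returns a vector of length 3*n: axis a occupies [a*n, (a+1)*n).
// [[Rcpp::export]]
NumericVector cpp_image_gradient(NumericVector data, IntegerVector dim,
                                 NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(3 * n);
  const double *d = data.begin();
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  const R_xlen_t strides[3] = {sx, sy, sz};
  const int dims[3] = {nx, ny, nz};
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix) {
        R_xlen_t idx = ix * sx + iy * sy + iz * sz;
        int pos[3] = {ix, iy, iz};
        for (int ax = 0; ax < 3; ++ax) {
          int i = pos[ax], nn = dims[ax];
          R_xlen_t st = strides[ax];
          double g;
          if (nn == 1)
            g = 0.0;
          else if (i == 0)
            g = (d[idx + st] - d[idx]) / spacing[ax];
          else if (i == nn - 1)
            g = (d[idx] - d[idx - st]) / spacing[ax];
          else
            g = (d[idx + st] - d[idx - st]) / (2.0 * spacing[ax]);
          out[ax * n + idx] = g;
        }
      }
  return out;
}

static inline void bspline_weights(double t, double *w) {
  double t2 = t * t, t3 = t2 * t;
  w[0] = (1 - 3 * t + 3 * t2 - t3) / 6.0;
  w[1] = (4 - 6 * t2 + 3 * t3) / 6.0;
  w[2] = (1 + 3 * t + 3 * t2 - 3 * t3) / 6.0;
  w[3] = t3 / 6.0;
}

// Evaluate a cubic B-spline free-form deformation displacement (mm) at world
// points. coef is an (n1*n2*n3*3) vector (dimension-major, displacement axis
// last); grid node (i,j,k) sits at origin + spacing*(i,j,k) (0-based).
// Points are clamped into the valid support so boundary evaluation
// extrapolates the edge cells.
// [[Rcpp::export]]
NumericMatrix cpp_bspline_disp(NumericVector coef, IntegerVector ncp,
                               NumericVector origin, NumericVector spacing,
                               NumericMatrix pts) {
  const int n1 = ncp[0], n2 = ncp[1], n3 = ncp[2];
  const R_xlen_t npt = pts.ncol();
  const R_xlen_t ncp_tot = (R_xlen_t)n1 * n2 * n3;
  NumericMatrix out(3, npt);
  const double *c = coef.begin();
  for (R_xlen_t p = 0; p < npt; ++p) {
    int l[3];
    double w[3][4];
    const int nn[3] = {n1, n2, n3};
    for (int ax = 0; ax < 3; ++ax) {
      double uu = (pts(ax, p) - origin[ax]) / spacing[ax];
      double lo = 1.0, hi = nn[ax] - 3.0;  // floor(u) must lie in [1, n-3]
      if (uu < lo) uu = lo;
      if (uu > hi - 1e-9) uu = hi - 1e-9;
      int ll = (int)std::floor(uu);
      if (ll > nn[ax] - 3) ll = nn[ax] - 3;
      l[ax] = ll;
      bspline_weights(uu - ll, w[ax]);
    }
    double acc[3] = {0.0, 0.0, 0.0};
    for (int ck = 0; ck < 4; ++ck) {
      int k = l[2] - 1 + ck;
      for (int cj = 0; cj < 4; ++cj) {
        int j = l[1] - 1 + cj;
        double wjk = w[1][cj] * w[2][ck];
        R_xlen_t base = ((R_xlen_t)k * n2 + j) * n1;
        for (int ci = 0; ci < 4; ++ci) {
          int i = l[0] - 1 + ci;
          double ww = w[0][ci] * wjk;
          R_xlen_t idx = base + i;
          acc[0] += ww * c[idx];
          acc[1] += ww * c[idx + ncp_tot];
          acc[2] += ww * c[idx + 2 * ncp_tot];
        }
      }
    }
    out(0, p) = acc[0];
    out(1, p) = acc[1];
    out(2, p) = acc[2];
  }
  return out;
}

// Accumulate d(metric)/d(coefficients) for a B-spline stage:
//   grad[i,j,k,d] = sum_n dmdm[n] * gmov[d,n] * w_n(i,j,k)
// where dmdm[n] = d(metric)/d(moving intensity at sample n) and gmov is the
// moving-image spatial gradient (1/mm) sampled at the mapped points.
// [[Rcpp::export]]
NumericVector cpp_bspline_grad(IntegerVector ncp, NumericVector origin,
                               NumericVector spacing, NumericMatrix pts,
                               NumericVector dmdm, NumericMatrix gmov) {
  const int n1 = ncp[0], n2 = ncp[1], n3 = ncp[2];
  const R_xlen_t npt = pts.ncol();
  const R_xlen_t ncp_tot = (R_xlen_t)n1 * n2 * n3;
  NumericVector grad(3 * ncp_tot);
  for (R_xlen_t p = 0; p < npt; ++p) {
    int l[3];
    double w[3][4];
    const int nn[3] = {n1, n2, n3};
    for (int ax = 0; ax < 3; ++ax) {
      double uu = (pts(ax, p) - origin[ax]) / spacing[ax];
      double lo = 1.0, hi = nn[ax] - 3.0;
      if (uu < lo) uu = lo;
      if (uu > hi - 1e-9) uu = hi - 1e-9;
      int ll = (int)std::floor(uu);
      if (ll > nn[ax] - 3) ll = nn[ax] - 3;
      l[ax] = ll;
      bspline_weights(uu - ll, w[ax]);
    }
    double f0 = dmdm[p] * gmov(0, p);
    double f1 = dmdm[p] * gmov(1, p);
    double f2 = dmdm[p] * gmov(2, p);
    for (int ck = 0; ck < 4; ++ck) {
      int k = l[2] - 1 + ck;
      for (int cj = 0; cj < 4; ++cj) {
        int j = l[1] - 1 + cj;
        double wjk = w[1][cj] * w[2][ck];
        R_xlen_t base = ((R_xlen_t)k * n2 + j) * n1;
        for (int ci = 0; ci < 4; ++ci) {
          double ww = w[0][ci] * wjk;
          R_xlen_t idx = base + l[0] - 1 + ci;
          grad[idx] += ww * f0;
          grad[idx + ncp_tot] += ww * f1;
          grad[idx + 2 * ncp_tot] += ww * f2;
        }
      }
    }
  }
  return grad;
}

// Trilinear interpolation of a dense displacement field (mm) stored as an
// (nx*ny*nz*3) vector on a grid with given origin/spacing; points outside
// the grid are clamped to the border.
// [[Rcpp::export]]
NumericMatrix cpp_field_interp(NumericVector field, IntegerVector dim,
                               NumericVector origin, NumericVector spacing,
                               NumericMatrix pts) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const R_xlen_t npt = pts.ncol();
  NumericMatrix out(3, npt);
  const double *f = field.begin();
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  for (R_xlen_t p = 0; p < npt; ++p) {
    double x = (pts(0, p) - origin[0]) / spacing[0];
    double y = (pts(1, p) - origin[1]) / spacing[1];
    double z = (pts(2, p) - origin[2]) / spacing[2];
    if (x < 0) x = 0;
    if (y < 0) y = 0;
    if (z < 0) z = 0;
    if (x > nx - 1) x = nx - 1;
    if (y > ny - 1) y = ny - 1;
    if (z > nz - 1) z = nz - 1;
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
        z0 = (int)std::floor(z);
    if (x0 == nx - 1 && nx > 1) x0--;
    if (y0 == ny - 1 && ny > 1) y0--;
    if (z0 == nz - 1 && nz > 1) z0--;
    double fx = x - x0, fy = y - y0, fz = z - z0;
    R_xlen_t b = x0 * sx + y0 * sy + z0 * sz;
    R_xlen_t dx = (nx > 1) ? sx : 0, dy = (ny > 1) ? sy : 0,
             dz = (nz > 1) ? sz : 0;
    for (int ax = 0; ax < 3; ++ax) {
      const double *g = f + ax * n;
      double c00 = g[b] * (1 - fx) + g[b + dx] * fx;
      double c10 = g[b + dy] * (1 - fx) + g[b + dy + dx] * fx;
      double c01 = g[b + dz] * (1 - fx) + g[b + dz + dx] * fx;
      double c11 = g[b + dz + dy] * (1 - fx) + g[b + dz + dy + dx] * fx;
      double c0 = c00 * (1 - fy) + c10 * fy;
      double c1 = c01 * (1 - fy) + c11 * fy;
      out(ax, p) = c0 * (1 - fz) + c1 * fz;
    }
  }
  return out;
}

// 3D median filter with an odd cubic window (mirror boundary).
// [[Rcpp::export]]
NumericVector cpp_median3d(NumericVector data, IntegerVector dim,
                           int kernel) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int r = kernel / 2;
  NumericVector out(data.size());
  const double *d = data.begin();
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  std::vector<double> buf(kernel * kernel * kernel);
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix) {
        int m = 0;
        for (int dz = -r; dz <= r; ++dz) {
          int z = reflect_index(iz + dz, nz);
          for (int dy = -r; dy <= r; ++dy) {
            int y = reflect_index(iy + dy, ny);
            for (int dx = -r; dx <= r; ++dx) {
              int x = reflect_index(ix + dx, nx);
              buf[m++] = d[x * sx + y * sy + z * sz];
            }
          }
        }
        std::nth_element(buf.begin(), buf.begin() + m / 2, buf.begin() + m);
        out[ix * sx + iy * sy + iz * sz] = buf[m / 2];
      }
  return out;
}
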