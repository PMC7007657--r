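#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double BIG = 1e20;

// 1D squared-distance transform (lower envelope of parabolas) with sample
// spacing s, after Felzenszwalb & Huttenlocher. f holds initial squared
// costs (0 at seeds, BIG elsewhere); d receives the transformed costs.
static void dt1d(const double* f, double* d, int n, double s,
                 std::vector<int>& v, std::vector<double>& z) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double xq = q * s;
    double xv = v[k] * s;
    double sint = (f[q] + xq * xq - f[v[k]] - xv * xv) / (2.0 * xq - 2.0 * xv);
    while (sint <= z[k]) {
      --k;
      xv = v[k] * s;
      sint = (f[q] + xq * xq - f[v[k]] - xv * xv) / (2.0 * xq - 2.0 * xv);
    }
    ++k;
    v[k] = q;
    z[k] = sint;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * s;
    while (z[k + 1] < xq) ++k;
    double xv = v[k] * s;
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
  }
}

// Exact squared Euclidean distance (mm^2) from every voxel center to the
// nearest seed voxel center, honouring anisotropic spacing.
// [[Rcpp::export]]
NumericVector edt_sq_cpp(LogicalVector seed, IntegerVector dim,
                         NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (seed.size() != n) stop("seed length does not match dim");
  NumericVector out(n);
  double* d = REAL(out);
  for (R_xlen_t i = 0; i < n; ++i) d[i] = seed[i] ? 0.0 : BIG;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), tmp(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // axis 0 (fastest varying)
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      double* row = d + (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
      for (int i = 0; i < nx; ++i) f[i] = row[i];
      dt1d(f.data(), tmp.data(), nx, spacing[0], v, z);
      for (int i = 0; i < nx; ++i) row[i] = tmp[i];
    }
  // axis 1
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      double* base = d + (R_xlen_t)k * nx * ny + i;
      for (int j = 0; j < ny; ++j) f[j] = base[(R_xlen_t)j * nx];
      dt1d(f.data(), tmp.data(), ny, spacing[1], v, z);
      for (int j = 0; j < ny; ++j) base[(R_xlen_t)j * nx] = tmp[j];
    }
  // axis 2
  R_xlen_t stride = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      double* base = d + (R_xlen_t)j * nx + i;
      for (int k = 0; k < nz; ++k) f[k] = base[(R_xlen_t)k * stride];
      dt1d(f.data(), tmp.data(), nz, spacing[2], v, z);
      for (int k = 0; k < nz; ++k) base[(R_xlen_t)k * stride] = tmp[k];
    }
  return out;
}

// Connected components under 6-connectivity (face neighbours).
// Returns integer labels, 0 for background, 1..n_components for foreground.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector occ, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (occ.size() != n) stop("occ length does not match dim");
  IntegerVector lab(n, 0);
  int cur = 0;
  std::vector<R_xlen_t> stack;
  R_xlen_t sxy = (R_xlen_t)nx * ny;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!occ[s] || lab[s] != 0) continue;
    ++cur;
    stack.push_back(s);
    lab[s] = cur;
    while (!stack.empty()) {
      R_xlen_t p = stack.back();
      stack.pop_back();
      int i = (int)(p % nx);
      int j = (int)((p / nx) % ny);
      int k = (int)(p / sxy);
      const int di[6] = {-1, 1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, -1, 1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, -1, 1};
      for (int m = 0; m < 6; ++m) {
        int ii = i + di[m], jj = j + dj[m], kk = k + dk[m];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        R_xlen_t q = ii + (R_xlen_t)jj * nx + (R_xlen_t)kk * sxy;
        if (occ[q] && lab[q] == 0) {
          lab[q] = cur;
          stack.push_back(q);
        }
      }
    }
  }
  lab.attr("n_components") = cur;
  return lab;
}

static void smooth_axis(double* d, int nx, int ny, int nz, int axis,
                        double sigma) {
  if (sigma <= 0) return;
  int radius = (int)std::ceil(3.0 * sigma);
  std::vector<double> kern(2 * radius + 1);
  for (int t = -radius; t <= radius; ++t)
    kern[t + radius] = std::exp(-0.5 * t * t / (sigma * sigma));
  int len = axis == 0 ? nx : (axis == 1 ? ny : nz);
  R_xlen_t stride = axis == 0 ? 1 : (axis == 1 ? (R_xlen_t)nx
                                               : (R_xlen_t)nx * ny);
  std::vector<double> buf(len);
  int n1 = axis == 0 ? ny : nx;
  int n2 = axis == 2 ? ny : nz;
  for (int b = 0; b < n2; ++b)
    for (int a = 0; a < n1; ++a) {
      R_xlen_t base;
      if (axis == 0)
        base = (R_xlen_t)a * nx + (R_xlen_t)b * nx * ny;
      else if (axis == 1)
        base = a + (R_xlen_t)b * nx * ny;
      else
        base = a + (R_xlen_t)b * nx;
      for (int q = 0; q < len; ++q) buf[q] = d[base + q * stride];
      for (int q = 0; q < len; ++q) {
        double acc = 0.0, wsum = 0.0;
        int lo = std::max(0, q - radius), hi = std::min(len - 1, q + radius);
        for (int t = lo; t <= hi; ++t) {
          double w = kern[t - q + radius];
          acc += w * buf[t];
          wsum += w;
        }
        d[base + q * stride] = acc / wsum;
      }
    }
}

// Separable Gaussian smoothing with per-axis sigma given in voxels; kernel
// renormalised near the volume boundary.
// [[Rcpp::export]]
NumericVector smooth_gaussian_cpp(NumericVector x, IntegerVector dim,
                                  NumericVector sigma_vox) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  if (x.size() != (R_xlen_t)nx * ny * nz) stop("x length does not match dim");
  NumericVector out = clone(x);
  smooth_axis(REAL(out), nx, ny, nz, 0, sigma_vox[0]);
  smooth_axis(REAL(out), nx, ny, nz, 1, sigma_vox[1]);
  smooth_axis(REAL(out), nx, ny, nz, 2, sigma_vox[2]);
  return out;
}

// Trilinear upsampling of a coarse grid onto a fine grid covering the same
// physical extent (both grids share the origin; coarse index c maps to fine
// index f via c = f * (cdim-1)/(fdim-1), degenerate axes held constant).
// [[Rcpp::export]]
NumericVector upsample_trilinear_cpp(NumericVector coarse, IntegerVector cdim,
                                     IntegerVector fdim) {
  int cx = cdim[0], cy = cdim[1], cz = cdim[2];
  int fx = fdim[0], fy = fdim[1], fz = fdim[2];
  if (coarse.size() != (R_xlen_t)cx * cy * cz)
    stop("coarse length does not match cdim");
  NumericVector out((R_xlen_t)fx * fy * fz);
  const double* c = REAL(coarse);
  double* o = REAL(out);
  double stepx = fx > 1 ? (double)(cx - 1) / (fx - 1) : 0.0;
  double stepy = fy > 1 ? (double)(cy - 1) / (fy - 1) : 0.0;
  double stepz = fz > 1 ? (double)(cz - 1) / (fz - 1) : 0.0;
  R_xlen_t cxy = (R_xlen_t)cx * cy;
  R_xlen_t idx = 0;
  for (int k = 0; k < fz; ++k) {
    double zc = k * stepz;
    int k0 = (int)zc;
    if (k0 > cz - 2) k0 = std::max(0, cz - 2);
    double wz = cz > 1 ? zc - k0 : 0.0;
    for (int j = 0; j < fy; ++j) {
      double yc = j * stepy;
      int j0 = (int)yc;
      if (j0 > cy - 2) j0 = std::max(0, cy - 2);
      double wy = cy > 1 ? yc - j0 : 0.0;
      for (int i = 0; i < fx; ++i, ++idx) {
        double xc = i * stepx;
        int i0 = (int)xc;
        if (i0 > cx - 2) i0 = std::max(0, cx - 2);
        double wx = cx > 1 ? xc - i0 : 0.0;
        R_xlen_t b = i0 + (R_xlen_t)j0 * cx + (R_xlen_t)k0 * cxy;
        int sx = cx > 1 ? 1 : 0;
        R_xlen_t sy = cy > 1 ? cx : 0;
        R_xlen_t sz = cz > 1 ? cxy : 0;
        double v000 = c[b], v100 = c[b + sx];
        double v010 = c[b + sy], v110 = c[b + sy + sx];
        double v001 = c[b + sz], v101 = c[b + sz + sx];
        double v011 = c[b + sz + sy], v111 = c[b + sz + sy + sx];
        double v00 = v000 + wx * (v100 - v000);
        double v10 = v010 + wx * (v110 - v010);
        double v01 = v001 + wx * (v101 - v001);
        double v11 = v011 + wx * (v111 - v011);
        double v0 = v00 + wy * (v10 - v00);
        double v1 = v01 + wy * (v11 - v01);
        o[idx] = v0 + wz * (v1 - v0);
      }
    }
  }
  return out;
}

// Backward nearest-neighbour source indices for warping: for each output
// voxel, the 1-based linear index of the input voxel it samples under
// displacement (ux,uy,uz) in mm, or NA if the source falls outside the grid.
// [[Rcpp::export]]
IntegerVector warp_source_index_cpp(IntegerVector dim, NumericVector spacing,
                                    NumericVector ux, NumericVector uy,
                                    NumericVector uz) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (ux.size() != n || uy.size() != n || uz.size() != n)
    stop("displacement length does not match dim");
  IntegerVector out(n);
  R_xlen_t sxy = (R_xlen_t)nx * ny;
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        int si = i - (int)std::lround(ux[idx] / spacing[0]);
        int sj = j - (int)std::lround(uy[idx] / spacing[1]);
        int sk = k - (int)std::lround(uz[idx] / spacing[2]);
        if (si < 0 || sj < 0 || sk < 0 || si >= nx || sj >= ny || sk >= nz)
          out[idx] = NA_INTEGER;
        else
          out[idx] = (int)(si + (R_xlen_t)sj * nx + (R_xlen_t)sk * sxy) + 1;
      }
  return out;
}

// Surface voxels: occupied with at least one face-adjacent unoccupied or
// out-of-bounds neighbour (image boundary counts as background).
// [[Rcpp::export]]
LogicalVector surface_mask_cpp(LogicalVector occ, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (occ.size() != n) stop("occ length does not match dim");
  LogicalVector out(n);
  R_xlen_t sxy = (R_xlen_t)nx * ny;
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        if (!occ[idx]) { out[idx] = FALSE; continue; }
        bool surf =
          i == 0 || i == nx - 1 || j == 0 || j == ny - 1 ||
          k == 0 || k == nz - 1 ||
          !occ[idx - 1] || !occ[idx + 1] ||
          !occ[idx - nx] || !occ[idx + nx] ||
          !occ[idx - sxy] || !occ[idx + sxy];
        out[idx] = surf;
      }
  return out;
}

// Euler characteristic V - E + F - C of the cubical complex spanned by the
// occupied voxels. Each cell class lives on its own staggered lattice; a
// cell is present if any voxel incident to it is occupied.
// [[Rcpp::export]]
int euler_char_cpp(LogicalVector occ, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (occ.size() != n) stop("occ length does not match dim");
  R_xlen_t sxy = (R_xlen_t)nx * ny;
  auto at = [&](int i, int j, int k) -> bool {
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz)
      return false;
    return occ[i + (R_xlen_t)j * nx + (R_xlen_t)k * sxy];
  };
  long long v = 0, e = 0, f = 0, c = 0;
  // vertices at lattice points (i,j,k) with i in 0..nx etc.; incident
  // voxels are the up to 8 with index offsets in {-1,0} per axis
  for (int k = 0; k <= nz; ++k)
    for (int j = 0; j <= ny; ++j)
      for (int i = 0; i <= nx; ++i) {
        bool hit = false;
        for (int dk = -1; dk <= 0 && !hit; ++dk)
          for (int dj = -1; dj <= 0 && !hit; ++dj)
            for (int di = -1; di <= 0 && !hit; ++di)
              hit = at(i + di, j + dj, k + dk);
        if (hit) ++v;
      }
  // edges along axis a: zero extent on the two other axes
  for (int axis = 0; axis < 3; ++axis) {
    int mx = nx + (axis == 0 ? 0 : 1);
    int my = ny + (axis == 1 ? 0 : 1);
    int mz = nz + (axis == 2 ? 0 : 1);
    for (int k = 0; k < mz; ++k)
      for (int j = 0; j < my; ++j)
        for (int i = 0; i < mx; ++i) {
          bool hit = false;
          for (int dk = (axis == 2 ? 0 : -1); dk <= 0 && !hit; ++dk)
            for (int dj = (axis == 1 ? 0 : -1); dj <= 0 && !hit; ++dj)
              for (int di = (axis == 0 ? 0 : -1); di <= 0 && !hit; ++di)
                hit = at(i + di, j + dj, k + dk);
          if (hit) ++e;
        }
  }
  // faces normal to axis a: zero extent on axis a only
  for (int axis = 0; axis < 3; ++axis) {
    int mx = nx + (axis == 0 ? 1 : 0);
    int my = ny + (axis == 1 ? 1 : 0);
    int mz = nz + (axis == 2 ? 1 : 0);
    for (int k = 0; k < mz; ++k)
      for (int j = 0; j < my; ++j)
        for (int i = 0; i < mx; ++i) {
          bool hit = false;
          for (int dk = (axis == 2 ? -1 : 0); dk <= 0 && !hit; ++dk)
            for (int dj = (axis == 1 ? -1 : 0); dj <= 0 && !hit; ++dj)
              for (int di = (axis == 0 ? -1 : 0); di <= 0 && !hit; ++di)
                hit = at(i + di, j + dj, k + dk);
          if (hit) ++f;
        }
  }
  for (R_xlen_t s = 0; s < n; ++s) if (occ[s]) ++c;
  long long chi = v - e + f - c;
  return (int)chi;
}

// Backward NN source indices for a field composed of a shared 3D residual
// (ux,uy,uz) plus a separable per-axis compensation (ax along x, ay along
// y, az along z), all in mm. Avoids materialising the composed field.
// [[Rcpp::export]]
IntegerVector warp_source_index_sep_cpp(IntegerVector dim,
                                        NumericVector spacing,
                                        NumericVector ux, NumericVector uy,
                                        NumericVector uz, NumericVector ax,
                                        NumericVector ay, NumericVector az) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (ux.size() != n || uy.size() != n || uz.size() != n)
    stop("displacement length does not match dim");
  if (ax.size() != nx || ay.size() != ny || az.size() != nz)
    stop("separable component length does not match dim");
  IntegerVector out(n);
  R_xlen_t sxy = (R_xlen_t)nx * ny;
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        int si = i - (int)std::lround((ux[idx] + ax[i]) / spacing[0]);
        int sj = j - (int)std::lround((uy[idx] + ay[j]) / spacing[1]);
        int sk = k - (int)std::lround((uz[idx] + az[k]) / spacing[2]);
        if (si < 0 || sj < 0 || sk < 0 || si >= nx || sj >= ny || sk >= nz)
          out[idx] = NA_INTEGER;
        else
          out[idx] = (int)(si + (R_xlen_t)sj * nx + (R_xlen_t)sk * sxy) + 1;
      }
  return out;
}
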