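#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// One-dimensional squared-distance transform (lower envelope of parabolas,
// Felzenszwalb & Huttenlocher), with sample spacing encoded through the
// squared axis weight w2 so anisotropic voxel grids are handled exactly.
static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z, int n,
                 double w2) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    int p = v[k];
    double s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) /
               (2.0 * w2 * (q - p));
    while (s <= z[k]) {
      --k;
      p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) /
          (2.0 * w2 * (q - p));
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    int p = v[k];
    d[q] = w2 * (double)(q - p) * (q - p) + f[p];
  }
}

// Squared Euclidean distance (mm^2) from every voxel to the nearest voxel
// outside the mask, respecting anisotropic spacing. Background voxels get 0.
// Voxels outside the grid are NOT treated as background.
// [[Rcpp::export]]
NumericVector edt_sq_cpp(LogicalVector mask, IntegerVector dim,
                         NumericVector spacing) {
  const double BIG = 1e20;
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? BIG : 0.0;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  double w2 = spacing[0] * spacing[0];
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; ++i) f[i] = out[base + i];
      dt1d(f, d, v, z, nx, w2);
      for (int i = 0; i < nx; ++i) out[base + i] = d[i];
    }
  }
  // pass along y
  w2 = spacing[1] * spacing[1];
  for (int k = 0; k < nz; ++k) {
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * ny * k;
      for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)nx * j];
      dt1d(f, d, v, z, ny, w2);
      for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)nx * j] = d[j];
    }
  }
  // pass along z
  w2 = spacing[2] * spacing[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * j;
      for (int k = 0; k < nz; ++k) f[k] = out[base + nxy * k];
      dt1d(f, d, v, z, nz, w2);
      for (int k = 0; k < nz; ++k) out[base + nxy * k] = d[k];
    }
  }
  // clamp: any voxel still at BIG-ish level has no background anywhere
  for (R_xlen_t i = 0; i < n; ++i) {
    if (out[i] >= BIG) out[i] = R_PosInf;
  }
  return out;
}
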