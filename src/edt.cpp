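#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Exact Euclidean distance transform on a regular 3D grid with anisotropic
// spacing, by the separable lower-envelope-of-parabolas method. Distances are
// measured between voxel centers; a large finite sentinel stands in for
// "no feature voxel" so that all-background scan lines stay well-defined.

static const double INF_SENTINEL = 1e20;

// One-dimensional squared distance transform along samples at positions q*s.
static void dt1d(const std::vector<double>& f, int n, double s,
                 std::vector<double>& d, std::vector<int>& v,
                 std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; q++) {
    double xq = q * s;
    while (true) {
      double xv = v[k] * s;
      double sint = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (sint <= z[k]) {
        k--;
      } else {
        k++;
        v[k] = q;
        z[k] = sint;
        z[k + 1] = std::numeric_limits<double>::infinity();
        break;
      }
    }
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    double x = q * s;
    while (z[k + 1] < x) k++;
    double dx = x - v[k] * s;
    d[q] = dx * dx + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector edt3d_cpp(LogicalVector occ, IntegerVector dims,
                        NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);

  for (R_xlen_t i = 0; i < n; i++)
    out[i] = (occ[i] == TRUE) ? 0.0 : INF_SENTINEL;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x (fastest-varying index)
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; i++) f[i] = out[base + i];
      dt1d(f, nx, sx, d, v, z);
      for (int i = 0; i < nx; i++) out[base + i] = d[i];
    }

  // pass along y
  for (int k = 0; k < nz; k++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = i + (R_xlen_t)nx * ny * k;
      for (int j = 0; j < ny; j++) f[j] = out[base + (R_xlen_t)nx * j];
      dt1d(f, ny, sy, d, v, z);
      for (int j = 0; j < ny; j++) out[base + (R_xlen_t)nx * j] = d[j];
    }

  // pass along z
  for (int j = 0; j < ny; j++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = i + (R_xlen_t)nx * j;
      R_xlen_t stride = (R_xlen_t)nx * ny;
      for (int k = 0; k < nz; k++) f[k] = out[base + stride * k];
      dt1d(f, nz, sz, d, v, z);
      for (int k = 0; k < nz; k++) out[base + stride * k] = d[k];
    }

  for (R_xlen_t i = 0; i < n; i++)
    out[i] = std::sqrt(out[i]);
  return out;
}
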