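#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// separable 1D lower-envelope passes along each array axis.

static const double INF = std::numeric_limits<double>::infinity();
// Seed value for foreground voxels: large but finite so the lower-envelope
// intersection arithmetic stays well-defined on all-foreground scan lines.
static const double BIG = 1e15;

// 1D squared distance transform of sampled function f, in place.
static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
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
    while (z[k + 1] < q) ++k;
    d[q] = (double)(q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt_squared")]]
NumericVector edt_squared(LogicalVector mask, IntegerVector dim) {
  int ndim = dim.size();
  if (ndim != 3) stop("mask must be 3D");
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = mask.size();

  NumericVector g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = mask[i] ? BIG : 0.0;

  int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), d(nmax);
  std::vector<int> v(nmax);
  std::vector<double> z(nmax + 1);

  R_xlen_t sy = nz, sx = (R_xlen_t)nz * ny;

  // pass along z (stride 1)
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = y * sy + x * sx;
      for (int q = 0; q < nz; ++q) f[q] = g[base + q];
      dt1d(f, d, v, z, nz);
      for (int q = 0; q < nz; ++q) g[base + q] = d[q];
    }
  // pass along y (stride nz)
  for (int x = 0; x < nx; ++x)
    for (int zz = 0; zz < nz; ++zz) {
      R_xlen_t base = zz + x * sx;
      for (int q = 0; q < ny; ++q) f[q] = g[base + q * sy];
      dt1d(f, d, v, z, ny);
      for (int q = 0; q < ny; ++q) g[base + q * sy] = d[q];
    }
  // pass along x (stride nz*ny)
  for (int zz = 0; zz < nz; ++zz)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = zz + y * sy;
      for (int q = 0; q < nx; ++q) f[q] = g[base + q * sx];
      dt1d(f, d, v, z, nx);
      for (int q = 0; q < nx; ++q) g[base + q * sx] = d[q];
    }

  g.attr("dim") = dim;
  return g;
}
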