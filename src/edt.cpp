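#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// Exact squared Euclidean distance transform of a sampled function along one
// line (Felzenszwalb & Huttenlocher lower-envelope algorithm), with grid
// spacing h (mm). f holds squared distances from previous passes; the result
// is min_j f[j] + h^2 (i - j)^2.
static void dt1d(const double* f, double* d, int* v, double* z, int n, double h2) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    for (;;) {
      int p = v[k];
      s = ((f[q] + h2 * q * q) - (f[p] + h2 * p * p)) / (2.0 * h2 * (q - p));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    int p = v[k];
    double dq = (double)(q - p);
    d[q] = h2 * dq * dq + f[p];
  }
}

// [[Rcpp::export(name = ".edt_squared_mm")]]
NumericVector edt_squared_mm(NumericVector mask, IntegerVector dims, NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  // large finite background sentinel: keeps the lower-envelope intersection
  // arithmetic finite on lines that mix feature and background samples
  const double INF = 1e20;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = (mask[i] != 0.0) ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x (stride 1)
  double h2 = spacing[0] * spacing[0];
  for (int kz = 0; kz < nz; ++kz)
    for (int ky = 0; ky < ny; ++ky) {
      double* line = &out[(R_xlen_t)kz * nx * ny + (R_xlen_t)ky * nx];
      bool any = false;
      for (int i = 0; i < nx; ++i) { f[i] = line[i]; if (f[i] < INF) any = true; }
      if (!any) continue;
      dt1d(f.data(), d.data(), v.data(), z.data(), nx, h2);
      for (int i = 0; i < nx; ++i) line[i] = d[i];
    }

  // pass along y (stride nx)
  h2 = spacing[1] * spacing[1];
  for (int kz = 0; kz < nz; ++kz)
    for (int kx = 0; kx < nx; ++kx) {
      double* base = &out[(R_xlen_t)kz * nx * ny + kx];
      bool any = false;
      for (int j = 0; j < ny; ++j) { f[j] = base[(R_xlen_t)j * nx]; if (f[j] < INF) any = true; }
      if (!any) continue;
      dt1d(f.data(), d.data(), v.data(), z.data(), ny, h2);
      for (int j = 0; j < ny; ++j) base[(R_xlen_t)j * nx] = d[j];
    }

  // pass along z (stride nx*ny)
  h2 = spacing[2] * spacing[2];
  const R_xlen_t sz = (R_xlen_t)nx * ny;
  for (int ky = 0; ky < ny; ++ky)
    for (int kx = 0; kx < nx; ++kx) {
      double* base = &out[(R_xlen_t)ky * nx + kx];
      bool any = false;
      for (int kq = 0; kq < nz; ++kq) { f[kq] = base[sz * kq]; if (f[kq] < INF) any = true; }
      if (!any) continue;
      dt1d(f.data(), d.data(), v.data(), z.data(), nz, h2);
      for (int kq = 0; kq < nz; ++kq) base[sz * kq] = d[kq];
    }

  return out;
}
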