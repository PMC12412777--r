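#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Group normalization and dual pooling kernels (all double precision; these
// are cheap relative to the convolutions but allocation-heavy in plain R).

// [[Rcpp::export(name = ".gn_fwd_cpp")]]
List gn_fwd_cpp(NumericVector x, int n, int c, int g,
                NumericVector gamma, NumericVector beta, double eps) {
  const int cs = c / g;
  const R_xlen_t m = (R_xlen_t)n * cs;
  NumericVector out((R_xlen_t)n * c);
  NumericVector mu(g), istd(g);
  const double* xp = REAL(x);
  double* op = REAL(out);
  for (int gi = 0; gi < g; ++gi) {
    const double* xg = xp + m * gi;
    double s = 0, s2 = 0;
    for (R_xlen_t i = 0; i < m; ++i) { s += xg[i]; s2 += xg[i] * xg[i]; }
    const double mean = s / m;
    const double var = s2 / m - mean * mean;
    const double is = 1.0 / std::sqrt(var + eps);
    mu[gi] = mean; istd[gi] = is;
    for (int cj = 0; cj < cs; ++cj) {
      const int ch = gi * cs + cj;
      const double ga = gamma[ch], be = beta[ch];
      const double* xc = xp + (R_xlen_t)ch * n;
      double* oc = op + (R_xlen_t)ch * n;
      for (int i = 0; i < n; ++i) oc[i] = (xc[i] - mean) * is * ga + be;
    }
  }
  out.attr("dim") = x.attr("dim");
  return List::create(_["out"] = out, _["mu"] = mu, _["istd"] = istd);
}

// [[Rcpp::export(name = ".gn_bwd_cpp")]]
List gn_bwd_cpp(NumericVector x, NumericVector mu, NumericVector istd,
                NumericVector gamma, NumericVector dout, int n, int c, int g) {
  const int cs = c / g;
  const R_xlen_t m = (R_xlen_t)n * cs;
  NumericVector dx((R_xlen_t)n * c), dgamma(c), dbeta(c);
  const double* xp = REAL(x);
  const double* dp = REAL(dout);
  double* dxp = REAL(dx);
  for (int gi = 0; gi < g; ++gi) {
    const double mean = mu[gi], is = istd[gi];
    double s1 = 0, s2 = 0;
    for (int cj = 0; cj < cs; ++cj) {
      const int ch = gi * cs + cj;
      const double ga = gamma[ch];
      const double* xc = xp + (R_xlen_t)ch * n;
      const double* dc = dp + (R_xlen_t)ch * n;
      double dg = 0, dbv = 0;
      for (int i = 0; i < n; ++i) {
        const double xh = (xc[i] - mean) * is;
        const double dxh = dc[i] * ga;
        dg += dc[i] * xh;
        dbv += dc[i];
        s1 += dxh;
        s2 += dxh * xh;
      }
      dgamma[ch] = dg; dbeta[ch] = dbv;
    }
    const double c1 = s1 / m, c2 = s2 / m;
    for (int cj = 0; cj < cs; ++cj) {
      const int ch = gi * cs + cj;
      const double ga = gamma[ch];
      const double* xc = xp + (R_xlen_t)ch * n;
      const double* dc = dp + (R_xlen_t)ch * n;
      double* dxc = dxp + (R_xlen_t)ch * n;
      for (int i = 0; i < n; ++i) {
        const double xh = (xc[i] - mean) * is;
        dxc[i] = is * (dc[i] * ga - c1 - xh * c2);
      }
    }
  }
  dx.attr("dim") = x.attr("dim");
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// Dual 2x2x2 max + average pooling: output channels = [max | avg].
// [[Rcpp::export(name = ".pool_dual_fwd_cpp")]]
List pool_dual_fwd_cpp(NumericVector x, IntegerVector dims) {
  const int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3];
  const int hX = X / 2, hY = Y / 2, hZ = Z / 2;
  const R_xlen_t Nh = (R_xlen_t)hX * hY * hZ;
  NumericVector out(Nh * 2 * C);
  IntegerVector best(Nh * C);
  const double* xp = REAL(x);
  double* mo = REAL(out);
  double* ao = REAL(out) + Nh * C;
  int* bp = INTEGER(best);
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (R_xlen_t)c * X * Y * Z;
    for (int z = 0; z < hZ; ++z)
      for (int y = 0; y < hY; ++y) {
        const R_xlen_t o0 = (R_xlen_t)c * Nh + ((R_xlen_t)z * hY + y) * hX;
        for (int xi = 0; xi < hX; ++xi) {
          double mx = -1e308, sum = 0;
          int arg = 0, idx = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dxo = 0; dxo < 2; ++dxo) {
                const double v = xc[((R_xlen_t)(2 * z + dz) * Y + (2 * y + dy)) * X + 2 * xi + dxo];
                sum += v;
                if (v > mx) { mx = v; arg = idx; }
                ++idx;
              }
          mo[o0 + xi] = mx;
          ao[o0 + xi] = sum / 8.0;
          bp[o0 + xi] = arg;
        }
      }
  }
  out.attr("dim") = IntegerVector::create(hX, hY, hZ, 2 * C);
  return List::create(_["out"] = out, _["best"] = best);
}

// [[Rcpp::export(name = ".pool_dual_bwd_cpp")]]
NumericVector pool_dual_bwd_cpp(NumericVector dout, IntegerVector best,
                                IntegerVector dims) {
  const int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3];
  const int hX = X / 2, hY = Y / 2, hZ = Z / 2;
  const R_xlen_t Nh = (R_xlen_t)hX * hY * hZ;
  NumericVector dx((R_xlen_t)X * Y * Z * C);
  const double* dmax = REAL(dout);
  const double* davg = REAL(dout) + Nh * C;
  const int* bp = INTEGER(best);
  double* dxp = REAL(dx);
  for (int c = 0; c < C; ++c) {
    double* dxc = dxp + (R_xlen_t)c * X * Y * Z;
    for (int z = 0; z < hZ; ++z)
      for (int y = 0; y < hY; ++y) {
        const R_xlen_t o0 = (R_xlen_t)c * Nh + ((R_xlen_t)z * hY + y) * hX;
        for (int xi = 0; xi < hX; ++xi) {
          const double gav = davg[o0 + xi] / 8.0;
          const double gmx = dmax[o0 + xi];
          const int arg = bp[o0 + xi];
          int idx = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dxo = 0; dxo < 2; ++dxo) {
                double* t = dxc + ((R_xlen_t)(2 * z + dz) * Y + (2 * y + dy)) * X + 2 * xi + dxo;
                *t += gav + (idx == arg ? gmx : 0.0);
                ++idx;
              }
        }
      }
  }
  dx.attr("dim") = dims;
  return dx;
}
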