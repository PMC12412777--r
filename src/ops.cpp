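#include <Rcpp.h>
#include <cstring>

using namespace Rcpp;

// Element-wise and geometric kernels for the training loop. All double
// precision; these exist because per-step allocation churn in plain R
// (logical masks, aperm copies, generic 4D subsetting) costs more than the
// arithmetic itself at training-patch sizes.

// [[Rcpp::export(name = ".relu_fwd_cpp")]]
NumericVector relu_fwd_cpp(NumericVector x) {
  NumericVector out(x.size());
  const double* xp = REAL(x);
  double* op = REAL(out);
  for (R_xlen_t i = 0; i < x.size(); ++i) op[i] = xp[i] > 0 ? xp[i] : 0.0;
  out.attr("dim") = x.attr("dim");
  return out;
}

// mask recovered from the forward output: out > 0  <=>  x > 0
// [[Rcpp::export(name = ".relu_bwd_cpp")]]
NumericVector relu_bwd_cpp(NumericVector out, NumericVector dout) {
  NumericVector dx(dout.size());
  const double* op = REAL(out);
  const double* dp = REAL(dout);
  double* xp = REAL(dx);
  for (R_xlen_t i = 0; i < dout.size(); ++i) xp[i] = op[i] > 0 ? dp[i] : 0.0;
  dx.attr("dim") = dout.attr("dim");
  return dx;
}

// Inverted dropout; draws from R's RNG stream so set.seed() reproducibility
// carries through. Returns the scaled mask for the backward pass.
// [[Rcpp::export(name = ".dropout_fwd_cpp")]]
List dropout_fwd_cpp(NumericVector x, double rate) {
  NumericVector out(x.size()), mask(x.size());
  const double scale = 1.0 / (1.0 - rate);
  const double* xp = REAL(x);
  double* op = REAL(out);
  double* mp = REAL(mask);
  GetRNGstate();
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    const double m = unif_rand() >= rate ? scale : 0.0;
    mp[i] = m;
    op[i] = xp[i] * m;
  }
  PutRNGstate();
  out.attr("dim") = x.attr("dim");
  return List::create(_["out"] = out, _["mask"] = mask);
}

// [[Rcpp::export(name = ".mul_cpp")]]
NumericVector mul_cpp(NumericVector a, NumericVector b) {
  NumericVector out(a.size());
  const double* ap = REAL(a);
  const double* bp = REAL(b);
  double* op = REAL(out);
  for (R_xlen_t i = 0; i < a.size(); ++i) op[i] = ap[i] * bp[i];
  out.attr("dim") = a.attr("dim");
  return out;
}

// ---- x2 upsampling ------------------------------------------------------

// [[Rcpp::export(name = ".up2_nn_fwd_cpp")]]
NumericVector up2_nn_fwd_cpp(NumericVector x, IntegerVector dims) {
  const int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3];
  const int X2 = 2 * X, Y2 = 2 * Y, Z2 = 2 * Z;
  NumericVector out((R_xlen_t)X2 * Y2 * Z2 * C);
  const double* xp = REAL(x);
  double* op = REAL(out);
  for (int c = 0; c < C; ++c)
    for (int z = 0; z < Z2; ++z)
      for (int y = 0; y < Y2; ++y) {
        const double* src = xp + (((R_xlen_t)c * Z + z / 2) * Y + y / 2) * X;
        double* dst = op + (((R_xlen_t)c * Z2 + z) * Y2 + y) * X2;
        for (int i = 0; i < X; ++i) { dst[2 * i] = src[i]; dst[2 * i + 1] = src[i]; }
      }
  out.attr("dim") = IntegerVector::create(X2, Y2, Z2, C);
  return out;
}

// [[Rcpp::export(name = ".up2_nn_bwd_cpp")]]
NumericVector up2_nn_bwd_cpp(NumericVector dout, IntegerVector in_dims) {
  const int X = in_dims[0], Y = in_dims[1], Z = in_dims[2], C = in_dims[3];
  const int X2 = 2 * X, Y2 = 2 * Y, Z2 = 2 * Z;
  NumericVector dx((R_xlen_t)X * Y * Z * C);
  const double* dp = REAL(dout);
  double* xp = REAL(dx);
  for (int c = 0; c < C; ++c)
    for (int z = 0; z < Z2; ++z)
      for (int y = 0; y < Y2; ++y) {
        const double* src = dp + (((R_xlen_t)c * Z2 + z) * Y2 + y) * X2;
        double* dst = xp + (((R_xlen_t)c * Z + z / 2) * Y + y / 2) * X;
        for (int i = 0; i < X; ++i) dst[i] += src[2 * i] + src[2 * i + 1];
      }
  dx.attr("dim") = in_dims;
  return dx;
}

// Half-voxel trilinear x2: output index i (0-based) samples input position
// (i - 0.5) / 2 + 0.5 - 0.5 = i/2 - 0.25 (0-based), clamped to the grid.
static void lin_coeff(int n, std::vector<int>& lo, std::vector<int>& hi,
                      std::vector<double>& w) {
  const int m = 2 * n;
  lo.resize(m); hi.resize(m); w.resize(m);
  for (int i = 0; i < m; ++i) {
    double p = 0.5 * i - 0.25;
    if (p < 0) p = 0;
    if (p > n - 1) p = n - 1;
    int l = (int)p;
    int h = l + 1;
    if (h > n - 1) h = n - 1;
    if (l > n - 1) l = n - 1;
    lo[i] = l; hi[i] = h; w[i] = p - l;
  }
}

// [[Rcpp::export(name = ".up2_lin_fwd_cpp")]]
NumericVector up2_lin_fwd_cpp(NumericVector x, IntegerVector dims) {
  const int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3];
  const int X2 = 2 * X, Y2 = 2 * Y, Z2 = 2 * Z;
  std::vector<int> lx, hx, ly, hy, lz, hz;
  std::vector<double> wx, wy, wz;
  lin_coeff(X, lx, hx, wx); lin_coeff(Y, ly, hy, wy); lin_coeff(Z, lz, hz, wz);
  NumericVector out((R_xlen_t)X2 * Y2 * Z2 * C);
  const double* xp = REAL(x);
  double* op = REAL(out);
  for (int c = 0; c < C; ++c)
    for (int z = 0; z < Z2; ++z) {
      const double wz1 = wz[z];
      const R_xlen_t z0 = ((R_xlen_t)c * Z + lz[z]) * Y;
      const R_xlen_t z1 = ((R_xlen_t)c * Z + hz[z]) * Y;
      for (int y = 0; y < Y2; ++y) {
        const double wy1 = wy[y];
        const double* r00 = xp + (z0 + ly[y]) * X;
        const double* r01 = xp + (z0 + hy[y]) * X;
        const double* r10 = xp + (z1 + ly[y]) * X;
        const double* r11 = xp + (z1 + hy[y]) * X;
        double* dst = op + (((R_xlen_t)c * Z2 + z) * Y2 + y) * X2;
        for (int i = 0; i < X2; ++i) {
          const int l = lx[i], h = hx[i];
          const double w1 = wx[i], w0 = 1 - w1;
          const double a = (1 - wy1) * ((1 - wz1) * (w0 * r00[l] + w1 * r00[h]) +
                                        wz1 * (w0 * r10[l] + w1 * r10[h]));
          const double b = wy1 * ((1 - wz1) * (w0 * r01[l] + w1 * r01[h]) +
                                  wz1 * (w0 * r11[l] + w1 * r11[h]));
          dst[i] = a + b;
        }
      }
    }
  out.attr("dim") = IntegerVector::create(X2, Y2, Z2, C);
  return out;
}

// [[Rcpp::export(name = ".up2_lin_bwd_cpp")]]
NumericVector up2_lin_bwd_cpp(NumericVector dout, IntegerVector in_dims) {
  const int X = in_dims[0], Y = in_dims[1], Z = in_dims[2], C = in_dims[3];
  const int X2 = 2 * X, Y2 = 2 * Y, Z2 = 2 * Z;
  std::vector<int> lx, hx, ly, hy, lz, hz;
  std::vector<double> wx, wy, wz;
  lin_coeff(X, lx, hx, wx); lin_coeff(Y, ly, hy, wy); lin_coeff(Z, lz, hz, wz);
  NumericVector dx((R_xlen_t)X * Y * Z * C);
  const double* dp = REAL(dout);
  double* xp = REAL(dx);
  for (int c = 0; c < C; ++c)
    for (int z = 0; z < Z2; ++z) {
      const double wz1 = wz[z];
      const R_xlen_t z0 = ((R_xlen_t)c * Z + lz[z]) * Y;
      const R_xlen_t z1 = ((R_xlen_t)c * Z + hz[z]) * Y;
      for (int y = 0; y < Y2; ++y) {
        const double wy1 = wy[y];
        double* r00 = xp + (z0 + ly[y]) * X;
        double* r01 = xp + (z0 + hy[y]) * X;
        double* r10 = xp + (z1 + ly[y]) * X;
        double* r11 = xp + (z1 + hy[y]) * X;
        const double* src = dp + (((R_xlen_t)c * Z2 + z) * Y2 + y) * X2;
        for (int i = 0; i < X2; ++i) {
          const int l = lx[i], h = hx[i];
          const double w1 = wx[i], w0 = 1 - w1;
          const double g = src[i];
          const double g00 = g * (1 - wy1) * (1 - wz1);
          const double g01 = g * wy1 * (1 - wz1);
          const double g10 = g * (1 - wy1) * wz1;
          const double g11 = g * wy1 * wz1;
          r00[l] += w0 * g00; r00[h] += w1 * g00;
          r01[l] += w0 * g01; r01[h] += w1 * g01;
          r10[l] += w0 * g10; r10[h] += w1 * g10;
          r11[l] += w0 * g11; r11[h] += w1 * g11;
        }
      }
    }
  dx.attr("dim") = in_dims;
  return dx;
}

// ---- patch geometry -----------------------------------------------------

// Zero-padded crop: start is the 0-based corner (may be negative).
// [[Rcpp::export(name = ".crop_patch_cpp")]]
NumericVector crop_patch_cpp(NumericVector x, IntegerVector dims,
                             IntegerVector start, IntegerVector psize) {
  const int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3];
  const int P = psize[0], Q = psize[1], R = psize[2];
  const int sx = start[0], sy = start[1], sz = start[2];
  NumericVector out((R_xlen_t)P * Q * R * C);
  const double* xp = REAL(x);
  double* op = REAL(out);
  const int i0 = std::max(0, -sx), i1 = std::min(P, X - sx);
  for (int c = 0; c < C; ++c)
    for (int r = 0; r < R; ++r) {
      const int z = r + sz;
      if (z < 0 || z >= Z) continue;
      for (int q = 0; q < Q; ++q) {
        const int y = q + sy;
        if (y < 0 || y >= Y || i0 >= i1) continue;
        const double* s = xp + (((R_xlen_t)c * Z + z) * Y + y) * X + i0 + sx;
        double* d = op + (((R_xlen_t)c * R + r) * Q + q) * P + i0;
        std::memcpy(d, s, sizeof(double) * (i1 - i0));
      }
    }
  out.attr("dim") = IntegerVector::create(P, Q, R, C);
  return out;
}

// Flip along x (axis 1) or y (axis 2).
// [[Rcpp::export(name = ".flip4d_cpp")]]
NumericVector flip4d_cpp(NumericVector x, IntegerVector dims, int axis) {
  const int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3];
  NumericVector out(x.size());
  const double* xp = REAL(x);
  double* op = REAL(out);
  const R_xlen_t nzc = (R_xlen_t)Z * C;
  for (R_xlen_t zc = 0; zc < nzc; ++zc) {
    const double* s = xp + zc * X * Y;
    double* d = op + zc * X * Y;
    if (axis == 1) {
      for (int y = 0; y < Y; ++y)
        for (int i = 0; i < X; ++i) d[(R_xlen_t)y * X + i] = s[(R_xlen_t)y * X + (X - 1 - i)];
    } else {
      for (int y = 0; y < Y; ++y)
        std::memcpy(d + (R_xlen_t)y * X, s + (R_xlen_t)(Y - 1 - y) * X, sizeof(double) * X);
    }
  }
  out.attr("dim") = dims;
  return out;
}

// k quarter-turns counter-clockwise in the (x, y) plane; requires X == Y
// for odd k.
// [[Rcpp::export(name = ".rot90_cpp")]]
NumericVector rot90_cpp(NumericVector x, IntegerVector dims, int k) {
  const int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3];
  NumericVector out(x.size());
  const double* xp = REAL(x);
  double* op = REAL(out);
  const R_xlen_t nzc = (R_xlen_t)Z * C;
  for (R_xlen_t zc = 0; zc < nzc; ++zc) {
    const double* s = xp + zc * X * Y;
    double* d = op + zc * X * Y;
    if (k == 2) {
      for (int y = 0; y < Y; ++y)
        for (int i = 0; i < X; ++i)
          d[(R_xlen_t)y * X + i] = s[(R_xlen_t)(Y - 1 - y) * X + (X - 1 - i)];
    } else if (k == 1) {
      // out[i, j] = in[j, X - 1 - i]
      for (int j = 0; j < X; ++j)
        for (int i = 0; i < X; ++i)
          d[(R_xlen_t)j * X + i] = s[(R_xlen_t)(X - 1 - i) * X + j];
    } else { // k == 3: out[i, j] = in[X - 1 - j, i]
      for (int j = 0; j < X; ++j)
        for (int i = 0; i < X; ++i)
          d[(R_xlen_t)j * X + i] = s[(R_xlen_t)i * X + (X - 1 - j)];
    }
  }
  out.attr("dim") = dims;
  return out;
}
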