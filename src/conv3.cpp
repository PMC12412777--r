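#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <vector>
#include <cstring>

using namespace Rcpp;

// 3D convolution (stride 1, "same" zero padding) evaluated per kernel
// offset: the shifted input is packed into an (N x C_sel) float matrix and
// multiplied against the offset's (C_sel x C_out) weight slice, accumulating
// over the k^3 offsets. The per-offset working set (a few MB at training
// patch sizes) stays cache-resident, which matters more here than GEMM
// shape: with narrow layers the arithmetic is memory-bandwidth bound.
// C_sel is the caller's channel selection — input channels that are
// identically zero (absent roster structures) are skipped losslessly in the
// forward product and weight gradient.
//
// Buffers and GEMMs are single precision (ample for conv arithmetic);
// parameters, activations and accumulated gradients stay double at the R
// level. A float copy of the selected input channels is cached between
// forward and backward and released deterministically after backward. An
// all-double reference implementation lives in R/nn-ops.R and backs the
// unit-test oracles.

extern "C" void F77_NAME(sgemm)(
    const char*, const char*, const int*, const int*, const int*,
    const float*, const float*, const int*, const float*, const int*,
    const float*, float*, const int*
#ifdef FC_LEN_T
    , FC_LEN_T, FC_LEN_T
#endif
);

static inline void sgemm_wrap(const char* ta, const char* tb, int m, int n, int k,
                              float alpha, const float* A, int lda,
                              const float* B, int ldb, float beta, float* C, int ldc) {
  F77_NAME(sgemm)(ta, tb, &m, &n, &k, &alpha, A, &lda, B, &ldb, &beta, C, &ldc
#ifdef FC_LEN_T
                  , (FC_LEN_T)1, (FC_LEN_T)1
#endif
  );
}

// Recycled float workspaces: buffer sizes repeat from step to step, so fresh
// allocation every call would spend more time in page faults than arithmetic.
static std::vector<std::vector<float>> g_pool;

static std::vector<float> pool_take(size_t n) {
  for (auto it = g_pool.begin(); it != g_pool.end(); ++it) {
    if (it->capacity() >= n) {
      std::vector<float> v = std::move(*it);
      g_pool.erase(it);
      v.resize(n);
      return v;
    }
  }
  std::vector<float> v;
  v.reserve(n);
  v.resize(n);
  return v;
}

static void pool_give(std::vector<float>&& v) {
  if (v.capacity() >= (1u << 16) && g_pool.size() < 16) {
    g_pool.push_back(std::move(v));
  }
}

struct PooledBuf {
  std::vector<float> v;
  explicit PooledBuf(size_t n) : v(pool_take(n)) {}
  ~PooledBuf() { pool_give(std::move(v)); }
  float* data() { return v.data(); }
};

// Float copy of the selected input channels, cached forward -> backward.
struct ConvCache {
  std::vector<float> xf;
  int N = 0;
  ~ConvCache() { pool_give(std::move(xf)); }
};

// Return a cache's buffer to the pool immediately (the backward pass
// consumes each cache exactly once; waiting for R's GC to run the
// external-pointer finalizer would let large buffers accumulate).
// [[Rcpp::export(name = ".conv3_release")]]
void conv3_release(SEXP cache_ptr) {
  XPtr<ConvCache> ptr(cache_ptr);
  pool_give(std::move(ptr->xf));
  ptr->xf = std::vector<float>();
  ptr->N = 0;
}

// Channels of the (n x c) tensor that contain any non-zero value (1-based).
// Early exit makes this near-free for dense feature maps.
// [[Rcpp::export(name = ".nonzero_channels")]]
IntegerVector nonzero_channels(NumericVector x, int n, int c) {
  std::vector<int> keep;
  for (int ch = 0; ch < c; ++ch) {
    const double* p = REAL(x) + (R_xlen_t)ch * n;
    for (int i = 0; i < n; ++i) {
      if (p[i] != 0.0) { keep.push_back(ch + 1); break; }
    }
  }
  return IntegerVector(keep.begin(), keep.end());
}

// Pack the float source (N x C contiguous channels) shifted by (dx,dy,dz)
// into buf (N x C), zero-filling out-of-range samples.
static void pack_shifted(const float* x, int X, int Y, int Z, int C,
                         int dx, int dy, int dz, float* buf) {
  const R_xlen_t N = (R_xlen_t)X * Y * Z;
  const int x0 = std::max(0, -dx), x1 = std::min(X, X - dx);
  for (int c = 0; c < C; ++c) {
    const float* src = x + (R_xlen_t)c * N;
    float* dst = buf + (R_xlen_t)c * N;
    for (int z = 0; z < Z; ++z) {
      int sz = z + dz;
      float* drow0 = dst + (R_xlen_t)z * X * Y;
      if (sz < 0 || sz >= Z) { std::memset(drow0, 0, sizeof(float) * X * Y); continue; }
      for (int y = 0; y < Y; ++y) {
        int sy = y + dy;
        float* drow = drow0 + (R_xlen_t)y * X;
        if (sy < 0 || sy >= Y || x0 >= x1) { std::memset(drow, 0, sizeof(float) * X); continue; }
        if (x0 > 0) std::memset(drow, 0, sizeof(float) * x0);
        std::memcpy(drow + x0, src + ((R_xlen_t)sz * Y + sy) * X + x0 + dx,
                    sizeof(float) * (x1 - x0));
        if (x1 < X) std::memset(drow + x1, 0, sizeof(float) * (X - x1));
      }
    }
  }
}

// Scatter-add the float (N x C) matrix g, shifted by (dx,dy,dz), into acc.
static void scatter_shifted(const float* g, int X, int Y, int Z, int C,
                            int dx, int dy, int dz, float* acc) {
  const R_xlen_t N = (R_xlen_t)X * Y * Z;
  const int x0 = std::max(0, -dx), x1 = std::min(X, X - dx);
  if (x0 >= x1) return;
  for (int c = 0; c < C; ++c) {
    const float* src = g + (R_xlen_t)c * N;
    float* dst = acc + (R_xlen_t)c * N;
    for (int z = 0; z < Z; ++z) {
      int sz = z + dz;
      if (sz < 0 || sz >= Z) continue;
      for (int y = 0; y < Y; ++y) {
        int sy = y + dy;
        if (sy < 0 || sy >= Y) continue;
        const float* s = src + ((R_xlen_t)z * Y + y) * X + x0;
        float* d = dst + ((R_xlen_t)sz * Y + sy) * X + x0 + dx;
        for (int i = 0; i < x1 - x0; ++i) d[i] += s[i];
      }
    }
  }
}

static void gather_offset_weights(const double* W, int k, int Cin, int Cout,
                                  int a, int bb, int cc,
                                  const std::vector<int>& sel, float* Wm) {
  const int nsel = (int)sel.size();
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < nsel; ++ci)
      Wm[ci + (R_xlen_t)nsel * co] =
        (float)W[a + k * (bb + k * ((R_xlen_t)cc + k * ((R_xlen_t)sel[ci] + (R_xlen_t)Cin * co)))];
}

// [[Rcpp::export(name = ".conv3_fwd_cpp")]]
List conv3_fwd_cpp(NumericVector x, IntegerVector dims, int k,
                   NumericVector W, IntegerVector wdim,
                   IntegerVector nz, NumericVector b, bool keep) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const int Cin = wdim[3], Cout = wdim[4];
  const int N = X * Y * Z;
  const int nsel = nz.size();
  const int p = (k - 1) / 2;
  NumericVector out((R_xlen_t)N * Cout);
  out.attr("dim") = IntegerVector::create(X, Y, Z, Cout);
  XPtr<ConvCache> ptr(new ConvCache(), true);
  if (nsel == 0) {
    for (int c = 0; c < Cout; ++c)
      std::fill(out.begin() + (R_xlen_t)c * N, out.begin() + (R_xlen_t)(c + 1) * N, b[c]);
    return List::create(_["out"] = out, _["ptr"] = ptr);
  }
  std::vector<int> sel(nsel);
  for (int i = 0; i < nsel; ++i) sel[i] = nz[i] - 1;
  ptr->xf = pool_take((R_xlen_t)N * nsel);
  ptr->N = N;
  for (int ci = 0; ci < nsel; ++ci) {
    const double* s = REAL(x) + (R_xlen_t)sel[ci] * N;
    float* d = ptr->xf.data() + (R_xlen_t)ci * N;
    for (int i = 0; i < N; ++i) d[i] = (float)s[i];
  }
  // Shifting commutes with the per-voxel channel mixing, so the GEMM runs
  // on the unshifted (cache-resident) input; all k^3 offsets are batched
  // into one GEMM (better BLAS shape than k^3 narrow products) and only the
  // narrow per-offset results need shift-scattering into the accumulator.
  const int ko = k * k * k;
  PooledBuf ybuf((R_xlen_t)N * Cout * ko), acc((R_xlen_t)N * Cout);
  std::memset(acc.data(), 0, sizeof(float) * (R_xlen_t)N * Cout);
  std::vector<float> Wm((R_xlen_t)nsel * Cout * ko);
  {
    int o = 0;
    for (int a = 0; a < k; ++a) for (int bb = 0; bb < k; ++bb) for (int cc = 0; cc < k; ++cc, ++o)
      gather_offset_weights(REAL(W), k, Cin, Cout, a, bb, cc, sel,
                            Wm.data() + (R_xlen_t)o * nsel * Cout);
  }
  sgemm_wrap("N", "N", N, Cout * ko, nsel, 1.0f, ptr->xf.data(), N, Wm.data(), nsel,
             0.0f, ybuf.data(), N);
  {
    int o = 0;
    for (int a = 0; a < k; ++a) for (int bb = 0; bb < k; ++bb) for (int cc = 0; cc < k; ++cc, ++o)
      // acc[v] += y_o[v + o]  <=>  scatter y_o with shift -o
      scatter_shifted(ybuf.data() + (R_xlen_t)o * N * Cout, X, Y, Z, Cout,
                      -(a - p), -(bb - p), -(cc - p), acc.data());
  }
  double* o = REAL(out);
  for (int co = 0; co < Cout; ++co) {
    const float* ac = acc.data() + (R_xlen_t)co * N;
    const double bc = b[co];
    double* oc = o + (R_xlen_t)co * N;
    for (int i = 0; i < N; ++i) oc[i] = (double)ac[i] + bc;
  }
  if (!keep) {
    pool_give(std::move(ptr->xf));
    ptr->xf = std::vector<float>();
    ptr->N = 0;
  }
  return List::create(_["out"] = out, _["ptr"] = ptr);
}

// [[Rcpp::export(name = ".conv3_bwd_cpp")]]
List conv3_bwd_cpp(SEXP cache_ptr, IntegerVector dims, int k,
                   NumericVector W, IntegerVector wdim,
                   IntegerVector nz, NumericVector dout, bool need_dx) {
  XPtr<ConvCache> ptr(cache_ptr);
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const int Cin = wdim[3], Cout = wdim[4];
  const int N = X * Y * Z;
  const int nsel = nz.size();
  const int p = (k - 1) / 2;
  NumericVector dW((R_xlen_t)k * k * k * Cin * Cout);
  dW.attr("dim") = IntegerVector::create(k, k, k, Cin, Cout);
  NumericVector db(Cout);
  PooledBuf df((R_xlen_t)N * Cout);
  for (int co = 0; co < Cout; ++co) {
    double s = 0;
    const double* dc = REAL(dout) + (R_xlen_t)co * N;
    float* ff = df.data() + (R_xlen_t)co * N;
    for (int i = 0; i < N; ++i) { s += dc[i]; ff[i] = (float)dc[i]; }
    db[co] = s;
  }
  if (nsel > 0 && ptr->N != N) stop("conv3 backward: input cache missing or stale");
  std::vector<int> sel(nsel), all(Cin);
  for (int i = 0; i < nsel; ++i) sel[i] = nz[i] - 1;
  for (int i = 0; i < Cin; ++i) all[i] = i;
  const int ko = k * k * k;
  std::vector<float> tmp((R_xlen_t)std::max(nsel, 1) * Cout * ko),
      WmT((R_xlen_t)Cin * Cout);
  std::vector<float> dxf;
  PooledBuf gbuf(need_dx ? (R_xlen_t)N * Cin : 1);
  if (nsel > 0) {
    // (S_o x)^T df = x^T S_{-o}(df): pack the narrow gradient at every
    // offset into one batch and take a single wide GEMM for all of dW
    PooledBuf dfs((R_xlen_t)N * Cout * ko);
    int o = 0;
    for (int a = 0; a < k; ++a) for (int bb = 0; bb < k; ++bb) for (int cc = 0; cc < k; ++cc, ++o)
      pack_shifted(df.data(), X, Y, Z, Cout, -(a - p), -(bb - p), -(cc - p),
                   dfs.data() + (R_xlen_t)o * N * Cout);
    sgemm_wrap("T", "N", nsel, Cout * ko, N, 1.0f, ptr->xf.data(), N, dfs.data(), N,
               0.0f, tmp.data(), nsel);
    o = 0;
    for (int a = 0; a < k; ++a) for (int bb = 0; bb < k; ++bb) for (int cc = 0; cc < k; ++cc, ++o) {
      const float* t = tmp.data() + (R_xlen_t)o * nsel * Cout;
      for (int co = 0; co < Cout; ++co)
        for (int ci = 0; ci < nsel; ++ci)
          dW[a + k * (bb + k * ((R_xlen_t)cc + k * ((R_xlen_t)sel[ci] + (R_xlen_t)Cin * co)))] =
            (double)t[ci + (R_xlen_t)nsel * co];
    }
  }
  if (need_dx) {
    dxf = pool_take((R_xlen_t)N * Cin);
    std::memset(dxf.data(), 0, sizeof(float) * (R_xlen_t)N * Cin);
    for (int a = 0; a < k; ++a) for (int bb = 0; bb < k; ++bb) for (int cc = 0; cc < k; ++cc) {
      // gradient w.r.t. every input channel (a zero input channel still has
      // a non-zero gradient), scattered back with the offset's shift
      gather_offset_weights(REAL(W), k, Cin, Cout, a, bb, cc, all, WmT.data());
      sgemm_wrap("N", "T", N, Cin, Cout, 1.0f, df.data(), N, WmT.data(), Cin,
                 0.0f, gbuf.data(), N);
      scatter_shifted(gbuf.data(), X, Y, Z, Cin, a - p, bb - p, cc - p, dxf.data());
    }
  }
  conv3_release(cache_ptr);
  if (!need_dx) return List::create(_["dW"] = dW, _["db"] = db);
  NumericVector dx_acc((R_xlen_t)N * Cin);
  for (R_xlen_t i = 0; i < (R_xlen_t)N * Cin; ++i) dx_acc[i] = (double)dxf[i];
  dx_acc.attr("dim") = IntegerVector::create(X, Y, Z, Cin);
  pool_give(std::move(dxf));
  return List::create(_["dW"] = dW, _["db"] = db, _["dx"] = dx_acc);
}

// ---- transposed convolution (2x2x2 kernel, stride 2) --------------------

// out[2v + o] = sum_cin x[v, cin] W[o, cin, cout] + b: one GEMM per offset
// on the unshifted input, written to the offset's interleaved positions.
// [[Rcpp::export(name = ".tconv2_fwd_cpp")]]
NumericVector tconv2_fwd_cpp(NumericVector x, IntegerVector dims,
                             NumericVector W, NumericVector b) {
  const int X = dims[0], Y = dims[1], Z = dims[2], Cin = dims[3];
  const int Cout = (int)(W.size() / (8 * Cin));
  const int N = X * Y * Z;
  const int X2 = 2 * X, Y2 = 2 * Y, Z2 = 2 * Z;
  NumericVector out((R_xlen_t)X2 * Y2 * Z2 * Cout);
  out.attr("dim") = IntegerVector::create(X2, Y2, Z2, Cout);
  std::vector<float> xf((R_xlen_t)N * Cin), y((R_xlen_t)N * Cout),
      Wm((R_xlen_t)Cin * Cout);
  for (R_xlen_t i = 0; i < (R_xlen_t)N * Cin; ++i) xf[i] = (float)x[i];
  double* op = REAL(out);
  for (int a = 0; a < 2; ++a) for (int bb = 0; bb < 2; ++bb) for (int cc = 0; cc < 2; ++cc) {
    for (int co = 0; co < Cout; ++co)
      for (int ci = 0; ci < Cin; ++ci)
        Wm[ci + (R_xlen_t)Cin * co] =
          (float)W[a + 2 * (bb + 2 * ((R_xlen_t)cc + 2 * ((R_xlen_t)ci + (R_xlen_t)Cin * co)))];
    sgemm_wrap("N", "N", N, Cout, Cin, 1.0f, xf.data(), N, Wm.data(), Cin,
               0.0f, y.data(), N);
    for (int co = 0; co < Cout; ++co) {
      const float* yc = y.data() + (R_xlen_t)co * N;
      const double bc = b[co];
      for (int z = 0; z < Z; ++z)
        for (int yy = 0; yy < Y; ++yy) {
          const float* s = yc + ((R_xlen_t)z * Y + yy) * X;
          double* d = op + (((R_xlen_t)co * Z2 + 2 * z + cc) * Y2 + 2 * yy + bb) * X2 + a;
          for (int i = 0; i < X; ++i) d[2 * i] = (double)s[i] + bc;
        }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".tconv2_bwd_cpp")]]
List tconv2_bwd_cpp(NumericVector x, IntegerVector dims,
                    NumericVector W, NumericVector dout, bool need_dx) {
  const int X = dims[0], Y = dims[1], Z = dims[2], Cin = dims[3];
  const int Cout = (int)(W.size() / (8 * Cin));
  const int N = X * Y * Z;
  const int X2 = 2 * X, Y2 = 2 * Y, Z2 = 2 * Z;
  NumericVector dW(W.size()), db(Cout);
  dW.attr("dim") = IntegerVector::create(2, 2, 2, Cin, Cout);
  std::vector<float> xf((R_xlen_t)N * Cin), sub((R_xlen_t)N * Cout),
      Wm((R_xlen_t)Cin * Cout), tmp((R_xlen_t)Cin * Cout),
      dxa((R_xlen_t)N * Cin, 0.0f);
  for (R_xlen_t i = 0; i < (R_xlen_t)N * Cin; ++i) xf[i] = (float)x[i];
  const double* dp = REAL(dout);
  for (int a = 0; a < 2; ++a) for (int bb = 0; bb < 2; ++bb) for (int cc = 0; cc < 2; ++cc) {
    for (int co = 0; co < Cout; ++co) {
      float* sc = sub.data() + (R_xlen_t)co * N;
      double s = 0;
      for (int z = 0; z < Z; ++z)
        for (int yy = 0; yy < Y; ++yy) {
          const double* dsrc = dp + (((R_xlen_t)co * Z2 + 2 * z + cc) * Y2 + 2 * yy + bb) * X2 + a;
          float* drow = sc + ((R_xlen_t)z * Y + yy) * X;
          for (int i = 0; i < X; ++i) { drow[i] = (float)dsrc[2 * i]; s += dsrc[2 * i]; }
        }
      db[co] += s;
    }
    sgemm_wrap("T", "N", Cin, Cout, N, 1.0f, xf.data(), N, sub.data(), N,
               0.0f, tmp.data(), Cin);
    for (int co = 0; co < Cout; ++co)
      for (int ci = 0; ci < Cin; ++ci)
        dW[a + 2 * (bb + 2 * ((R_xlen_t)cc + 2 * ((R_xlen_t)ci + (R_xlen_t)Cin * co)))] =
          (double)tmp[ci + (R_xlen_t)Cin * co];
    if (need_dx) {
      for (int co = 0; co < Cout; ++co)
        for (int ci = 0; ci < Cin; ++ci)
          Wm[ci + (R_xlen_t)Cin * co] =
            (float)W[a + 2 * (bb + 2 * ((R_xlen_t)cc + 2 * ((R_xlen_t)ci + (R_xlen_t)Cin * co)))];
      sgemm_wrap("N", "T", N, Cin, Cout, 1.0f, sub.data(), N, Wm.data(), Cin,
                 1.0f, dxa.data(), N);
    }
  }
  if (!need_dx) return List::create(_["dW"] = dW, _["db"] = db);
  NumericVector dx((R_xlen_t)N * Cin);
  for (R_xlen_t i = 0; i < (R_xlen_t)N * Cin; ++i) dx[i] = (double)dxa[i];
  dx.attr("dim") = IntegerVector::create(X, Y, Z, Cin);
  return List::create(_["dW"] = dW, _["db"] = db, _["dx"] = dx);
}
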