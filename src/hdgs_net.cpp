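// Compiled float32 engine for the hybrid dilated/gated/depthwise-separable
// convolutional network.
//
// Activations are stored channel x (W*B) fmat with POSITION-MAJOR columns:
// column index = w*B + b, where b = sample*16 + row indexes the B = N*16
// independent convolution lanes (the 16 dinucleotide rows of the input are
// independent lanes for 1xK kernels, exactly as in a 16 x W x C tensor with
// height-1 kernels). With this layout every dilation tap of a same-padded
// 1xK convolution is a single contiguous GEMM: shifting the position w by a
// tap offset o shifts the column block by o*B, so the K taps accumulate via
// K sgemm calls with beta = 1 and no im2col gather. Widths change only at
// the 1x3 stride-3 max pools.
#include <RcppArmadillo.h>
#include <memory>
#include <string>
#include <vector>
#include <cmath>
#include <cstring>
#ifdef __GLIBC__
#include <malloc.h>
#endif

// The engine allocates and frees large (10-100 MB) activation buffers every
// batch; keep glibc from returning them to the kernel each time, which would
// pay the first-touch page-fault cost on every reallocation.
static void tune_allocator() {
#ifdef __GLIBC__
  static bool done = false;
  if (!done) {
    mallopt(M_MMAP_THRESHOLD, 1 << 30);
    mallopt(M_TRIM_THRESHOLD, 1 << 30);
    done = true;
  }
#endif
}

using namespace arma;

// accumulating single-precision GEMM on raw column-major blocks
static void gemm_f(char ta, char tb, int m, int n, int k, float alpha,
                   const float* a, int lda, const float* b, int ldb, float beta,
                   float* c, int ldc) {
  if (m == 0 || n == 0) return;
  arma::blas_int M = m, N = n, K = k, LDA = lda, LDB = ldb, LDC = ldc;
  arma::blas::gemm<float>(&ta, &tb, &M, &N, &K, &alpha, a, &LDA, b, &LDB,
                          &beta, c, &LDC);
}

// ---------------------------------------------------------------------------
// deterministic RNG (engine state is part of the net; independent of R's)
struct RNG {
  uint64_t s;
  explicit RNG(uint64_t seed) : s(seed * 2654435769u + 1442695040888963407ULL) {}
  uint64_t next() { // splitmix64
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  float unif() { return (float)((next() >> 40) * (1.0 / 16777216.0)); } // [0,1)
  float unif(float a, float b) { return a + (b - a) * unif(); }
};

// ---------------------------------------------------------------------------
// trainable parameter with Adam state
struct Param {
  fmat w, m, v;
  std::string name;
  void init(int r, int c, const std::string& nm) {
    w.set_size(r, c); m.zeros(r, c); v.zeros(r, c); name = nm;
  }
  void adam(const fmat& g, float lr, int t) {
    m = 0.9f * m + 0.1f * g;
    v = 0.999f * v + 0.001f * (g % g);
    float bc1 = 1.0f - std::pow(0.9f, (float)t);
    float bc2 = 1.0f - std::pow(0.999f, (float)t);
    w -= lr * (m / bc1) / (sqrt(v / bc2) + 1e-7f);
  }
};

// fast single-precision exp/sigmoid (polynomial 2^f, ~1e-6 relative error);
// the gate nonlinearity is evaluated tens of millions of times per batch
static inline float fast_exp(float x) {
  x = x < -87.0f ? -87.0f : (x > 87.0f ? 87.0f : x);
  const float t = x * 1.44269504088896f;
  const float fi = std::floor(t);
  const float f = t - fi;
  const float p = 1.0f + f * (0.693147182f + f * (0.240226507f +
                  f * (0.055504109f + f * (0.009618129f +
                  f * (0.001333356f + f * 0.000154035f)))));
  union { uint32_t u; float fl; } bits;
  bits.u = (uint32_t)((int)fi + 127) << 23;
  return p * bits.fl;
}
static inline float fast_sigmoid(float x) { return 1.0f / (1.0f + fast_exp(-x)); }

// tap offsets of a centred 1xK kernel with dilation d, clipped to width W:
// tap k (0-based) reads position w + (k - K/2)*d
struct TapRange {
  int o, wlo, whi; // valid output positions w in [wlo, whi)
};
static TapRange tap_range(int k, int K, int d, int W) {
  TapRange t;
  t.o = (k - K / 2) * d;
  t.wlo = std::max(0, -t.o);
  t.whi = std::min(W, W - t.o);
  return t;
}

// ---------------------------------------------------------------------------
// full 1xK convolution (same padding, dilation d)
struct Conv {
  int K = 1, d = 1, Cin = 1, Cout = 1;
  Param W, b;
  void init(RNG& rng, const std::string& nm) {
    W.init(Cout, K * Cin, nm + ".kernel");
    const float lim = std::sqrt(6.0f / (float)(K * Cin + K * Cout));
    for (auto& x : W.w) x = rng.unif(-lim, lim);
    b.init(Cout, 1, nm + ".bias");
    b.w.zeros();
  }
  // For the 1-channel input stage the per-tap GEMMs are pure memory traffic;
  // gathering a transposed patch matrix (one contiguous block copy per tap)
  // turns the K accumulation passes into a single GEMM.
  bool thin() const { return Cin == 1; }
  void build_patches_t(const fmat& X, int B, int Wd, fmat& XcT) const {
    XcT.zeros(X.n_cols, K); // row j = patch of column j; column k contiguous
    for (int k = 0; k < K; ++k) {
      const TapRange t = tap_range(k, K, d, Wd);
      if (t.whi <= t.wlo) continue;
      std::memcpy(XcT.colptr(k) + (uword)t.wlo * B,
                  X.colptr((uword)(t.wlo + t.o) * B),
                  sizeof(float) * (uword)(t.whi - t.wlo) * B);
    }
  }
  fmat fwd(const fmat& X, int B, int Wd) const {
    fmat Y(Cout, X.n_cols);
    const fvec bv = b.w.col(0);
    Y.each_col() = bv;
    if (thin()) {
      fmat XcT;
      build_patches_t(X, B, Wd, XcT);
      gemm_f('N', 'T', Cout, X.n_cols, K, 1.0f, W.w.memptr(), Cout,
             XcT.memptr(), X.n_cols, 1.0f, Y.memptr(), Cout);
      return Y;
    }
    for (int k = 0; k < K; ++k) {
      const TapRange t = tap_range(k, K, d, Wd);
      if (t.whi <= t.wlo) continue;
      gemm_f('N', 'N', Cout, (t.whi - t.wlo) * B, Cin, 1.0f,
           W.w.colptr((uword)k * Cin), Cout,
           X.colptr((uword)(t.wlo + t.o) * B), Cin, 1.0f,
           Y.colptr((uword)t.wlo * B), Cout);
    }
    return Y;
  }
  fmat bwd(const fmat& G, const fmat& X, int B, int Wd, float lr, int t_adam) {
    fmat dW(Cout, (uword)K * Cin, fill::zeros);
    fmat dX(Cin, X.n_cols, fill::zeros);
    if (thin()) {
      fmat XcT;
      build_patches_t(X, B, Wd, XcT);
      gemm_f('N', 'N', Cout, K, G.n_cols, 1.0f, G.memptr(), Cout,
             XcT.memptr(), G.n_cols, 0.0f, dW.memptr(), Cout);
      fmat dXcT(G.n_cols, K);
      gemm_f('T', 'N', G.n_cols, K, Cout, 1.0f, G.memptr(), Cout,
             W.w.memptr(), Cout, 0.0f, dXcT.memptr(), G.n_cols);
      for (int k = 0; k < K; ++k) {
        const TapRange t = tap_range(k, K, d, Wd);
        if (t.whi <= t.wlo) continue;
        float* dst = dX.colptr((uword)(t.wlo + t.o) * B);
        const float* src = dXcT.colptr(k) + (uword)t.wlo * B;
        const uword n = (uword)(t.whi - t.wlo) * B;
        for (uword j = 0; j < n; ++j) dst[j] += src[j];
      }
    } else {
      for (int k = 0; k < K; ++k) {
        const TapRange t = tap_range(k, K, d, Wd);
        if (t.whi <= t.wlo) continue;
        const int n = (t.whi - t.wlo) * B;
        gemm_f('N', 'T', Cout, Cin, n, 1.0f,
             G.colptr((uword)t.wlo * B), Cout,
             X.colptr((uword)(t.wlo + t.o) * B), Cin, 0.0f,
             dW.colptr((uword)k * Cin), Cout);
        gemm_f('T', 'N', Cin, n, Cout, 1.0f,
             W.w.colptr((uword)k * Cin), Cout,
             G.colptr((uword)t.wlo * B), Cout, 1.0f,
             dX.colptr((uword)(t.wlo + t.o) * B), Cin);
      }
    }
    fmat db = sum(G, 1);
    W.adam(dW, lr, t_adam);
    b.adam(db, lr, t_adam);
    return dX;
  }
};

// depthwise (1xK per input channel, no bias) + pointwise (1x1, bias)
struct SepConv {
  int K = 1, d = 1, Cin = 1, Cout = 1;
  Param Wd_, Wp, b;
  fmat Ydw; // cache for the pointwise weight gradient
  void init(RNG& rng, const std::string& nm) {
    Wd_.init(Cin, K, nm + ".depthwise");
    const float limd = std::sqrt(6.0f / (float)(2 * K));
    for (auto& x : Wd_.w) x = rng.unif(-limd, limd);
    Wp.init(Cout, Cin, nm + ".pointwise");
    const float limp = std::sqrt(6.0f / (float)(Cin + Cout));
    for (auto& x : Wp.w) x = rng.unif(-limp, limp);
    b.init(Cout, 1, nm + ".bias");
    b.w.zeros();
  }
  fmat fwd(const fmat& X, int B, int Wdth) {
    Ydw.zeros(Cin, X.n_cols);
    for (int k = 0; k < K; ++k) {
      const TapRange t = tap_range(k, K, d, Wdth);
      if (t.whi <= t.wlo) continue;
      fmat blk = X.cols((uword)(t.wlo + t.o) * B, (uword)(t.whi + t.o) * B - 1);
      const fvec wk = Wd_.w.col(k);
      blk.each_col() %= wk;
      Ydw.cols((uword)t.wlo * B, (uword)t.whi * B - 1) += blk;
    }
    fmat Y(Cout, X.n_cols);
    const fvec bv = b.w.col(0);
    Y.each_col() = bv;
    gemm_f('N', 'N', Cout, X.n_cols, Cin, 1.0f, Wp.w.memptr(), Cout,
         Ydw.memptr(), Cin, 1.0f, Y.memptr(), Cout);
    return Y;
  }
  fmat bwd(const fmat& G, const fmat& X, int B, int Wdth, float lr, int t_adam) {
    fmat dWp(Cout, Cin);
    gemm_f('N', 'T', Cout, Cin, G.n_cols, 1.0f, G.memptr(), Cout,
         Ydw.memptr(), Cin, 0.0f, dWp.memptr(), Cout);
    fmat db = sum(G, 1);
    fmat dYdw(Cin, G.n_cols);
    gemm_f('T', 'N', Cin, G.n_cols, Cout, 1.0f, Wp.w.memptr(), Cout,
         G.memptr(), Cout, 0.0f, dYdw.memptr(), Cin);
    Ydw.reset();
    fmat dWd(Cin, K, fill::zeros);
    fmat dX(Cin, X.n_cols, fill::zeros);
    for (int k = 0; k < K; ++k) {
      const TapRange t = tap_range(k, K, d, Wdth);
      if (t.whi <= t.wlo) continue;
      const uword a = (uword)t.wlo * B, bcol = (uword)t.whi * B - 1;
      const uword as = (uword)(t.wlo + t.o) * B, bs = (uword)(t.whi + t.o) * B - 1;
      dWd.col(k) = sum(dYdw.cols(a, bcol) % X.cols(as, bs), 1);
      fmat blk = dYdw.cols(a, bcol);
      const fvec wk = Wd_.w.col(k);
      blk.each_col() %= wk;
      dX.cols(as, bs) += blk;
    }
    Wd_.adam(dWd, lr, t_adam);
    Wp.adam(dWp, lr, t_adam);
    b.adam(db, lr, t_adam);
    return dX;
  }
};

// ---------------------------------------------------------------------------
// a module branch: gated ("gc", feature path x sigmoid gate path) or
// dilated+ReLU ("dc"); either may be depthwise separable. Non-separable
// gated branches run feature and gate as one stacked convolution (2*Cout
// output rows) so both paths share each tap's GEMM.
struct Branch {
  std::string type; // "gc" | "dc"
  bool sep = false;
  int Cout = 0;
  Conv cf;
  SepConv sf, sg;
  fmat Fc, Gt, Zc; // caches

  void build(const std::string& ty, int K, int d, int Cin, int Co, bool sep_,
             RNG& rng, const std::string& nm) {
    type = ty; sep = sep_; Cout = Co;
    if (type == "gc") {
      if (!sep) {
        cf.K = K; cf.d = d; cf.Cin = Cin; cf.Cout = 2 * Co;
        cf.init(rng, nm + ".gc");
      } else {
        sf.K = K; sf.d = d; sf.Cin = Cin; sf.Cout = Co; sf.init(rng, nm + ".gc_feature");
        sg.K = K; sg.d = d; sg.Cin = Cin; sg.Cout = Co; sg.init(rng, nm + ".gc_gate");
      }
    } else {
      if (!sep) {
        cf.K = K; cf.d = d; cf.Cin = Cin; cf.Cout = Co; cf.init(rng, nm + ".dc");
      } else {
        sf.K = K; sf.d = d; sf.Cin = Cin; sf.Cout = Co; sf.init(rng, nm + ".dc");
      }
    }
  }
  // writes the branch output into rows [r0, r0+Cout) of the concat buffer
  void fwd_into(const fmat& X, int B, int Wd, bool train, fmat& Cc, int r0) {
    const uword cols = X.n_cols;
    if (type == "gc") {
      if (!sep) {
        fmat Y = cf.fwd(X, B, Wd); // feature rows stacked over gate rows
        if (train) { Fc.set_size(Cout, cols); Gt.set_size(Cout, cols); }
        for (uword j = 0; j < cols; ++j) {
          const float* y = Y.colptr(j);
          float* out = Cc.colptr(j) + r0;
          float* fc = train ? Fc.colptr(j) : nullptr;
          float* gt = train ? Gt.colptr(j) : nullptr;
          for (int c = 0; c < Cout; ++c) {
            const float f = y[c];
            const float g = fast_sigmoid(y[Cout + c]);
            out[c] = f * g;
            if (train) { fc[c] = f; gt[c] = g; }
          }
        }
      } else {
        fmat F = sf.fwd(X, B, Wd);
        fmat Zg = sg.fwd(X, B, Wd);
        if (train) Gt.set_size(Cout, cols);
        for (uword j = 0; j < cols; ++j) {
          const float* f = F.colptr(j);
          const float* zg = Zg.colptr(j);
          float* out = Cc.colptr(j) + r0;
          float* gt = train ? Gt.colptr(j) : nullptr;
          for (int c = 0; c < Cout; ++c) {
            const float g = fast_sigmoid(zg[c]);
            out[c] = f[c] * g;
            if (train) gt[c] = g;
          }
        }
        if (train) Fc = std::move(F);
      }
      return;
    }
    fmat Z = sep ? sf.fwd(X, B, Wd) : cf.fwd(X, B, Wd);
    for (uword j = 0; j < cols; ++j) {
      const float* z = Z.colptr(j);
      float* out = Cc.colptr(j) + r0;
      for (int c = 0; c < Cout; ++c) out[c] = z[c] > 0.0f ? z[c] : 0.0f;
    }
    if (train) Zc = std::move(Z);
  }
  // reads rows [r0, r0+Cout) of the concat gradient, returns dX
  fmat bwd_from(const fmat& dC, int r0, const fmat& X, int B, int Wd,
                float lr, int t) {
    const uword cols = dC.n_cols;
    if (type == "gc") {
      if (!sep) {
        fmat Gs(2 * Cout, cols); // d(feature) stacked over d(gate preact)
        for (uword j = 0; j < cols; ++j) {
          const float* g = dC.colptr(j) + r0;
          const float* fc = Fc.colptr(j);
          const float* gt = Gt.colptr(j);
          float* gs = Gs.colptr(j);
          for (int c = 0; c < Cout; ++c) {
            gs[c] = g[c] * gt[c];
            gs[Cout + c] = g[c] * fc[c] * gt[c] * (1.0f - gt[c]);
          }
        }
        Fc.reset(); Gt.reset();
        return cf.bwd(Gs, X, B, Wd, lr, t);
      }
      fmat dF(Cout, cols), dZg(Cout, cols);
      for (uword j = 0; j < cols; ++j) {
        const float* g = dC.colptr(j) + r0;
        const float* fc = Fc.colptr(j);
        const float* gt = Gt.colptr(j);
        float* df = dF.colptr(j);
        float* dz = dZg.colptr(j);
        for (int c = 0; c < Cout; ++c) {
          df[c] = g[c] * gt[c];
          dz[c] = g[c] * fc[c] * gt[c] * (1.0f - gt[c]);
        }
      }
      Fc.reset(); Gt.reset();
      return sf.bwd(dF, X, B, Wd, lr, t) + sg.bwd(dZg, X, B, Wd, lr, t);
    }
    fmat dZ(Cout, cols);
    for (uword j = 0; j < cols; ++j) {
      const float* g = dC.colptr(j) + r0;
      const float* z = Zc.colptr(j);
      float* dz = dZ.colptr(j);
      for (int c = 0; c < Cout; ++c) dz[c] = z[c] > 0.0f ? g[c] : 0.0f;
    }
    Zc.reset();
    return sep ? sf.bwd(dZ, X, B, Wd, lr, t) : cf.bwd(dZ, X, B, Wd, lr, t);
  }
  void params(std::vector<Param*>& out) {
    if (type == "gc" && !sep) { out.push_back(&cf.W); out.push_back(&cf.b); }
    else if (type == "gc") {
      out.push_back(&sf.Wd_); out.push_back(&sf.Wp); out.push_back(&sf.b);
      out.push_back(&sg.Wd_); out.push_back(&sg.Wp); out.push_back(&sg.b);
    } else if (!sep) { out.push_back(&cf.W); out.push_back(&cf.b); }
    else { out.push_back(&sf.Wd_); out.push_back(&sf.Wp); out.push_back(&sf.b); }
  }
};

// ---------------------------------------------------------------------------
struct BatchNorm {
  int C = 0;
  float mom = 0.9f, eps = 1e-3f;
  Param gamma, beta;
  fvec rmean, rvar;
  fmat xhat;
  fvec invstd;
  float n = 1.0f;
  void init(int C_, const std::string& nm) {
    C = C_;
    gamma.init(C, 1, nm + ".gamma"); gamma.w.ones();
    beta.init(C, 1, nm + ".beta");   beta.w.zeros();
    rmean.zeros(C); rvar.ones(C);
  }
  fmat fwd(const fmat& X, bool train) {
    if (train) {
      const fvec mu = mean(X, 1);
      fmat Xd = X.each_col() - mu;
      const fvec var = mean(Xd % Xd, 1);
      rmean = mom * rmean + (1.0f - mom) * mu;
      rvar = mom * rvar + (1.0f - mom) * var;
      invstd = 1.0f / sqrt(var + eps);
      Xd.each_col() %= invstd;
      xhat = Xd;
      n = (float)X.n_cols;
      fmat Y = Xd.each_col() % fvec(gamma.w.col(0));
      Y.each_col() += fvec(beta.w.col(0));
      return Y;
    }
    const fvec is = 1.0f / sqrt(rvar + eps);
    fmat Y = X.each_col() - rmean;
    Y.each_col() %= (is % fvec(gamma.w.col(0)));
    Y.each_col() += fvec(beta.w.col(0));
    return Y;
  }
  fmat bwd(const fmat& G, float lr, int t) {
    fmat dgamma = sum(G % xhat, 1);
    fmat dbeta = sum(G, 1);
    fmat dX = G;
    dX.each_col() -= fvec(dbeta.col(0) / n);
    dX -= xhat.each_col() % fvec(dgamma.col(0) / n);
    dX.each_col() %= (fvec(gamma.w.col(0)) % invstd);
    xhat.reset();
    gamma.adam(dgamma, lr, t);
    beta.adam(dbeta, lr, t);
    return dX;
  }
};

struct Dropout {
  float rate = 0.0f;
  fmat mask;
  fmat fwd(const fmat& X, bool train, RNG& rng) {
    if (!train || rate <= 0.0f) { mask.reset(); return X; }
    const float keep = 1.0f - rate;
    const float inv = 1.0f / keep;
    const uint32_t thr = (uint32_t)(keep * 65536.0f);
    mask.set_size(X.n_rows, X.n_cols);
    float* m = mask.memptr();
    const uword n = mask.n_elem;
    uword i = 0;
    while (i + 4 <= n) { // 16 random bits per element, 4 elements per draw
      uint64_t r = rng.next();
      m[i++] = ((r & 0xFFFF) < thr) ? inv : 0.0f;
      m[i++] = (((r >> 16) & 0xFFFF) < thr) ? inv : 0.0f;
      m[i++] = (((r >> 32) & 0xFFFF) < thr) ? inv : 0.0f;
      m[i++] = (((r >> 48) & 0xFFFF) < thr) ? inv : 0.0f;
    }
    while (i < n) m[i++] = ((rng.next() & 0xFFFF) < thr) ? inv : 0.0f;
    return X % mask;
  }
  fmat bwd(const fmat& G) const {
    if (mask.is_empty()) return G;
    return G % mask;
  }
};

struct MaxPool { // 1x3, stride 3, valid; position-major blocks are contiguous
  int Win = 0, Wout = 0;
  Mat<unsigned char> sel;
  fmat fwd(const fmat& X, int B) {
    const uword C = X.n_rows;
    const uword blk = C * (uword)B; // elements per position block
    fmat Y(C, (uword)B * Wout);
    sel.set_size(C, (uword)B * Wout);
    for (int w = 0; w < Wout; ++w) {
      const float* p0 = X.colptr((uword)(3 * w) * B);
      const float* p1 = p0 + blk;
      const float* p2 = p1 + blk;
      float* py = Y.colptr((uword)w * B);
      unsigned char* ps = sel.colptr((uword)w * B);
      for (uword i = 0; i < blk; ++i) {
        float m = p0[i]; unsigned char j = 0;
        if (p1[i] > m) { m = p1[i]; j = 1; }
        if (p2[i] > m) { m = p2[i]; j = 2; }
        py[i] = m; ps[i] = j;
      }
    }
    return Y;
  }
  fmat bwd(const fmat& G, int B) const {
    const uword C = G.n_rows;
    const uword blk = C * (uword)B;
    fmat dX(C, (uword)B * Win, fill::zeros);
    for (int w = 0; w < Wout; ++w) {
      float* p = dX.colptr((uword)(3 * w) * B);
      const float* pg = G.colptr((uword)w * B);
      const unsigned char* ps = sel.colptr((uword)w * B);
      for (uword i = 0; i < blk; ++i) p[i + (uword)ps[i] * blk] += pg[i];
    }
    return dX;
  }
};

struct Module {
  std::vector<Branch> branches;
  BatchNorm bn;
  Dropout drop;
  MaxPool pool;
  int Cin = 0, Cout = 0, Win = 0, Wout = 0;
  fmat Xin;
  fmat fwd(const fmat& X, int B, bool train, RNG& rng) {
    if (train) Xin = X;
    fmat Cc(Cout, X.n_cols);
    int r0 = 0;
    for (auto& br : branches) {
      br.fwd_into(X, B, Win, train, Cc, r0);
      r0 += br.Cout;
    }
    fmat Z = bn.fwd(Cc, train);
    Cc.reset();
    fmat D = drop.fwd(Z, train, rng);
    Z.reset();
    return pool.fwd(D, B);
  }
  fmat bwd(const fmat& G, int B, float lr, int t) {
    fmat dD = pool.bwd(G, B);
    fmat dZ = drop.bwd(dD);
    dD.reset();
    fmat dC = bn.bwd(dZ, lr, t);
    dZ.reset();
    fmat dX(Cin, Xin.n_cols, fill::zeros);
    int r0 = 0;
    for (auto& br : branches) {
      dX += br.bwd_from(dC, r0, Xin, B, Win, lr, t);
      r0 += br.Cout;
    }
    Xin.reset();
    return dX;
  }
};

struct Dense {
  int In = 0, Out = 0;
  Param W, b;
  fmat Xc;
  void init(RNG& rng, const std::string& nm) {
    W.init(Out, In, nm + ".kernel");
    const float lim = std::sqrt(6.0f / (float)(In + Out));
    for (auto& x : W.w) x = rng.unif(-lim, lim);
    b.init(Out, 1, nm + ".bias");
    b.w.zeros();
  }
  fmat fwd(const fmat& X, bool cache) {
    if (cache) Xc = X;
    fmat Y = W.w * X;
    Y.each_col() += fvec(b.w.col(0));
    return Y;
  }
  fmat bwd(const fmat& G, float lr, int t) {
    fmat dW = G * Xc.t();
    fmat db = sum(G, 1);
    fmat dX = W.w.t() * G;
    Xc.reset();
    W.adam(dW, lr, t);
    b.adam(db, lr, t);
    return dX;
  }
};

// ---------------------------------------------------------------------------
struct Net {
  int H = 16, W0 = 146;
  float dropout_rate = 0.4f;
  std::string head = "regression";
  BatchNorm bn0;
  std::vector<Module> modules;
  std::vector<Dense> dense;
  int flatC = 0, flatW = 0, flatDim = 0;
  RNG rng;
  int adam_t = 0;
  std::vector<fmat> zcache;

  explicit Net(uint64_t seed) : rng(seed) {}

  void collect(std::vector<Param*>& ps) {
    ps.push_back(&bn0.gamma); ps.push_back(&bn0.beta);
    for (auto& m : modules) {
      for (auto& br : m.branches) br.params(ps);
      ps.push_back(&m.bn.gamma); ps.push_back(&m.bn.beta);
    }
    for (auto& d : dense) { ps.push_back(&d.W); ps.push_back(&d.b); }
  }
  void buffers(std::vector<fvec*>& bs) {
    bs.push_back(&bn0.rmean); bs.push_back(&bn0.rvar);
    for (auto& m : modules) { bs.push_back(&m.bn.rmean); bs.push_back(&m.bn.rvar); }
  }

  // flatten (C, Wf*B) with col = w*B + n*H + r  ->  (H*Wf*C, N);
  // feature index = (r*Wf + w)*C + c
  fmat flatten(const fmat& X, int N) const {
    fmat Y(flatDim, N);
    for (int n = 0; n < N; ++n)
      for (int r = 0; r < H; ++r)
        for (int w = 0; w < flatW; ++w)
          std::memcpy(Y.colptr(n) + ((uword)r * flatW + w) * flatC,
                      X.colptr(((uword)w * N + n) * H + r),
                      sizeof(float) * flatC);
    return Y;
  }
  fmat unflatten(const fmat& G, int N) const {
    fmat dX(flatC, (uword)N * H * flatW);
    for (int n = 0; n < N; ++n)
      for (int r = 0; r < H; ++r)
        for (int w = 0; w < flatW; ++w)
          std::memcpy(dX.colptr((uword)w * N * H + (uword)n * H + r),
                      G.colptr(n) + ((uword)r * flatW + w) * flatC,
                      sizeof(float) * flatC);
    return dX;
  }

  fmat fwd(const fmat& X0, int N, bool train) {
    const int B = N * H;
    fmat a = bn0.fwd(X0, train);
    for (auto& m : modules) a = m.fwd(a, B, train, rng);
    fmat f = flatten(a, N);
    a.reset();
    zcache.clear();
    for (size_t i = 0; i < dense.size(); ++i) {
      fmat z = dense[i].fwd(f, true);
      if (i + 1 < dense.size()) {
        if (train) zcache.push_back(z);
        z.transform([](float x) { return x > 0.0f ? x : 0.0f; });
      }
      f = std::move(z);
    }
    return f; // pre-activation of the head
  }

  static fmat head_act(const fmat& z, const std::string& head) {
    fmat p = z;
    if (head == "regression")
      p.transform([](float x) { return x > 0.0f ? x : 0.0f; });
    else
      p = 1.0f / (1.0f + exp(-p));
    return p;
  }

  void bwd(const fmat& dz_last, int N, float lr) {
    ++adam_t;
    const int B = N * H;
    fmat g = dz_last;
    for (int i = (int)dense.size() - 1; i >= 0; --i) {
      g = dense[i].bwd(g, lr, adam_t);
      if (i > 0) {
        const fmat& z = zcache[i - 1];
        g.elem(find(z <= 0.0f)).zeros();
      }
    }
    zcache.clear();
    g = unflatten(g, N);
    for (int i = (int)modules.size() - 1; i >= 0; --i) g = modules[i].bwd(g, B, lr, adam_t);
    bn0.bwd(g, lr, adam_t);
  }
};

// ---------------------------------------------------------------------------
static Net* build_net(const Rcpp::List& cfg) {
  const int H = Rcpp::as<int>(cfg["input_height"]);
  const int W0 = Rcpp::as<int>(cfg["input_width"]);
  const double drop = Rcpp::as<double>(cfg["dropout"]);
  const std::string head = Rcpp::as<std::string>(cfg["head"]);
  const uint64_t seed = (uint64_t)Rcpp::as<double>(cfg["seed"]);
  std::unique_ptr<Net> net(new Net(seed));
  net->H = H; net->W0 = W0;
  net->dropout_rate = (float)drop;
  net->head = head;
  net->bn0.init(1, "input_bn");

  Rcpp::List mods = cfg["modules"];
  int W = W0, Cin = 1;
  for (int i = 0; i < mods.size(); ++i) {
    Rcpp::List ms = mods[i];
    Rcpp::List brs = ms["branches"];
    Module m;
    m.Cin = Cin; m.Win = W;
    const std::string mnm = "module" + std::to_string(i + 1);
    int Cout = 0;
    for (int j = 0; j < brs.size(); ++j) {
      Rcpp::List bs = brs[j];
      Branch br;
      br.build(Rcpp::as<std::string>(bs["type"]),
               Rcpp::as<int>(bs["kernel"]),
               Rcpp::as<int>(bs["dilation"]),
               Cin,
               Rcpp::as<int>(bs["channels"]),
               Rcpp::as<bool>(bs["separable"]),
               net->rng,
               mnm + ".branch" + std::to_string(j + 1));
      Cout += br.Cout;
      m.branches.push_back(std::move(br));
    }
    m.Cout = Cout;
    m.bn.init(Cout, mnm + ".bn");
    m.drop.rate = (float)drop;
    if (W < 3)
      Rcpp::stop("stage '%s': width %d is below the 1x3 pooling footprint", mnm.c_str(), W);
    m.pool.Win = W;
    m.pool.Wout = (W - 3) / 3 + 1;
    W = m.pool.Wout;
    Cin = Cout;
    net->modules.push_back(std::move(m));
  }
  net->flatC = Cin;
  net->flatW = W;
  net->flatDim = H * W * Cin;

  Rcpp::IntegerVector fc = cfg["fc"];
  int In = net->flatDim;
  for (int i = 0; i < fc.size(); ++i) {
    Dense d; d.In = In; d.Out = fc[i];
    d.init(net->rng, "dense" + std::to_string(i + 1));
    In = fc[i];
    net->dense.push_back(std::move(d));
  }
  Dense dout; dout.In = In; dout.Out = 1;
  dout.init(net->rng, "dense_out");
  // regression head: start the output bias at the dMean genome mean (1) so
  // the ReLU output is live from the first step (an all-negative start has
  // zero gradient and would never recover)
  if (head == "regression") dout.b.w.fill(1.0f);
  net->dense.push_back(std::move(dout));
  return net.release();
}

// build the (1, W0*B) position-major input for sample indices idx (0-based)
// from the R feature array with dim (N, H, W0); lane b = i*H + r
static fmat make_input(const Rcpp::IntegerVector& feat, const Rcpp::IntegerVector& dims,
                       const std::vector<int>& idx, int H, int W0) {
  const int Ntot = dims[0];
  if (dims[1] != H || dims[2] != W0)
    Rcpp::stop("feature array is %d x %d but the model expects %d x %d",
               dims[1], dims[2], H, W0);
  const int n = (int)idx.size();
  const uword B = (uword)n * H;
  fmat X0(1, (uword)W0 * B);
  float* x = X0.memptr();
  const int* f = feat.begin();
  for (int w = 0; w < W0; ++w)
    for (int i = 0; i < n; ++i) {
      const uword base = (uword)w * B + (uword)i * H;
      const int s = idx[i];
      for (int r = 0; r < H; ++r)
        x[base + r] = (float)f[s + (uword)Ntot * (r + (uword)H * w)];
    }
  return X0;
}

// [[Rcpp::export(name = ".hdgs_build_cpp")]]
SEXP hdgs_build_cpp(Rcpp::List cfg) {
  tune_allocator();
  Rcpp::XPtr<Net> p(build_net(cfg), true);
  return p;
}

// [[Rcpp::export(name = ".hdgs_nparams_cpp")]]
double hdgs_nparams_cpp(SEXP ptr) {
  Rcpp::XPtr<Net> net(ptr);
  std::vector<Param*> ps;
  net->collect(ps);
  double tot = 0;
  for (auto* p : ps) tot += (double)p->w.n_elem;
  return tot;
}

// [[Rcpp::export(name = ".hdgs_manifest_cpp")]]
Rcpp::DataFrame hdgs_manifest_cpp(SEXP ptr) {
  Rcpp::XPtr<Net> net(ptr);
  std::vector<Param*> ps;
  net->collect(ps);
  std::vector<std::string> nm;
  std::vector<double> cnt;
  for (auto* p : ps) { nm.push_back(p->name); cnt.push_back((double)p->w.n_elem); }
  return Rcpp::DataFrame::create(Rcpp::Named("parameter") = nm,
                                 Rcpp::Named("count") = cnt,
                                 Rcpp::Named("stringsAsFactors") = false);
}

// [[Rcpp::export(name = ".hdgs_shape_trace_cpp")]]
Rcpp::DataFrame hdgs_shape_trace_cpp(SEXP ptr) {
  Rcpp::XPtr<Net> net(ptr);
  std::vector<std::string> st;
  std::vector<int> wd, ch;
  st.push_back("input"); wd.push_back(net->W0); ch.push_back(1);
  int i = 1;
  for (auto& m : net->modules) {
    st.push_back("module" + std::to_string(i++));
    wd.push_back(m.pool.Wout);
    ch.push_back(m.Cout);
  }
  return Rcpp::DataFrame::create(Rcpp::Named("stage") = st,
                                 Rcpp::Named("width") = wd,
                                 Rcpp::Named("channels") = ch,
                                 Rcpp::Named("stringsAsFactors") = false);
}

// [[Rcpp::export(name = ".hdgs_forward_cpp")]]
Rcpp::NumericVector hdgs_forward_cpp(SEXP ptr, Rcpp::IntegerVector feat,
                                     Rcpp::IntegerVector idx, bool train,
                                     int chunk = 128) {
  Rcpp::XPtr<Net> net(ptr);
  Rcpp::IntegerVector dims = feat.attr("dim");
  const int n = idx.size();
  Rcpp::NumericVector out(n);
  for (int at = 0; at < n; at += chunk) {
    const int m = std::min(chunk, n - at);
    std::vector<int> ii(m);
    for (int i = 0; i < m; ++i) ii[i] = idx[at + i];
    fmat X0 = make_input(feat, dims, ii, net->H, net->W0);
    fmat z = net->fwd(X0, m, train);
    fmat p = Net::head_act(z, net->head);
    for (int i = 0; i < m; ++i) out[at + i] = (double)p(0, i);
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// weight get/set (trainable parameters + batch-norm running buffers)
// [[Rcpp::export(name = ".hdgs_get_weights_cpp")]]
Rcpp::List hdgs_get_weights_cpp(SEXP ptr) {
  Rcpp::XPtr<Net> net(ptr);
  std::vector<Param*> ps;
  net->collect(ps);
  Rcpp::List w(ps.size());
  Rcpp::CharacterVector wn(ps.size());
  for (size_t i = 0; i < ps.size(); ++i) {
    Param* p = ps[i];
    Rcpp::NumericMatrix m(p->w.n_rows, p->w.n_cols);
    for (uword j = 0; j < p->w.n_elem; ++j) m[j] = p->w(j);
    w[i] = m;
    wn[i] = p->name;
  }
  w.names() = wn;
  std::vector<fvec*> bs;
  net->buffers(bs);
  Rcpp::List bl(bs.size());
  Rcpp::CharacterVector bn(bs.size());
  for (size_t i = 0; i < bs.size(); ++i) {
    Rcpp::NumericVector v(bs[i]->n_elem);
    for (uword j = 0; j < bs[i]->n_elem; ++j) v[j] = (*bs[i])(j);
    bl[i] = v;
    bn[i] = "buffer" + std::to_string(i + 1);
  }
  bl.names() = bn;
  return Rcpp::List::create(Rcpp::Named("trainable") = w, Rcpp::Named("buffers") = bl);
}

// [[Rcpp::export(name = ".hdgs_set_weights_cpp")]]
void hdgs_set_weights_cpp(SEXP ptr, Rcpp::List weights) {
  Rcpp::XPtr<Net> net(ptr);
  std::vector<Param*> ps;
  net->collect(ps);
  Rcpp::List w = weights["trainable"];
  for (auto* p : ps) {
    if (!w.containsElementNamed(p->name.c_str()))
      Rcpp::stop("weight list lacks parameter '%s'", p->name.c_str());
    Rcpp::NumericMatrix m = w[p->name];
    if ((uword)m.nrow() != p->w.n_rows || (uword)m.ncol() != p->w.n_cols)
      Rcpp::stop("parameter '%s' has shape %d x %d, expected %d x %d",
                 p->name.c_str(), m.nrow(), m.ncol(), (int)p->w.n_rows, (int)p->w.n_cols);
    for (uword j = 0; j < p->w.n_elem; ++j) p->w(j) = (float)m[j];
  }
  std::vector<fvec*> bs;
  net->buffers(bs);
  Rcpp::List bl = weights["buffers"];
  for (size_t i = 0; i < bs.size(); ++i) {
    const std::string bname = "buffer" + std::to_string(i + 1);
    if (!bl.containsElementNamed(bname.c_str()))
      Rcpp::stop("weight list lacks buffer '%s'", bname.c_str());
    Rcpp::NumericVector v = bl[bname];
    for (uword j = 0; j < bs[i]->n_elem; ++j) (*bs[i])(j) = (float)v[j];
  }
}

// ---------------------------------------------------------------------------
// training loop: Adam, MSE (regression) or BCE (classification), plateau
// learning-rate schedule, best-validation checkpointing (weights restored)
// [[Rcpp::export(name = ".hdgs_train_cpp")]]
Rcpp::List hdgs_train_cpp(SEXP ptr, Rcpp::IntegerVector feat, Rcpp::NumericVector labels,
                          Rcpp::IntegerVector train_idx, Rcpp::IntegerVector val_idx,
                          int epochs, int batch, double lr0, double plateau_factor,
                          int patience, double min_lr, int seed, bool verbose) {
  Rcpp::XPtr<Net> net(ptr);
  Rcpp::IntegerVector dims = feat.attr("dim");
  const int ntr = train_idx.size(), nva = val_idx.size();
  const bool cls = (net->head == "classification");
  RNG shuffler((uint64_t)seed);

  std::vector<Param*> ps;
  net->collect(ps);
  std::vector<fvec*> bs;
  net->buffers(bs);
  std::vector<fmat> best_w;
  std::vector<fvec> best_b;
  double best_val = datum::inf;
  int best_epoch = 0, wait = 0;
  float lr = (float)lr0;

  std::vector<int> order(ntr);
  for (int i = 0; i < ntr; ++i) order[i] = train_idx[i];

  std::vector<double> h_epoch, h_lr, h_loss, h_metric, h_vloss, h_vmetric;

  auto eval_set = [&](const std::vector<int>& ii, double& loss, double& metric) {
    double sl = 0, sm = 0;
    const size_t chunk = 256;
    for (size_t at = 0; at < ii.size(); at += chunk) {
      const int m = (int)std::min(chunk, ii.size() - at);
      std::vector<int> sub(ii.begin() + at, ii.begin() + at + m);
      fmat X0 = make_input(feat, dims, sub, net->H, net->W0);
      fmat z = net->fwd(X0, m, false);
      fmat p = Net::head_act(z, net->head);
      for (int i = 0; i < m; ++i) {
        const double y = p(0, i), t = labels[sub[i]];
        if (cls) {
          const double pc = std::min(1.0 - 1e-7, std::max(1e-7, y));
          sl += -(t * std::log(pc) + (1.0 - t) * std::log(1.0 - pc));
          sm += ((y > 0.5) == (t > 0.5)) ? 1.0 : 0.0;
        } else {
          sl += (y - t) * (y - t);
          sm += std::fabs(y - t);
        }
      }
    }
    loss = sl / std::max((size_t)1, ii.size());
    metric = sm / std::max((size_t)1, ii.size());
  };

  for (int ep = 1; ep <= epochs; ++ep) {
    for (int i = ntr - 1; i > 0; --i) { // Fisher-Yates under the run seed
      const int j = (int)(shuffler.next() % (uint64_t)(i + 1));
      std::swap(order[i], order[j]);
    }
    double sl = 0, sm = 0;
    int seen = 0;
    for (int at = 0; at < ntr; at += batch) {
      const int m = std::min(batch, ntr - at);
      std::vector<int> sub(order.begin() + at, order.begin() + at + m);
      fmat X0 = make_input(feat, dims, sub, net->H, net->W0);
      fmat z = net->fwd(X0, m, true);
      fmat p = Net::head_act(z, net->head);
      fmat dz(1, m);
      for (int i = 0; i < m; ++i) {
        const double y = p(0, i), t = labels[sub[i]];
        if (!std::isfinite((double)z(0, i)))
          sl = datum::inf; // exploded activations hide behind relu(NaN) = 0
        if (cls) {
          const double pc = std::min(1.0 - 1e-7, std::max(1e-7, y));
          sl += -(t * std::log(pc) + (1.0 - t) * std::log(1.0 - pc));
          sm += ((y > 0.5) == (t > 0.5)) ? 1.0 : 0.0;
          dz(0, i) = (float)((y - t) / m);
        } else {
          sl += (y - t) * (y - t);
          sm += std::fabs(y - t);
          dz(0, i) = (z(0, i) > 0.0f) ? (float)(2.0 * (y - t) / m) : 0.0f;
        }
      }
      seen += m;
      net->bwd(dz, m, lr);
      Rcpp::checkUserInterrupt();
    }
    const double tr_loss = sl / seen, tr_metric = sm / seen;
    double va_loss = datum::nan, va_metric = datum::nan;
    if (nva > 0) {
      std::vector<int> vi(val_idx.begin(), val_idx.end());
      eval_set(vi, va_loss, va_metric);
    }
    if (!std::isfinite(tr_loss) || (nva > 0 && !std::isfinite(va_loss)))
      Rcpp::stop("non-finite loss at epoch %d (train %g, val %g): training aborted",
                 ep, tr_loss, va_loss);
    h_epoch.push_back(ep); h_lr.push_back(lr);
    h_loss.push_back(tr_loss); h_metric.push_back(tr_metric);
    h_vloss.push_back(va_loss); h_vmetric.push_back(va_metric);
    if (verbose)
      Rcpp::Rcout << "epoch " << ep << " lr " << lr << " loss " << tr_loss
                  << " val_loss " << va_loss << std::endl;

    const double monitored = (nva > 0) ? va_loss : tr_loss;
    if (monitored < best_val) {
      best_val = monitored;
      best_epoch = ep;
      wait = 0;
      best_w.clear(); best_b.clear();
      for (auto* p : ps) best_w.push_back(p->w);
      for (auto* b : bs) best_b.push_back(*b);
    } else if (++wait >= patience) {
      lr = std::max((float)min_lr, lr * (float)plateau_factor);
      wait = 0;
    }
  }
  if (!best_w.empty()) {
    for (size_t i = 0; i < ps.size(); ++i) ps[i]->w = best_w[i];
    for (size_t i = 0; i < bs.size(); ++i) *bs[i] = best_b[i];
  }
  return Rcpp::List::create(
    Rcpp::Named("history") = Rcpp::DataFrame::create(
      Rcpp::Named("epoch") = h_epoch, Rcpp::Named("lr") = h_lr,
      Rcpp::Named("loss") = h_loss, Rcpp::Named("metric") = h_metric,
      Rcpp::Named("val_loss") = h_vloss, Rcpp::Named("val_metric") = h_vmetric),
    Rcpp::Named("best_epoch") = best_epoch,
    Rcpp::Named("best_val_loss") = best_val);
}

// ---------------------------------------------------------------------------
// direct convolution entry point used by unit tests to check the conv engine
// against an independent R-side oracle. X is C x (W*B) position-major
// (column = w*B + b); with B = 1 this is simply C x W. Weights are
// Cout x (K*Cin) with tap k in columns k*Cin..(k+1)*Cin-1.
// [[Rcpp::export(name = ".hdgs_conv_same_cpp")]]
Rcpp::NumericMatrix hdgs_conv_same_cpp(Rcpp::NumericMatrix X, Rcpp::NumericMatrix Wt,
                                       Rcpp::NumericVector bias, int K, int d,
                                       int B, int W) {
  const int C = X.nrow();
  fmat Xf(C, X.ncol());
  for (int j = 0; j < X.ncol(); ++j)
    for (int i = 0; i < C; ++i) Xf(i, j) = (float)X(i, j);
  Conv cv;
  cv.K = K; cv.d = d; cv.Cin = C; cv.Cout = Wt.nrow();
  cv.W.init(Wt.nrow(), Wt.ncol(), "w");
  for (int j = 0; j < Wt.ncol(); ++j)
    for (int i = 0; i < Wt.nrow(); ++i) cv.W.w(i, j) = (float)Wt(i, j);
  cv.b.init(Wt.nrow(), 1, "b");
  for (int i = 0; i < bias.size(); ++i) cv.b.w(i, 0) = (float)bias[i];
  fmat Y = cv.fwd(Xf, B, W);
  Rcpp::NumericMatrix out(Y.n_rows, Y.n_cols);
  for (uword j = 0; j < Y.n_cols; ++j)
    for (uword i = 0; i < Y.n_rows; ++i) out(i, j) = (double)Y(i, j);
  return out;
}
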