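// Core numerical engine: a small convolutional-network stack with manual
// backpropagation, used for the residual-noise U-Net (with optional
// squeeze-and-excitation recalibration) and for the perceptual
// feature-extractor losses.  Feature maps are stored as arma::fmat with
// rows = N*H*W (image-major, then row-major pixels) and cols = channels,
// so convolutions reduce to im2col + sgemm.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include <random>
#include <vector>
#include <cmath>
#include <cstring>

using arma::fmat;
using arma::frowvec;
using Rcpp::List;
using Rcpp::NumericVector;
using Rcpp::XPtr;

static const float BN_EPS = 1e-5f;
static const float BN_MOMENTUM = 0.1f;

// runtime-dispatched AVX2 clones of the hot elementwise loops; the default
// clone keeps the binary runnable on any x86-64
#if defined(__GNUC__) && defined(__x86_64__) && !defined(__clang__)
#define HOT __attribute__((target_clones("avx2", "default")))
#else
#define HOT
#endif

// ---------------------------------------------------------------- activations
// codes: 0 leaky(0.01), 1 mish, 2 relu, 3 leaky(0.1)
static inline float softplusf(float x) {
  if (x > 20.f) return x;
  if (x < -20.f) return std::exp(x);
  return std::log1p(std::exp(x));
}
static inline float act_f(float x, int a) {
  switch (a) {
    case 0: return x > 0.f ? x : 0.01f * x;
    case 1: return x * std::tanh(softplusf(x));
    case 2: return x > 0.f ? x : 0.f;
    default: return x > 0.f ? x : 0.1f * x;
  }
}
static inline float act_g(float x, int a) {
  switch (a) {
    case 0: return x > 0.f ? 1.f : 0.01f;
    case 1: {
      float t = std::tanh(softplusf(x));
      float s = 1.f / (1.f + std::exp(-x));
      return t + x * (1.f - t * t) * s;
    }
    case 2: return x > 0.f ? 1.f : 0.f;
    default: return x > 0.f ? 1.f : 0.1f;
  }
}
static void act_apply(const fmat& A, fmat& out, int a) {
  out.set_size(arma::size(A));
  const float* s = A.memptr(); float* d = out.memptr();
  size_t n = A.n_elem;
  for (size_t i = 0; i < n; ++i) d[i] = act_f(s[i], a);
}
static void act_backward(const fmat& A, fmat& dOut, int a) {
  float* d = dOut.memptr(); const float* s = A.memptr();
  size_t n = A.n_elem;
  for (size_t i = 0; i < n; ++i) d[i] *= act_g(s[i], a);
}

// fast expf (relative error ~1e-7), used in the training-path Mish where
// libm transcendentals dominate the runtime
static inline float fast_expf(float x) {
  x = x < -87.f ? -87.f : (x > 88.f ? 88.f : x);
  float t = x * 1.44269504f;
  // branch-free floor for t in (-1024, 1024): positive-shift truncation
  int32_t ii = (int32_t)(t + 1024.f) - 1024;
  float fi = (float)ii;
  float f = t - fi;
  float p = 1.f + f * (0.6931471806f + f * (0.2402265069f +
              f * (0.0555041087f + f * (0.0096181291f + f * 0.0013333558f))));
  union { int32_t i; float f; } v;
  v.i = (ii + 127) << 23;
  return v.f * p;
}

// branch-free Mish loops: clamping x at 15 inside the exponential leaves
// t = tanh(softplus(x)) and the sigmoid at 1 within float precision;
// identity tanh(log(1+u)) = ((1+u)^2 - 1)/((1+u)^2 + 1) with u = e^x needs
// a single exponential per element
HOT static void mish_fwd_keep(const float* s, float* d, float* tp, float* sp,
                              size_t n) {
  for (size_t i = 0; i < n; ++i) {
    float x = s[i];
    float xc = x > 15.f ? 15.f : x;
    float u = fast_expf(xc);
    float w = 1.f + u, w2 = w * w;
    float inv = 1.f / (w * (w2 + 1.f));
    float t = (w2 - 1.f) * w * inv;
    d[i] = x * t;
    tp[i] = t; sp[i] = u * (w2 + 1.f) * inv;
  }
}
HOT static void mish_fwd(const float* s, float* d, size_t n) {
  for (size_t i = 0; i < n; ++i) {
    float x = s[i];
    float xc = x > 15.f ? 15.f : x;
    float u = fast_expf(xc);
    float w = 1.f + u, w2 = w * w;
    d[i] = x * ((w2 - 1.f) / (w2 + 1.f));
  }
}
HOT static void mish_bwd(const float* s, const float* tp, const float* sp,
                         float* d, size_t n) {
  for (size_t i = 0; i < n; ++i) {
    float t = tp[i];
    d[i] *= t + s[i] * (1.f - t * t) * sp[i];
  }
}
HOT static void slope_fwd(const float* s, float* d, size_t n, float slope) {
  for (size_t i = 0; i < n; ++i) d[i] = s[i] > 0.f ? s[i] : slope * s[i];
}
HOT static void slope_bwd(const float* s, float* d, size_t n, float slope) {
  for (size_t i = 0; i < n; ++i) d[i] = s[i] > 0.f ? d[i] : slope * d[i];
}

static void act_forward_cached(const fmat& A, fmat& out, int a,
                               fmat& T, fmat& S, bool keep) {
  out.set_size(arma::size(A));
  size_t n = A.n_elem;
  const float* s = A.memptr(); float* d = out.memptr();
  if (a == 1) {
    if (keep) {
      T.set_size(arma::size(A)); S.set_size(arma::size(A));
      mish_fwd_keep(s, d, T.memptr(), S.memptr(), n);
    } else mish_fwd(s, d, n);
  } else {
    slope_fwd(s, d, n, a == 0 ? 0.01f : (a == 2 ? 0.f : 0.1f));
  }
}
static void act_backward_cached(const fmat& A, fmat& dOut, int a,
                                const fmat& T, const fmat& S) {
  size_t n = A.n_elem;
  if (a == 1) mish_bwd(A.memptr(), T.memptr(), S.memptr(), dOut.memptr(), n);
  else slope_bwd(A.memptr(), dOut.memptr(), n,
                 a == 0 ? 0.01f : (a == 2 ? 0.f : 0.1f));
}

// batch-norm per-channel passes
HOT static void colsum2(const float* y, size_t M, double& s1, double& s2) {
  double d1 = 0, d2 = 0;
  for (size_t i = 0; i < M; ++i) { d1 += y[i]; d2 += (double)y[i] * y[i]; }
  s1 = d1; s2 = d2;
}
HOT static void bn_apply(const float* y, size_t M, float m, float is, float g,
                         float b, float* xh, float* a) {
  for (size_t i = 0; i < M; ++i) {
    float v = (y[i] - m) * is;
    xh[i] = v;
    a[i] = g * v + b;
  }
}
HOT static void bn_bwd_stats(const float* dd, const float* xh, size_t M,
                             double& sG, double& sB) {
  double g = 0, b = 0;
  for (size_t i = 0; i < M; ++i) { g += (double)dd[i] * xh[i]; b += dd[i]; }
  sG = g; sB = b;
}
HOT static void bn_bwd_apply_train(const float* dd, const float* xh, size_t M,
                                   float gi, float dG, float dB, float invM,
                                   float* dy) {
  for (size_t i = 0; i < M; ++i)
    dy[i] = gi * (dd[i] - (dB + xh[i] * dG) * invM);
}
HOT static void vscale(const float* s, float* d, float g, size_t n) {
  for (size_t i = 0; i < n; ++i) d[i] = s[i] * g;
}
HOT static void vadd(float* d, const float* s, int len) {
  for (int i = 0; i < len; ++i) d[i] += s[i];
}
HOT static void se_bwd_seg(const float* dd, const float* xs, float g,
                           float* dx, double& acc, size_t n) {
  double a = 0;
  for (size_t i = 0; i < n; ++i) {
    a += (double)dd[i] * xs[i];
    dx[i] = dd[i] * g;
  }
  acc = a;
}

// ------------------------------------------------------------------ conv plan
struct ConvPlan {
  int H, W, HW;
  arma::Mat<int> nbr;  // HW x 9, -1 marks zero padding
};
static ConvPlan make_plan(int H, int W) {
  ConvPlan pl; pl.H = H; pl.W = W; pl.HW = H * W;
  pl.nbr.set_size(pl.HW, 9);
  for (int dr = -1; dr <= 1; ++dr)
    for (int dc = -1; dc <= 1; ++dc) {
      int k = (dr + 1) * 3 + (dc + 1);
      int* col = pl.nbr.colptr(k);
      for (int r = 0; r < H; ++r)
        for (int c = 0; c < W; ++c) {
          int rr = r + dr, cc = c + dc;
          col[r * W + c] =
            (rr < 0 || rr >= H || cc < 0 || cc >= W) ? -1 : rr * W + cc;
        }
    }
  return pl;
}

// within one image row the 3x3 neighbor map is an affine shift, so the
// gather/scatter reduce to contiguous segment copies/adds per (offset, row)
static fmat im2col(const fmat& X, const ConvPlan& pl, int N) {
  int H = pl.H, W = pl.W, HW = pl.HW, Cin = X.n_cols;
  fmat K((size_t)N * HW, (size_t)Cin * 9);
  for (int ci = 0; ci < Cin; ++ci) {
    const float* src = X.colptr(ci);
    for (int k = 0; k < 9; ++k) {
      int dr = k / 3 - 1, dc = k % 3 - 1;
      float* dst = K.colptr((size_t)ci * 9 + k);
      int c0 = dc < 0 ? 1 : 0;              // first valid dest col
      int c1 = dc > 0 ? W - 1 : W;          // one past last valid dest col
      int len = c1 - c0;
      for (int n = 0; n < N; ++n) {
        const float* s = src + (size_t)n * HW;
        float* d = dst + (size_t)n * HW;
        for (int r = 0; r < H; ++r) {
          float* drow = d + r * W;
          int rr = r + dr;
          if (rr < 0 || rr >= H) { std::memset(drow, 0, W * sizeof(float)); continue; }
          if (dc < 0) drow[0] = 0.f;
          if (dc > 0) drow[W - 1] = 0.f;
          std::memcpy(drow + c0, s + rr * W + c0 + dc, len * sizeof(float));
        }
      }
    }
  }
  return K;
}
static fmat col2im(const fmat& dK, const ConvPlan& pl, int N, int Cin) {
  int H = pl.H, W = pl.W, HW = pl.HW;
  fmat dX((size_t)N * HW, Cin, arma::fill::zeros);
  for (int ci = 0; ci < Cin; ++ci) {
    float* dst = dX.colptr(ci);
    for (int k = 0; k < 9; ++k) {
      int dr = k / 3 - 1, dc = k % 3 - 1;
      const float* src = dK.colptr((size_t)ci * 9 + k);
      int c0 = dc < 0 ? 1 : 0;
      int c1 = dc > 0 ? W - 1 : W;
      int len = c1 - c0;
      for (int n = 0; n < N; ++n) {
        const float* s = src + (size_t)n * HW;
        float* d = dst + (size_t)n * HW;
        for (int r = 0; r < H; ++r) {
          int rr = r + dr;
          if (rr < 0 || rr >= H) continue;
          vadd(d + rr * W + c0 + dc, s + r * W + c0, len);
        }
      }
    }
  }
  return dX;
}

// ----------------------------------------------------------------- parameters
struct Param {
  fmat w, g, m, v;
  void init(int r, int c) {
    w.set_size(r, c); g.zeros(r, c); m.zeros(r, c); v.zeros(r, c);
  }
};
static void fill_normal(fmat& w, float sd, std::mt19937& gen) {
  std::normal_distribution<float> d(0.f, sd);
  for (size_t i = 0; i < w.n_elem; ++i) w.memptr()[i] = d(gen);
}

// -------------------------------------------------------- conv + BN + act unit
struct ConvBNAct {
  int Cin, Cout, act;
  Param W;            // (Cin*9 x Cout); no conv bias (BN beta absorbs it)
  Param gamma, beta;  // (1 x Cout)
  frowvec run_m, run_v;
  // caches
  fmat K, xhat, A, out, actT, actS;
  frowvec invstd;

  void setup(int cin, int cout, int a, std::mt19937& gen,
             std::vector<Param*>& reg) {
    Cin = cin; Cout = cout; act = a;
    W.init(cin * 9, cout);
    fill_normal(W.w, std::sqrt(2.f / (cin * 9)), gen);
    gamma.init(1, cout); gamma.w.ones();
    beta.init(1, cout);  beta.w.zeros();
    run_m.zeros(cout); run_v.ones(cout);
    reg.push_back(&W); reg.push_back(&gamma); reg.push_back(&beta);
  }
  void forward(const fmat& X, const ConvPlan& pl, int N, bool training) {
    K = im2col(X, pl, N);
    fmat Y = K * W.w;
    size_t M = Y.n_rows;
    xhat.set_size(arma::size(Y));
    A.set_size(arma::size(Y));
    if (training) {
      frowvec mu(Cout), va(Cout);
      invstd.set_size(Cout);
      for (int c = 0; c < Cout; ++c) {
        double s1, s2;
        colsum2(Y.colptr(c), M, s1, s2);
        float m = (float)(s1 / M);
        float v = (float)(s2 / M) - m * m;
        if (v < 0) v = 0;
        mu(c) = m; va(c) = v;
        invstd(c) = 1.f / std::sqrt(v + BN_EPS);
        bn_apply(Y.colptr(c), M, m, invstd(c), gamma.w(0, c), beta.w(0, c),
                 xhat.colptr(c), A.colptr(c));
      }
      run_m = (1.f - BN_MOMENTUM) * run_m + BN_MOMENTUM * mu;
      run_v = (1.f - BN_MOMENTUM) * run_v + BN_MOMENTUM * va;
    } else {
      invstd = 1.f / arma::sqrt(run_v + BN_EPS);
      for (int c = 0; c < Cout; ++c)
        bn_apply(Y.colptr(c), M, run_m(c), invstd(c), gamma.w(0, c),
                 beta.w(0, c), xhat.colptr(c), A.colptr(c));
    }
    act_forward_cached(A, out, act, actT, actS, training);
  }
  // consumes dOut (grad wrt this->out); returns grad wrt input X
  fmat backward(fmat dOut, const ConvPlan& pl, int N, bool training,
                bool need_dx = true) {
    act_backward_cached(A, dOut, act, actT, actS);  // now grad wrt A
    size_t M = dOut.n_rows;
    fmat dY(arma::size(dOut));
    for (int c = 0; c < Cout; ++c) {
      const float* dd = dOut.colptr(c);
      const float* xh = xhat.colptr(c);
      float* dy = dY.colptr(c);
      double sG, sB;
      bn_bwd_stats(dd, xh, M, sG, sB);
      float dG = (float)sG, dB = (float)sB;
      gamma.g(0, c) += dG; beta.g(0, c) += dB;
      float gi = gamma.w(0, c) * invstd(c);
      if (training)
        bn_bwd_apply_train(dd, xh, M, gi, dG, dB, 1.f / (float)M, dy);
      else
        vscale(dd, dy, gi, M);
    }
    W.g += K.t() * dY;
    if (!need_dx) return fmat();
    fmat dK = dY * W.w.t();
    return col2im(dK, pl, N, Cin);
  }
};

// ------------------------------------------------------ squeeze-and-excitation
struct SEBlock {
  int C, Cr, HW;
  Param W1, b1, W2, b2;
  const fmat* Xin = nullptr;  // points at the preceding conv output
  fmat z, a1, h, s, out;
  void setup(int c, int r, std::mt19937& gen, std::vector<Param*>& reg) {
    C = c; Cr = std::max(1, c / r);
    W1.init(C, Cr); fill_normal(W1.w, std::sqrt(2.f / C), gen);
    b1.init(1, Cr); b1.w.zeros();
    W2.init(Cr, C); fill_normal(W2.w, std::sqrt(2.f / Cr), gen);
    b2.init(1, C);  b2.w.zeros();
    reg.push_back(&W1); reg.push_back(&b1); reg.push_back(&W2); reg.push_back(&b2);
  }
  void forward(const fmat& X, int hw, int N) {
    Xin = &X; HW = hw;
    z.set_size(N, C);
    for (int n = 0; n < N; ++n)
      z.row(n) = arma::mean(X.rows((size_t)n * hw, (size_t)(n + 1) * hw - 1), 0);
    a1 = z * W1.w; a1.each_row() += b1.w.row(0);
    h = arma::clamp(a1, 0.f, arma::datum::inf);
    fmat a2 = h * W2.w; a2.each_row() += b2.w.row(0);
    s = 1.f / (1.f + arma::exp(-a2));
    out.set_size(arma::size(X));
    for (int c = 0; c < C; ++c) {
      const float* xs = X.colptr(c); float* d = out.colptr(c);
      for (int n = 0; n < N; ++n)
        vscale(xs + (size_t)n * hw, d + (size_t)n * hw, s(n, c), hw);
    }
  }
  fmat backward(const fmat& dOut, int N) {
    fmat dX(arma::size(dOut));
    fmat ds(N, C);
    for (int c = 0; c < C; ++c) {
      const float* dd = dOut.colptr(c); const float* xs = Xin->colptr(c);
      float* dx = dX.colptr(c);
      for (int n = 0; n < N; ++n) {
        size_t o = (size_t)n * HW;
        double acc;
        se_bwd_seg(dd + o, xs + o, s(n, c), dx + o, acc, HW);
        ds(n, c) = (float)acc;
      }
    }
    fmat da2 = ds % s % (1.f - s);
    W2.g += h.t() * da2;
    b2.g.row(0) += arma::sum(da2, 0);
    fmat da1 = (da2 * W2.w.t()) % arma::conv_to<fmat>::from(a1 > 0.f);
    W1.g += z.t() * da1;
    b1.g.row(0) += arma::sum(da1, 0);
    fmat dz = da1 * W1.w.t();   // N x C
    float inv = 1.f / (float)HW;
    for (int n = 0; n < N; ++n)
      dX.rows((size_t)n * HW, (size_t)(n + 1) * HW - 1).each_row() +=
        dz.row(n) * inv;
    return dX;
  }
};

// -------------------------------------------------------------------- pooling
static fmat maxpool2(const fmat& X, int h, int w, int N, arma::Mat<int>& arg) {
  int h2 = h / 2, w2 = w / 2, HW = h * w, HW2 = h2 * w2, C = X.n_cols;
  fmat Y((size_t)N * HW2, C);
  arg.set_size((size_t)N * HW2, C);
  for (int c = 0; c < C; ++c) {
    const float* s = X.colptr(c); float* d = Y.colptr(c); int* a = arg.colptr(c);
    for (int n = 0; n < N; ++n)
      for (int r = 0; r < h2; ++r)
        for (int cc = 0; cc < w2; ++cc) {
          int base = n * HW + 2 * r * w + 2 * cc;
          int o = n * HW2 + r * w2 + cc;
          int bi = base; float bv = s[base];
          if (s[base + 1] > bv) { bv = s[base + 1]; bi = base + 1; }
          if (s[base + w] > bv) { bv = s[base + w]; bi = base + w; }
          if (s[base + w + 1] > bv) { bv = s[base + w + 1]; bi = base + w + 1; }
          d[o] = bv; a[o] = bi;
        }
  }
  return Y;
}
static fmat maxpool2_back(const fmat& dY, const arma::Mat<int>& arg,
                          size_t rows_in) {
  int C = dY.n_cols;
  fmat dX(rows_in, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const float* s = dY.colptr(c); const int* a = arg.colptr(c);
    float* d = dX.colptr(c);
    for (size_t i = 0; i < dY.n_rows; ++i) d[a[i]] += s[i];
  }
  return dX;
}
static fmat avgpool2(const fmat& X, int h, int w, int N) {
  int h2 = h / 2, w2 = w / 2, HW = h * w, HW2 = h2 * w2, C = X.n_cols;
  fmat Y((size_t)N * HW2, C);
  for (int c = 0; c < C; ++c) {
    const float* s = X.colptr(c); float* d = Y.colptr(c);
    for (int n = 0; n < N; ++n)
      for (int r = 0; r < h2; ++r)
        for (int cc = 0; cc < w2; ++cc) {
          int base = n * HW + 2 * r * w + 2 * cc;
          d[n * HW2 + r * w2 + cc] =
            0.25f * (s[base] + s[base + 1] + s[base + w] + s[base + w + 1]);
        }
  }
  return Y;
}
static fmat avgpool2_back(const fmat& dY, int h, int w, int N) {
  int h2 = h / 2, w2 = w / 2, HW = h * w, HW2 = h2 * w2, C = dY.n_cols;
  fmat dX((size_t)N * HW, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const float* s = dY.colptr(c); float* d = dX.colptr(c);
    for (int n = 0; n < N; ++n)
      for (int r = 0; r < h2; ++r)
        for (int cc = 0; cc < w2; ++cc) {
          float g = 0.25f * s[n * HW2 + r * w2 + cc];
          int base = n * HW + 2 * r * w + 2 * cc;
          d[base] += g; d[base + 1] += g; d[base + w] += g; d[base + w + 1] += g;
        }
  }
  return dX;
}

// ------------------------------------------------- 2x2 stride-2 transposed conv
struct UpConv {
  int Cin, Cout;
  Param W;  // (Cin x Cout*4), position q = dy*2+dx
  Param b;  // (1 x Cout)
  fmat Xin, out;
  void setup(int cin, int cout, std::mt19937& gen, std::vector<Param*>& reg) {
    Cin = cin; Cout = cout;
    W.init(cin, cout * 4);
    fill_normal(W.w, std::sqrt(2.f / cin), gen);
    b.init(1, cout); b.w.zeros();
    reg.push_back(&W); reg.push_back(&b);
  }
  void forward(const fmat& X, int h, int w, int N) {
    Xin = X;
    fmat U = X * W.w;  // (N*h*w x Cout*4)
    int HW = h * w, H2 = 2 * h, W2 = 2 * w, HW2 = H2 * W2;
    out.set_size((size_t)N * HW2, Cout);
    for (int co = 0; co < Cout; ++co) {
      float* d = out.colptr(co);
      float bias = b.w(0, co);
      for (int q = 0; q < 4; ++q) {
        const float* s = U.colptr((size_t)co * 4 + q);
        int dy = q / 2, dx = q % 2;
        for (int n = 0; n < N; ++n)
          for (int r = 0; r < h; ++r)
            for (int cc = 0; cc < w; ++cc)
              d[n * HW2 + (2 * r + dy) * W2 + (2 * cc + dx)] =
                s[n * HW + r * w + cc];
      }
      for (size_t i = 0; i < (size_t)N * HW2; ++i) d[i] += bias;
    }
  }
  fmat backward(const fmat& dOut, int h, int w, int N) {
    int HW = h * w, W2 = 2 * w, HW2 = 4 * h * w;
    fmat dU((size_t)N * HW, (size_t)Cout * 4);
    for (int co = 0; co < Cout; ++co) {
      const float* s = dOut.colptr(co);
      double bsum = 0;
      for (size_t i = 0; i < dOut.n_rows; ++i) bsum += s[i];
      b.g(0, co) += (float)bsum;
      for (int q = 0; q < 4; ++q) {
        float* d = dU.colptr((size_t)co * 4 + q);
        int dy = q / 2, dx = q % 2;
        for (int n = 0; n < N; ++n)
          for (int r = 0; r < h; ++r)
            for (int cc = 0; cc < w; ++cc)
              d[n * HW + r * w + cc] =
                s[n * HW2 + (2 * r + dy) * W2 + (2 * cc + dx)];
      }
    }
    W.g += Xin.t() * dU;
    return dU * W.w.t();
  }
};

// ----------------------------------------------------------------------- UNet
struct EncBlock { ConvBNAct c1, c2; SEBlock se; bool use_se; fmat out; };
struct DecBlock {
  UpConv up; ConvBNAct c1, c2; SEBlock se; bool use_se;
  fmat cat, out;
};

struct UNet {
  int depth, base, H, W, act, se_r;
  bool use_se;
  std::vector<ConvPlan> plans;
  std::vector<EncBlock> enc;
  std::vector<DecBlock> dec;
  std::vector<arma::Mat<int>> poolArg;   // depth-1 transitions
  std::vector<fmat> pooled;
  Param Wf, bf;
  fmat dec_in_grad;  // scratch
  std::vector<Param*> params;
  fmat final_in;     // dec[0].out (or enc[0].out when depth==1)
  fmat out;
  int curN = 0;
  bool curTrain = false;
  long t_step = 0;

  UNet(int depth_, int base_, int H_, int W_, int act_, bool use_se_,
       int se_r_, unsigned int seed)
      : depth(depth_), base(base_), H(H_), W(W_), act(act_), se_r(se_r_),
        use_se(use_se_) {
    std::mt19937 gen(seed);
    plans.resize(depth);
    for (int i = 0; i < depth; ++i) plans[i] = make_plan(H >> i, W >> i);
    enc.resize(depth);
    for (int i = 0; i < depth; ++i) {
      int cin = i == 0 ? 1 : (base << (i - 1));
      int cout = base << i;
      enc[i].c1.setup(cin, cout, act, gen, params);
      enc[i].c2.setup(cout, cout, act, gen, params);
      enc[i].use_se = use_se;
      if (use_se) enc[i].se.setup(cout, se_r, gen, params);
    }
    dec.resize(depth > 1 ? depth - 1 : 0);
    for (int i = depth - 2; i >= 0; --i) {
      int cout = base << i;
      dec[i].up.setup(base << (i + 1), cout, gen, params);
      dec[i].c1.setup(2 * cout, cout, act, gen, params);
      dec[i].c2.setup(cout, cout, act, gen, params);
      dec[i].use_se = use_se;
      if (use_se) dec[i].se.setup(cout, se_r, gen, params);
    }
    Wf.init(base, 1);
    fill_normal(Wf.w, std::sqrt(1.f / base), gen);
    bf.init(1, 1); bf.w.zeros();
    params.push_back(&Wf); params.push_back(&bf);
    poolArg.resize(depth > 1 ? depth - 1 : 0);
    pooled.resize(depth > 1 ? depth - 1 : 0);
  }

  void forward(const fmat& X, int N, bool training) {
    curN = N; curTrain = training;
    const fmat* cur = &X;
    for (int i = 0; i < depth; ++i) {
      if (i > 0) {
        pooled[i - 1] = maxpool2(enc[i - 1].out, H >> (i - 1), W >> (i - 1), N,
                                 poolArg[i - 1]);
        cur = &pooled[i - 1];
      }
      enc[i].c1.forward(*cur, plans[i], N, training);
      enc[i].c2.forward(enc[i].c1.out, plans[i], N, training);
      if (enc[i].use_se) {
        enc[i].se.forward(enc[i].c2.out, plans[i].HW, N);
        enc[i].out = std::move(enc[i].se.out);
      } else enc[i].out = enc[i].c2.out;
    }
    const fmat* deep = &enc[depth - 1].out;
    for (int i = depth - 2; i >= 0; --i) {
      dec[i].up.forward(*deep, H >> (i + 1), W >> (i + 1), N);
      dec[i].cat = arma::join_rows(dec[i].up.out, enc[i].out);
      dec[i].c1.forward(dec[i].cat, plans[i], N, training);
      dec[i].c2.forward(dec[i].c1.out, plans[i], N, training);
      if (dec[i].use_se) {
        dec[i].se.forward(dec[i].c2.out, plans[i].HW, N);
        dec[i].out = std::move(dec[i].se.out);
      } else dec[i].out = dec[i].c2.out;
      deep = &dec[i].out;
    }
    final_in = *deep;
    out = final_in * Wf.w;
    out.each_row() += bf.w.row(0);
  }

  void backward(const fmat& dY) {
    int N = curN;
    Wf.g += final_in.t() * dY;
    bf.g(0, 0) += arma::accu(dY);
    fmat dcur = dY * Wf.w.t();
    std::vector<fmat> dSkip(depth > 1 ? depth - 1 : 0);
    fmat dDeep;
    if (depth == 1) {
      dDeep = dcur;
    } else {
      for (int i = 0; i <= depth - 2; ++i) {
        if (dec[i].use_se) dcur = dec[i].se.backward(dcur, N);
        dcur = dec[i].c2.backward(dcur, plans[i], N, curTrain);
        dcur = dec[i].c1.backward(dcur, plans[i], N, curTrain);
        int cout = base << i;
        dSkip[i] = dcur.cols(cout, 2 * cout - 1);
        fmat dUpOut = dcur.cols(0, cout - 1);
        dcur = dec[i].up.backward(dUpOut, H >> (i + 1), W >> (i + 1), N);
      }
      dDeep = dcur;
    }
    // encoder chain, deepest first
    fmat dFromAbove = dDeep;
    for (int i = depth - 1; i >= 0; --i) {
      fmat dOut = dFromAbove;
      if (i < depth - 1) dOut += dSkip[i];
      if (enc[i].use_se) dOut = enc[i].se.backward(dOut, N);
      dOut = enc[i].c2.backward(dOut, plans[i], N, curTrain);
      dOut = enc[i].c1.backward(dOut, plans[i], N, curTrain, i > 0);
      if (i > 0)
        dFromAbove = maxpool2_back(dOut, poolArg[i - 1],
                                   (size_t)N * plans[i - 1].HW);
    }
  }

  void zero_grad() { for (Param* p : params) p->g.zeros(); }

  void adam_step(float lr, float b1, float b2, float eps) {
    ++t_step;
    float c1 = 1.f - std::pow(b1, (float)t_step);
    float c2 = 1.f - std::pow(b2, (float)t_step);
    for (Param* p : params) {
      p->m = b1 * p->m + (1.f - b1) * p->g;
      p->v = b2 * p->v + (1.f - b2) * arma::square(p->g);
      p->w -= lr * (p->m / c1) / (arma::sqrt(p->v / c2) + eps);
    }
  }

  long n_params() const {
    long s = 0;
    for (const Param* p : params) s += (long)p->w.n_elem;
    return s;
  }
};

// ------------------------------------------------------------------ R bindings
// [[Rcpp::export]]
SEXP cpp_unet_create(int depth, int base, int H, int W, int act, bool use_se,
                     int se_r, int seed) {
  XPtr<UNet> p(new UNet(depth, base, H, W, act, use_se, se_r,
                        (unsigned int)seed), true);
  return p;
}

// [[Rcpp::export]]
bool cpp_ptr_valid(SEXP ptr) {
  return R_ExternalPtrAddr(ptr) != NULL;
}

// [[Rcpp::export]]
NumericVector cpp_unet_forward(SEXP ptr, NumericVector x, int N,
                               bool training) {
  XPtr<UNet> m(ptr);
  fmat X(m->H * m->W * (size_t)N, 1);
  for (size_t i = 0; i < X.n_elem; ++i) X(i, 0) = (float)x[i];
  m->forward(X, N, training);
  NumericVector out(m->out.n_rows);
  for (size_t i = 0; i < m->out.n_rows; ++i) out[i] = m->out(i, 0);
  return out;
}

// [[Rcpp::export]]
void cpp_unet_backward(SEXP ptr, NumericVector grad) {
  XPtr<UNet> m(ptr);
  fmat dY(grad.size(), 1);
  for (int i = 0; i < grad.size(); ++i) dY(i, 0) = (float)grad[i];
  m->backward(dY);
}

// [[Rcpp::export]]
void cpp_unet_zero_grad(SEXP ptr) { XPtr<UNet>(ptr)->zero_grad(); }

// [[Rcpp::export]]
void cpp_unet_step(SEXP ptr, double lr, double b1, double b2, double eps) {
  XPtr<UNet>(ptr)->adam_step((float)lr, (float)b1, (float)b2, (float)eps);
}

// [[Rcpp::export]]
double cpp_unet_nparams(SEXP ptr) { return (double)XPtr<UNet>(ptr)->n_params(); }

// [[Rcpp::export]]
List cpp_unet_get_state(SEXP ptr) {
  XPtr<UNet> m(ptr);
  List par(m->params.size());
  for (size_t i = 0; i < m->params.size(); ++i) {
    const fmat& w = m->params[i]->w;
    Rcpp::NumericMatrix out(w.n_rows, w.n_cols);
    for (size_t j = 0; j < w.n_elem; ++j) out[j] = w.memptr()[j];
    par[i] = out;
  }
  // running batch-norm statistics, encoder blocks then decoder blocks
  std::vector<ConvBNAct*> cbs;
  for (auto& e : m->enc) { cbs.push_back(&e.c1); cbs.push_back(&e.c2); }
  for (auto& d : m->dec) { cbs.push_back(&d.c1); cbs.push_back(&d.c2); }
  List run(cbs.size() * 2);
  for (size_t i = 0; i < cbs.size(); ++i) {
    NumericVector rm(cbs[i]->run_m.n_elem), rv(cbs[i]->run_v.n_elem);
    for (size_t j = 0; j < rm.size(); ++j) rm[j] = cbs[i]->run_m(j);
    for (size_t j = 0; j < rv.size(); ++j) rv[j] = cbs[i]->run_v(j);
    run[2 * i] = rm; run[2 * i + 1] = rv;
  }
  return List::create(Rcpp::Named("params") = par, Rcpp::Named("running") = run,
                      Rcpp::Named("t_step") = (double)m->t_step);
}

// [[Rcpp::export]]
void cpp_unet_set_state(SEXP ptr, List state) {
  XPtr<UNet> m(ptr);
  List par = state["params"];
  if ((size_t)par.size() != m->params.size())
    Rcpp::stop("parameter list length mismatch");
  for (size_t i = 0; i < m->params.size(); ++i) {
    Rcpp::NumericMatrix w = par[i];
    fmat& dst = m->params[i]->w;
    if ((size_t)w.nrow() != dst.n_rows || (size_t)w.ncol() != dst.n_cols)
      Rcpp::stop("parameter shape mismatch at index %d", (int)i + 1);
    for (size_t j = 0; j < dst.n_elem; ++j) dst.memptr()[j] = (float)w[j];
  }
  List run = state["running"];
  std::vector<ConvBNAct*> cbs;
  for (auto& e : m->enc) { cbs.push_back(&e.c1); cbs.push_back(&e.c2); }
  for (auto& d : m->dec) { cbs.push_back(&d.c1); cbs.push_back(&d.c2); }
  for (size_t i = 0; i < cbs.size(); ++i) {
    NumericVector rm = run[2 * i], rv = run[2 * i + 1];
    for (size_t j = 0; j < rm.size(); ++j) cbs[i]->run_m(j) = (float)rm[j];
    for (size_t j = 0; j < rv.size(); ++j) cbs[i]->run_v(j) = (float)rv[j];
  }
  m->t_step = (long)Rcpp::as<double>(state["t_step"]);
}

// =================================================== perceptual feature pyramid
struct PyrConv {
  fmat W;      // (Cin*9 x Cout)
  frowvec b;
  fmat A, out; // caches
  int Cin, Cout;
};
struct Pyramid {
  int H, W, act, nstage;
  std::vector<int> nconv, chan, taps;  // taps: 0-based stage ids contributing
  std::vector<ConvPlan> plans;
  std::vector<std::vector<PyrConv>> convs;  // per stage
  std::vector<fmat> stage_out;              // tap caches (pred pass)

  Pyramid(std::vector<int> nconv_, std::vector<int> chan_,
          std::vector<int> taps_, int H_, int W_, int act_, unsigned seed)
      : H(H_), W(W_), act(act_), nconv(nconv_), chan(chan_), taps(taps_) {
    nstage = (int)nconv.size();
    std::mt19937 gen(seed);
    plans.resize(nstage);
    convs.resize(nstage);
    for (int s = 0; s < nstage; ++s) {
      plans[s] = make_plan(H >> s, W >> s);
      int cin = s == 0 ? 1 : chan[s - 1];
      for (int j = 0; j < nconv[s]; ++j) {
        PyrConv pc;
        pc.Cin = j == 0 ? cin : chan[s];
        pc.Cout = chan[s];
        pc.W.set_size(pc.Cin * 9, pc.Cout);
        fill_normal(pc.W, std::sqrt(2.f / (pc.Cin * 9)), gen);
        pc.b.zeros(pc.Cout);
        convs[s].push_back(pc);
      }
    }
    stage_out.resize(nstage);
  }

  // forward; keep==true caches pre-activations for input-gradient backprop
  std::vector<fmat> run(const fmat& X, int N, bool keep) {
    std::vector<fmat> tapsOut;
    fmat cur = X;
    for (int s = 0; s < nstage; ++s) {
      if (s > 0) cur = avgpool2(cur, H >> (s - 1), W >> (s - 1), N);
      for (auto& pc : convs[s]) {
        fmat K = im2col(cur, plans[s], N);
        fmat A = K * pc.W;
        A.each_row() += pc.b;
        if (keep) pc.A = A;
        act_apply(A, cur, act);
        if (keep) pc.out = cur;
      }
      if (keep) stage_out[s] = cur;
      for (int t : taps) if (t == s) tapsOut.push_back(cur);
    }
    return tapsOut;
  }

  // grads at tapped stage outputs -> grad wrt input image
  fmat back_to_input(std::vector<fmat>& dTap, int N) {
    std::vector<fmat> dStage(nstage);
    int ti = 0;
    for (int s = 0; s < nstage; ++s) {
      bool tapped = false;
      for (int t : taps) if (t == s) tapped = true;
      if (tapped) dStage[s] = dTap[ti++];
    }
    fmat dcur;
    for (int s = nstage - 1; s >= 0; --s) {
      if (dcur.n_elem == 0) dcur = dStage[s];
      else if (dStage[s].n_elem > 0) dcur += dStage[s];
      for (int j = (int)convs[s].size() - 1; j >= 0; --j) {
        PyrConv& pc = convs[s][j];
        act_backward(pc.A, dcur, act);
        fmat dK = dcur * pc.W.t();
        dcur = col2im(dK, plans[s], N, pc.Cin);
      }
      if (s > 0) dcur = avgpool2_back(dcur, H >> (s - 1), W >> (s - 1), N);
    }
    return dcur;
  }
};

// [[Rcpp::export]]
SEXP cpp_pyr_create(Rcpp::IntegerVector nconv, Rcpp::IntegerVector chan,
                    Rcpp::IntegerVector taps, int H, int W, int act, int seed) {
  std::vector<int> nc(nconv.begin(), nconv.end());
  std::vector<int> ch(chan.begin(), chan.end());
  std::vector<int> tp(taps.begin(), taps.end());
  XPtr<Pyramid> p(new Pyramid(nc, ch, tp, H, W, act, (unsigned)seed), true);
  return p;
}

// [[Rcpp::export]]
List cpp_pyr_loss(SEXP ptr, NumericVector pred, NumericVector target, int N,
                  bool want_grad, int dist = 2) {
  XPtr<Pyramid> py(ptr);
  size_t M = (size_t)py->H * py->W * N;
  fmat P(M, 1), T(M, 1);
  for (size_t i = 0; i < M; ++i) { P(i, 0) = (float)pred[i]; T(i, 0) = (float)target[i]; }
  std::vector<fmat> ft = py->run(T, N, false);
  std::vector<fmat> fp = py->run(P, N, want_grad);
  int ntap = (int)fp.size();
  double value = 0;
  std::vector<fmat> dTap(ntap);
  // per-channel unit normalization by the target feature RMS balances the
  // randomly-scaled channels so every feature direction contributes
  for (int t = 0; t < ntap; ++t) {
    fmat diff = fp[t] - ft[t];
    int C = diff.n_cols;
    size_t Mr = diff.n_rows;
    if (want_grad) dTap[t].set_size(arma::size(diff));
    for (int c = 0; c < C; ++c) {
      double denom = arma::accu(arma::square(ft[t].col(c))) / Mr + 1e-6;
      if (dist == 1) {
        double dn = std::sqrt(denom);
        value += (arma::accu(arma::abs(diff.col(c))) / Mr) / dn / ntap / C;
        if (want_grad)
          dTap[t].col(c) = arma::sign(diff.col(c)) *
            (float)(1.0 / (Mr * dn * ntap * C));
      } else {
        value += (arma::accu(arma::square(diff.col(c))) / Mr) / denom / ntap / C;
        if (want_grad)
          dTap[t].col(c) = diff.col(c) * (float)(2.0 / (Mr * denom * ntap * C));
      }
    }
  }
  if (!want_grad) return List::create(Rcpp::Named("value") = value);
  fmat g = py->back_to_input(dTap, N);
  NumericVector grad(M);
  for (size_t i = 0; i < M; ++i) grad[i] = g(i, 0);
  return List::create(Rcpp::Named("value") = value, Rcpp::Named("grad") = grad);
}

// [[Rcpp::export]]
List cpp_pyr_taps(SEXP ptr, NumericVector x, int N) {
  XPtr<Pyramid> py(ptr);
  size_t M = (size_t)py->H * py->W * N;
  fmat X(M, 1);
  for (size_t i = 0; i < M; ++i) X(i, 0) = (float)x[i];
  std::vector<fmat> f = py->run(X, N, false);
  List out(f.size());
  for (size_t t = 0; t < f.size(); ++t) {
    Rcpp::NumericMatrix m(f[t].n_rows, f[t].n_cols);
    for (size_t j = 0; j < f[t].n_elem; ++j) m[j] = f[t].memptr()[j];
    out[t] = m;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_pyr_get_weights(SEXP ptr) {
  XPtr<Pyramid> py(ptr);
  List out;
  for (int s = 0; s < py->nstage; ++s)
    for (size_t j = 0; j < py->convs[s].size(); ++j) {
      const fmat& w = py->convs[s][j].W;
      Rcpp::NumericMatrix m(w.n_rows, w.n_cols);
      for (size_t i = 0; i < w.n_elem; ++i) m[i] = w.memptr()[i];
      out.push_back(m);
    }
  return out;
}

// [[Rcpp::export]]
void cpp_pyr_set_weights(SEXP ptr, List ws) {
  XPtr<Pyramid> py(ptr);
  int k = 0;
  for (int s = 0; s < py->nstage; ++s)
    for (size_t j = 0; j < py->convs[s].size(); ++j) {
      if (k >= ws.size()) Rcpp::stop("too few weight matrices");
      Rcpp::NumericMatrix m = ws[k++];
      fmat& w = py->convs[s][j].W;
      if ((size_t)m.nrow() != w.n_rows || (size_t)m.ncol() != w.n_cols)
        Rcpp::stop("extractor weight shape mismatch at matrix %d", k);
      for (size_t i = 0; i < w.n_elem; ++i) w.memptr()[i] = (float)m[i];
    }
}

// ============================================ separable window utilities (double)
// valid-region separable correlation of an image with a 1-D kernel (applied
// along both axes); used by the SSIM family
// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_sepconv_valid(Rcpp::NumericMatrix x,
                                      NumericVector k) {
  int H = x.nrow(), W = x.ncol(), L = k.size();
  int H2 = H - L + 1, W2 = W - L + 1;
  if (H2 < 1 || W2 < 1) Rcpp::stop("image smaller than window");
  Rcpp::NumericMatrix tmp(H2, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H2; ++r) {
      double s = 0;
      for (int a = 0; a < L; ++a) s += x(r + a, c) * k[a];
      tmp(r, c) = s;
    }
  Rcpp::NumericMatrix out(H2, W2);
  for (int c = 0; c < W2; ++c)
    for (int r = 0; r < H2; ++r) {
      double s = 0;
      for (int a = 0; a < L; ++a) s += tmp(r, c + a) * k[a];
      out(r, c) = s;
    }
  return out;
}

// adjoint of cpp_sepconv_valid: maps a (H-L+1)x(W-L+1) field back to HxW
// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_sepconv_valid_t(Rcpp::NumericMatrix m, NumericVector k,
                                        int H, int W) {
  int h = m.nrow(), w = m.ncol(), L = k.size();
  Rcpp::NumericMatrix tmp(H, w);
  for (int c = 0; c < w; ++c)
    for (int p = 0; p < h; ++p) {
      double v = m(p, c);
      if (v == 0) continue;
      for (int a = 0; a < L; ++a) tmp(p + a, c) += v * k[a];
    }
  Rcpp::NumericMatrix out(H, W);
  for (int r = 0; r < H; ++r)
    for (int q = 0; q < w; ++q) {
      double v = tmp(r, q);
      if (v == 0) continue;
      for (int b = 0; b < L; ++b) out(r, q + b) += v * k[b];
    }
  return out;
}
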