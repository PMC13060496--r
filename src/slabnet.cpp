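// Compact CPU engine for the distance-conditioned residual U-Net:
// forward pass, backpropagation and Adam, with convolutions performed as
// im2col + BLAS GEMM in single precision. Activations are stored as
// arma::fcube with slice index (channel + C * sample).

#include <RcppArmadillo.h>
#ifdef __GLIBC__
#include <malloc.h>
#endif
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::Named;
using Rcpp::NumericMatrix;
using Rcpp::NumericVector;
using Rcpp::stop;

// kernel offset enumeration: kk = (dh+1) + 3*(dw+1)
static const int KOFF[9][2] = {
  {-1, -1}, {0, -1}, {1, -1},
  {-1,  0}, {0,  0}, {1,  0},
  {-1,  1}, {0,  1}, {1,  1}
};

// ---------------------------------------------------------------- layers --

struct Conv {
  int Cin = 0, Cout = 0, k = 3;
  fmat W;      // (k*k*Cin) x Cout, row index kk*Cin + c
  frowvec b;
  fmat dW, mW, vW;
  frowvec db, mb, vb;
};

struct GNorm {
  int C = 0, G = 1;
  fvec gamma, beta;
  fvec dgamma, dbeta, mgam, vgam, mbet, vbet;
};

struct Unit {
  bool has_gn = true;
  GNorm gn;
  Conv conv;
};

// persistent per-unit workspace: the large matrices are reused across
// iterations (their sizes are stable for a fixed problem size), avoiding
// repeated large allocations and the page faults they trigger
struct UnitCache {
  fcube xhat;   // normalized pre-affine GN output (if has_gn)
  fvec invstd;  // per (n, group)
  fmat cols;    // im2col of the conv input
  fmat dY, dcols;  // backward workspaces
  fcube dx;        // col2im output buffer
  std::vector<unsigned char> mask;  // LReLU negative-input mask
};

struct Tape {
  int H0 = 0, W0 = 0, N = 0;
  std::vector<UnitCache> enc_uc, bot_uc, dec_uc;
  std::vector<fcube> skips;
  std::vector<Mat<unsigned char>> poolarg;  // (H/2*W/2) x slices
  fmat head_cols, head_dY, head_dcols;
};

static inline void ensure_mat(fmat& m, size_t r, size_t c) {
  if (m.n_rows != r || m.n_cols != c) m.set_size(r, c);
}
static inline void ensure_cube(fcube& m, size_t r, size_t c, size_t s) {
  if (m.n_rows != r || m.n_cols != c || m.n_slices != s) m.set_size(r, c, s);
}

struct Model {
  int in_ch = 4, base = 64, depth = 4, groups = 8;
  float slope = 0.01f;
  std::vector<Unit> enc;  // 2 per stage
  std::vector<Unit> bot;  // 2
  std::vector<Unit> dec;  // 2 per stage
  Conv head;              // 1x1 -> 1 channel
  long t = 0;             // adam step counter
  Tape tape;              // persistent training workspace
};

// ------------------------------------------------------------ primitives --

static void im2col3(const fcube& x, int H, int W, int C, int N, fmat& cols) {
  const size_t HW = (size_t)H * W;
  ensure_mat(cols, HW * N, (size_t)9 * C);
  fmat pad(H + 2, W + 2, fill::zeros);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const float* src = x.slice_memptr((size_t)c + (size_t)C * n);
      for (int w0 = 0; w0 < W; ++w0)
        std::memcpy(pad.colptr(w0 + 1) + 1, src + (size_t)w0 * H,
                    sizeof(float) * H);
      for (int kk = 0; kk < 9; ++kk) {
        const int dh = KOFF[kk][0], dw = KOFF[kk][1];
        float* dst = cols.colptr((size_t)kk * C + c) + HW * n;
        for (int w0 = 0; w0 < W; ++w0)
          std::memcpy(dst + (size_t)w0 * H,
                      pad.colptr(w0 + dw + 1) + dh + 1, sizeof(float) * H);
      }
    }
  }
}

static void col2im3(const fmat& cols, int H, int W, int C, int N, fcube& dx) {
  const size_t HW = (size_t)H * W;
  ensure_cube(dx, H, W, (size_t)C * N);
  fmat pad(H + 2, W + 2);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      pad.zeros();
      for (int kk = 0; kk < 9; ++kk) {
        const int dh = KOFF[kk][0], dw = KOFF[kk][1];
        const float* src = cols.colptr((size_t)kk * C + c) + HW * n;
        for (int w0 = 0; w0 < W; ++w0) {
          float* dst = pad.colptr(w0 + dw + 1) + dh + 1;
          const float* s = src + (size_t)w0 * H;
          for (int h0 = 0; h0 < H; ++h0) dst[h0] += s[h0];
        }
      }
      float* out = dx.slice_memptr((size_t)c + (size_t)C * n);
      for (int w0 = 0; w0 < W; ++w0)
        std::memcpy(out + (size_t)w0 * H, pad.colptr(w0 + 1) + 1,
                    sizeof(float) * H);
    }
  }
}

static void flatten1(const fcube& x, int H, int W, int C, int N, fmat& cols) {
  const size_t HW = (size_t)H * W;
  ensure_mat(cols, HW * N, C);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      std::memcpy(cols.colptr(c) + HW * n,
                  x.slice_memptr((size_t)c + (size_t)C * n),
                  sizeof(float) * HW);
}

static void unflatten1(const fmat& cols, int H, int W, int C, int N, fcube& x) {
  const size_t HW = (size_t)H * W;
  ensure_cube(x, H, W, (size_t)C * N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      std::memcpy(x.slice_memptr((size_t)c + (size_t)C * n),
                  cols.colptr(c) + HW * n, sizeof(float) * HW);
}

static fcube conv_fwd(const Conv& cv, const fcube& x, int H, int W, int N,
                      fmat* colsbuf) {
  const size_t HW = (size_t)H * W;
  fmat local;
  fmat& cols = colsbuf ? *colsbuf : local;
  if (cv.k == 3) im2col3(x, H, W, cv.Cin, N, cols);
  else flatten1(x, H, W, cv.Cin, N, cols);
  fmat Y = cols * cv.W;
  Y.each_row() += cv.b;
  fcube out(H, W, (size_t)cv.Cout * N);
  for (int n = 0; n < N; ++n)
    for (int o = 0; o < cv.Cout; ++o)
      std::memcpy(out.slice_memptr((size_t)o + (size_t)cv.Cout * n),
                  Y.colptr(o) + HW * n, sizeof(float) * HW);
  return out;
}

// sets cv.dW/db; fills uc.dx with the gradient w.r.t. the conv input
// (unless !need_dx); workspaces live in the unit cache
static void conv_bwd(Conv& cv, UnitCache& uc, const fcube& dy,
                     int H, int W, int N, bool need_dx = true) {
  const size_t HW = (size_t)H * W;
  ensure_mat(uc.dY, HW * N, cv.Cout);
  for (int n = 0; n < N; ++n)
    for (int o = 0; o < cv.Cout; ++o)
      std::memcpy(uc.dY.colptr(o) + HW * n,
                  dy.slice_memptr((size_t)o + (size_t)cv.Cout * n),
                  sizeof(float) * HW);
  cv.dW = uc.cols.t() * uc.dY;
  cv.db = sum(uc.dY, 0);
  if (!need_dx) return;
  ensure_mat(uc.dcols, HW * N, (size_t)cv.k * cv.k * cv.Cin);
  uc.dcols = uc.dY * cv.W.t();
  if (cv.k == 3) col2im3(uc.dcols, H, W, cv.Cin, N, uc.dx);
  else unflatten1(uc.dcols, H, W, cv.Cin, N, uc.dx);
}

static fcube gn_fwd(const GNorm& g, const fcube& x, int H, int W, int N,
                    fcube* xhat_keep, fvec* invstd_keep) {
  const int C = g.C, G = g.G, Cg = C / G;
  const size_t HW = (size_t)H * W;
  const double m = (double)HW * Cg;
  const float eps = 1e-5f;
  fcube out(H, W, (size_t)C * N);
  const bool keep = xhat_keep != nullptr;
  if (keep) ensure_cube(*xhat_keep, H, W, (size_t)C * N);
  fcube& xhat = keep ? *xhat_keep : out;  // alias unused when !keep
  fvec invstd(N * G);
  for (int n = 0; n < N; ++n) {
    for (int gi = 0; gi < G; ++gi) {
      double s = 0.0, s2 = 0.0;
      for (int c = gi * Cg; c < (gi + 1) * Cg; ++c) {
        const float* p = x.slice_memptr((size_t)c + (size_t)C * n);
        for (size_t i = 0; i < HW; ++i) {
          s += p[i];
          s2 += (double)p[i] * p[i];
        }
      }
      const double mu = s / m;
      double var = s2 / m - mu * mu;
      if (var < 0) var = 0;
      const float is = (float)(1.0 / std::sqrt(var + eps));
      const float fmu = (float)mu;
      invstd((size_t)gi + (size_t)G * n) = is;
      for (int c = gi * Cg; c < (gi + 1) * Cg; ++c) {
        const size_t sidx = (size_t)c + (size_t)C * n;
        const float* p = x.slice_memptr(sidx);
        float* o = out.slice_memptr(sidx);
        const float ga = g.gamma(c), be = g.beta(c);
        if (keep) {
          float* xh = xhat.slice_memptr(sidx);
          for (size_t i = 0; i < HW; ++i) {
            const float v = (p[i] - fmu) * is;
            xh[i] = v;
            o[i] = v * ga + be;
          }
        } else {
          for (size_t i = 0; i < HW; ++i)
            o[i] = (p[i] - fmu) * is * ga + be;
        }
      }
    }
  }
  if (invstd_keep) *invstd_keep = std::move(invstd);
  return out;
}

static fcube gn_bwd(GNorm& g, const fcube& xhat, const fvec& invstd,
                    const fcube& dy, int H, int W, int N) {
  const int C = g.C, G = g.G, Cg = C / G;
  const size_t HW = (size_t)H * W;
  const double m = (double)HW * Cg;
  fcube dx(H, W, (size_t)C * N);
  g.dgamma.zeros(C);
  g.dbeta.zeros(C);
  for (int n = 0; n < N; ++n) {
    for (int gi = 0; gi < G; ++gi) {
      double s1 = 0.0, s2 = 0.0;
      for (int c = gi * Cg; c < (gi + 1) * Cg; ++c) {
        const size_t sidx = (size_t)c + (size_t)C * n;
        const float* d = dy.slice_memptr(sidx);
        const float* xh = xhat.slice_memptr(sidx);
        double sd = 0.0, sdx = 0.0;
        for (size_t i = 0; i < HW; ++i) {
          sd += d[i];
          sdx += (double)d[i] * xh[i];
        }
        g.dbeta(c) += (float)sd;
        g.dgamma(c) += (float)sdx;
        s1 += (double)g.gamma(c) * sd;
        s2 += (double)g.gamma(c) * sdx;
      }
      const float mean1 = (float)(s1 / m), mean2 = (float)(s2 / m);
      const float is = invstd((size_t)gi + (size_t)G * n);
      for (int c = gi * Cg; c < (gi + 1) * Cg; ++c) {
        const size_t sidx = (size_t)c + (size_t)C * n;
        const float* d = dy.slice_memptr(sidx);
        const float* xh = xhat.slice_memptr(sidx);
        float* o = dx.slice_memptr(sidx);
        const float ga = g.gamma(c);
        for (size_t i = 0; i < HW; ++i)
          o[i] = is * (d[i] * ga - mean1 - xh[i] * mean2);
      }
    }
  }
  return dx;
}

static void lrelu_inplace(fcube& x, float slope,
                          std::vector<unsigned char>* mask) {
  float* p = x.memptr();
  const size_t n = x.n_elem;
  if (mask) {
    mask->resize(n);
    unsigned char* mk = mask->data();
    for (size_t i = 0; i < n; ++i) {
      const bool neg = p[i] < 0.0f;
      mk[i] = neg;
      if (neg) p[i] *= slope;
    }
  } else {
    for (size_t i = 0; i < n; ++i)
      if (p[i] < 0.0f) p[i] *= slope;
  }
}

static fcube pool_fwd(const fcube& x, int H, int W, int S,
                      Mat<unsigned char>* arg) {
  const int Ho = H / 2, Wo = W / 2;
  fcube out(Ho, Wo, S);
  if (arg) arg->set_size((size_t)Ho * Wo, S);
  for (int s = 0; s < S; ++s) {
    const fmat& in = x.slice(s);
    fmat& o = out.slice(s);
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        const float v0 = in(2 * i, 2 * j), v1 = in(2 * i + 1, 2 * j);
        const float v2 = in(2 * i, 2 * j + 1), v3 = in(2 * i + 1, 2 * j + 1);
        float best = v0;
        unsigned char a = 0;
        if (v1 > best) { best = v1; a = 1; }
        if (v2 > best) { best = v2; a = 2; }
        if (v3 > best) { best = v3; a = 3; }
        o(i, j) = best;
        if (arg) (*arg)((size_t)i + (size_t)Ho * j, s) = a;
      }
    }
  }
  return out;
}

static fcube pool_bwd(const fcube& dy, const Mat<unsigned char>& arg,
                      int H, int W, int S) {
  const int Ho = H / 2, Wo = W / 2;
  fcube dx(H, W, S, fill::zeros);
  for (int s = 0; s < S; ++s) {
    const fmat& d = dy.slice(s);
    fmat& o = dx.slice(s);
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        const unsigned char a = arg((size_t)i + (size_t)Ho * j, s);
        o(2 * i + (a & 1), 2 * j + (a >> 1)) += d(i, j);
      }
    }
  }
  return dx;
}

// bilinear x2 stencil (align_corners = false): out[i] pulls from in[j0],in[j1]
static void up_stencil(int L, ivec& j0, ivec& j1, fvec& w1) {
  j0.set_size(2 * L); j1.set_size(2 * L); w1.set_size(2 * L);
  for (int i = 0; i < 2 * L; ++i) {
    double s = (i + 0.5) / 2.0 - 0.5;
    if (s < 0) s = 0;
    if (s > L - 1) s = L - 1;
    int a = (int)std::floor(s);
    if (a > L - 1) a = L - 1;
    int b = a + 1 < L ? a + 1 : L - 1;
    j0(i) = a; j1(i) = b; w1(i) = (float)(s - a);
  }
}

static fcube up_fwd(const fcube& x, int H, int W, int S) {
  ivec r0, r1, c0, c1;
  fvec wr, wc;
  up_stencil(H, r0, r1, wr);
  up_stencil(W, c0, c1, wc);
  fcube out(2 * H, 2 * W, S);
  for (int s = 0; s < S; ++s) {
    const fmat& in = x.slice(s);
    fmat& o = out.slice(s);
    for (int j = 0; j < 2 * W; ++j) {
      const int cj0 = c0(j), cj1 = c1(j);
      const float wj = wc(j);
      for (int i = 0; i < 2 * H; ++i) {
        const float wi = wr(i);
        const float top = (1 - wj) * in(r0(i), cj0) + wj * in(r0(i), cj1);
        const float bot = (1 - wj) * in(r1(i), cj0) + wj * in(r1(i), cj1);
        o(i, j) = (1 - wi) * top + wi * bot;
      }
    }
  }
  return out;
}

static fcube up_bwd(const fcube& dy, int H, int W, int S) {
  ivec r0, r1, c0, c1;
  fvec wr, wc;
  up_stencil(H, r0, r1, wr);
  up_stencil(W, c0, c1, wc);
  fcube dx(H, W, S, fill::zeros);
  for (int s = 0; s < S; ++s) {
    const fmat& d = dy.slice(s);
    fmat& o = dx.slice(s);
    for (int j = 0; j < 2 * W; ++j) {
      const int cj0 = c0(j), cj1 = c1(j);
      const float wj = wc(j);
      for (int i = 0; i < 2 * H; ++i) {
        const float wi = wr(i);
        const float g = d(i, j);
        o(r0(i), cj0) += (1 - wi) * (1 - wj) * g;
        o(r0(i), cj1) += (1 - wi) * wj * g;
        o(r1(i), cj0) += wi * (1 - wj) * g;
        o(r1(i), cj1) += wi * wj * g;
      }
    }
  }
  return dx;
}

static fcube concat_ch(const fcube& a, int Ca, const fcube& b, int Cb, int N) {
  const int C = Ca + Cb;
  fcube out(a.n_rows, a.n_cols, (size_t)C * N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < Ca; ++c)
      out.slice((size_t)c + (size_t)C * n) = a.slice((size_t)c + (size_t)Ca * n);
    for (int c = 0; c < Cb; ++c)
      out.slice((size_t)Ca + c + (size_t)C * n) = b.slice((size_t)c + (size_t)Cb * n);
  }
  return out;
}

static void split_ch(const fcube& d, int Ca, int Cb, int N, fcube& da, fcube& db) {
  const int C = Ca + Cb;
  da.set_size(d.n_rows, d.n_cols, (size_t)Ca * N);
  db.set_size(d.n_rows, d.n_cols, (size_t)Cb * N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < Ca; ++c)
      da.slice((size_t)c + (size_t)Ca * n) = d.slice((size_t)c + (size_t)C * n);
    for (int c = 0; c < Cb; ++c)
      db.slice((size_t)c + (size_t)Cb * n) = d.slice((size_t)Ca + c + (size_t)C * n);
  }
}

// ------------------------------------------------------------------ units --

static fcube unit_fwd(const Unit& u, const fcube& x, int H, int W, int N,
                      float slope, bool train, UnitCache* uc) {
  fcube cur;
  const fcube* in = &x;
  if (u.has_gn) {
    cur = gn_fwd(u.gn, x, H, W, N,
                 train ? &uc->xhat : nullptr,
                 train ? &uc->invstd : nullptr);
    in = &cur;
  }
  fcube out = conv_fwd(u.conv, *in, H, W, N, train ? &uc->cols : nullptr);
  lrelu_inplace(out, slope, train ? &uc->mask : nullptr);
  return out;
}

static fcube unit_bwd(Unit& u, UnitCache& uc, fcube dy,
                      int H, int W, int N, float slope, bool need_dx = true) {
  {
    float* d = dy.memptr();
    const unsigned char* mk = uc.mask.data();
    const size_t n = dy.n_elem;
    for (size_t i = 0; i < n; ++i)
      if (mk[i]) d[i] *= slope;
  }
  conv_bwd(u.conv, uc, dy, H, W, N, need_dx);
  if (!need_dx) return fcube();
  if (u.has_gn)
    return gn_bwd(u.gn, uc.xhat, uc.invstd, uc.dx, H, W, N);
  return uc.dx;
}

// ------------------------------------------------------------- model init --

static int pick_groups(int C, int pref) {
  int g = std::min(pref, C);
  while (C % g != 0) --g;
  return g;
}

static void init_conv(Conv& cv, int Cin, int Cout, int k, bool zero) {
  cv.Cin = Cin; cv.Cout = Cout; cv.k = k;
  const int K = k * k * Cin;
  cv.W.set_size(K, Cout);
  if (zero) {
    cv.W.zeros();
  } else {
    const double sd = std::sqrt(2.0 / K);
    for (uword j = 0; j < cv.W.n_cols; ++j)
      for (uword i = 0; i < cv.W.n_rows; ++i)
        cv.W(i, j) = (float)(R::norm_rand() * sd);
  }
  cv.b.zeros(Cout);
  cv.dW.zeros(K, Cout); cv.mW.zeros(K, Cout); cv.vW.zeros(K, Cout);
  cv.db.zeros(Cout); cv.mb.zeros(Cout); cv.vb.zeros(Cout);
}

static void init_gn(GNorm& g, int C, int pref_groups) {
  g.C = C;
  g.G = pick_groups(C, pref_groups);
  g.gamma.ones(C); g.beta.zeros(C);
  g.dgamma.zeros(C); g.dbeta.zeros(C);
  g.mgam.zeros(C); g.vgam.zeros(C); g.mbet.zeros(C); g.vbet.zeros(C);
}

static Unit make_unit(int Cin, int Cout, bool gn, int groups) {
  Unit u;
  u.has_gn = gn;
  if (gn) init_gn(u.gn, Cin, groups);
  init_conv(u.conv, Cin, Cout, 3, false);
  return u;
}

static Model* build_model(int in_ch, int base, int depth, int groups,
                          double slope, bool zero_head) {
  Model* m = new Model();
  m->in_ch = in_ch; m->base = base; m->depth = depth;
  m->groups = groups; m->slope = (float)slope;
  int cin = in_ch;
  for (int s = 0; s < depth; ++s) {
    const int cf = base << s;
    m->enc.push_back(make_unit(cin, cf, !(s == 0 && m->enc.empty()), groups));
    m->enc.push_back(make_unit(cf, cf, true, groups));
    cin = cf;
  }
  const int cb = base << depth;
  m->bot.push_back(make_unit(cin, cb, true, groups));
  m->bot.push_back(make_unit(cb, cb, true, groups));
  int cprev = cb;
  for (int s = depth - 1; s >= 0; --s) {
    const int cf = base << s;
    m->dec.push_back(make_unit(cprev + cf, cf, true, groups));
    m->dec.push_back(make_unit(cf, cf, true, groups));
    cprev = cf;
  }
  init_conv(m->head, cprev, 1, 1, zero_head);
  return m;
}

// --------------------------------------------------------------- forward --

static fcube model_fwd(Model& M, const fcube& input, int H, int W, int N,
                       bool train) {
  if (H % (1 << M.depth) || W % (1 << M.depth))
    stop("input dimensions must be divisible by %d", 1 << M.depth);
  Tape local;
  Tape& T = train ? M.tape : local;
  T.H0 = H; T.W0 = W; T.N = N;
  T.enc_uc.resize(M.enc.size());
  T.bot_uc.resize(M.bot.size());
  T.dec_uc.resize(M.dec.size());
  T.skips.resize(M.depth);
  T.poolarg.resize(M.depth);

  fcube x = input;
  int h = H, w = W;
  for (int s = 0; s < M.depth; ++s) {
    const int cf = M.base << s;
    x = unit_fwd(M.enc[2 * s], x, h, w, N, M.slope, train,
                 train ? &T.enc_uc[2 * s] : nullptr);
    x = unit_fwd(M.enc[2 * s + 1], x, h, w, N, M.slope, train,
                 train ? &T.enc_uc[2 * s + 1] : nullptr);
    T.skips[s] = x;
    x = pool_fwd(x, h, w, cf * N, train ? &T.poolarg[s] : nullptr);
    h /= 2; w /= 2;
  }
  x = unit_fwd(M.bot[0], x, h, w, N, M.slope, train,
               train ? &T.bot_uc[0] : nullptr);
  x = unit_fwd(M.bot[1], x, h, w, N, M.slope, train,
               train ? &T.bot_uc[1] : nullptr);
  int cprev = M.base << M.depth;
  for (int s = M.depth - 1; s >= 0; --s) {
    const int cf = M.base << s;
    const int di = 2 * (M.depth - 1 - s);
    x = up_fwd(x, h, w, cprev * N);
    h *= 2; w *= 2;
    x = concat_ch(x, cprev, T.skips[s], cf, N);
    x = unit_fwd(M.dec[di], x, h, w, N, M.slope, train,
                 train ? &T.dec_uc[di] : nullptr);
    x = unit_fwd(M.dec[di + 1], x, h, w, N, M.slope, train,
                 train ? &T.dec_uc[di + 1] : nullptr);
    cprev = cf;
  }
  fcube S = conv_fwd(M.head, x, h, w, N, train ? &T.head_cols : nullptr);
  return S;  // (H, W, 1*N)
}

static void model_bwd(Model& M, const fcube& dS) {
  Tape& T = M.tape;
  const int N = T.N;
  int h = T.H0, w = T.W0;
  // decoder runs at full resolution at its end
  fcube dx;
  {
    // head backward (input had M.base channels at full res)
    ensure_mat(T.head_dY, (size_t)h * w * N, 1);
    for (int n = 0; n < N; ++n)
      std::memcpy(T.head_dY.colptr(0) + (size_t)h * w * n,
                  dS.slice_memptr(n), sizeof(float) * (size_t)h * w);
    M.head.dW = T.head_cols.t() * T.head_dY;
    M.head.db = sum(T.head_dY, 0);
    ensure_mat(T.head_dcols, (size_t)h * w * N, M.head.Cin);
    T.head_dcols = T.head_dY * M.head.W.t();
    unflatten1(T.head_dcols, h, w, M.head.Cin, N, dx);
  }
  std::vector<fcube> dskips(M.depth);
  int cprev_after;  // channels entering the upsample at each stage
  for (int s = 0; s < M.depth; ++s) {
    // reverse of decoder stage s (the decoder ended with stage 0)
    const int cf = M.base << s;
    const int di = 2 * (M.depth - 1 - s);
    dx = unit_bwd(M.dec[di + 1], T.dec_uc[di + 1], std::move(dx), h, w, N, M.slope);
    dx = unit_bwd(M.dec[di], T.dec_uc[di], std::move(dx), h, w, N, M.slope);
    cprev_after = (s == M.depth - 1) ? (M.base << M.depth) : (M.base << (s + 1));
    fcube dup, dskip;
    split_ch(dx, cprev_after, cf, N, dup, dskip);
    dskips[s] = std::move(dskip);
    h /= 2; w /= 2;
    dx = up_bwd(dup, h, w, cprev_after * N);
  }
  dx = unit_bwd(M.bot[1], T.bot_uc[1], std::move(dx), h, w, N, M.slope);
  dx = unit_bwd(M.bot[0], T.bot_uc[0], std::move(dx), h, w, N, M.slope);
  for (int s = M.depth - 1; s >= 0; --s) {
    const int cf = M.base << s;
    fcube dpool = pool_bwd(dx, T.poolarg[s], h * 2, w * 2, cf * N);
    h *= 2; w *= 2;
    dpool += dskips[s];
    dx = unit_bwd(M.enc[2 * s + 1], T.enc_uc[2 * s + 1], std::move(dpool),
                  h, w, N, M.slope);
    // the gradient w.r.t. the network input is never used
    dx = unit_bwd(M.enc[2 * s], T.enc_uc[2 * s], std::move(dx), h, w, N,
                  M.slope, s != 0);
  }
}

// ------------------------------------------------------------------ adam --

template <typename T>
static void adam_upd(T& W, const T& g, T& mv, T& vv,
                     float lr, float b1, float b2, float eps,
                     float bc1, float bc2) {
  mv = b1 * mv + (1 - b1) * g;
  vv = b2 * vv + (1 - b2) * square(g);
  W -= lr * ((mv / bc1) / (sqrt(vv / bc2) + eps));
}

static void adam_step(Model& M, float lr, float b1, float b2, float eps) {
  M.t += 1;
  const float bc1 = 1.0f - std::pow(b1, (float)M.t);
  const float bc2 = 1.0f - std::pow(b2, (float)M.t);
  auto upd_conv = [&](Conv& c) {
    adam_upd(c.W, c.dW, c.mW, c.vW, lr, b1, b2, eps, bc1, bc2);
    adam_upd(c.b, c.db, c.mb, c.vb, lr, b1, b2, eps, bc1, bc2);
  };
  auto upd_unit = [&](Unit& u) {
    if (u.has_gn) {
      adam_upd(u.gn.gamma, u.gn.dgamma, u.gn.mgam, u.gn.vgam, lr, b1, b2, eps, bc1, bc2);
      adam_upd(u.gn.beta, u.gn.dbeta, u.gn.mbet, u.gn.vbet, lr, b1, b2, eps, bc1, bc2);
    }
    upd_conv(u.conv);
  };
  for (auto& u : M.enc) upd_unit(u);
  for (auto& u : M.bot) upd_unit(u);
  for (auto& u : M.dec) upd_unit(u);
  upd_conv(M.head);
}

// ------------------------------------------------------------------ loss --

// symmetric (edge-replicating) 1-pixel pad
static fmat pad_edge(const fmat& x) {
  const int H = x.n_rows, W = x.n_cols;
  fmat p(H + 2, W + 2);
  p.submat(1, 1, H, W) = x;
  p.row(0) = p.row(1);
  p.row(H + 1) = p.row(H);
  p.col(0) = p.col(1);
  p.col(W + 1) = p.col(W);
  return p;
}

// correlation with a 3x3 kernel on an edge-padded image
static fmat corr3_edge(const fmat& x, const float K[3][3]) {
  const int H = x.n_rows, W = x.n_cols;
  fmat p = pad_edge(x);
  fmat out(H, W);
  for (int j = 0; j < W; ++j) {
    const float* c0 = p.colptr(j);
    const float* c1 = p.colptr(j + 1);
    const float* c2 = p.colptr(j + 2);
    float* o = out.colptr(j);
    for (int i = 0; i < H; ++i)
      o[i] = K[0][0] * c0[i] + K[1][0] * c0[i + 1] + K[2][0] * c0[i + 2]
           + K[0][1] * c1[i] + K[1][1] * c1[i + 1] + K[2][1] * c1[i + 2]
           + K[0][2] * c2[i] + K[1][2] * c2[i + 1] + K[2][2] * c2[i + 2];
  }
  return out;
}

// adjoint of corr3_edge (scatter through the edge padding)
static fmat corr3_edge_adj(const fmat& g, const float K[3][3]) {
  const int H = g.n_rows, W = g.n_cols;
  fmat p(H + 2, W + 2, fill::zeros);
  for (int j = 0; j < W; ++j) {
    const float* gc = g.colptr(j);
    for (int dj = 0; dj < 3; ++dj) {
      float* pc = p.colptr(j + dj);
      for (int di = 0; di < 3; ++di) {
        const float k = K[di][dj];
        for (int i = 0; i < H; ++i) pc[i + di] += k * gc[i];
      }
    }
  }
  fmat out = p.submat(1, 1, H, W);
  out.row(0) += p.row(0).subvec(1, W);
  out.row(H - 1) += p.row(H + 1).subvec(1, W);
  out.col(0) += p.col(0).subvec(1, H);
  out.col(W - 1) += p.col(W + 1).subvec(1, H);
  // corners of the padded frame fold onto the image corners
  out(0, 0) += p(0, 0);
  out(0, W - 1) += p(0, W + 1);
  out(H - 1, 0) += p(H + 1, 0);
  out(H - 1, W - 1) += p(H + 1, W + 1);
  return out;
}

static const float SOBEL_X[3][3] = {  // derivative along columns
  {-1.f, 0.f, 1.f}, {-2.f, 0.f, 2.f}, {-1.f, 0.f, 1.f}
};
static const float SOBEL_Y[3][3] = {  // derivative along rows
  {-1.f, -2.f, -1.f}, {0.f, 0.f, 0.f}, {1.f, 2.f, 1.f}
};

// per-slice min-max with detached constants; constant slice -> zeros
static fmat mm_norm(const fmat& x, float* scale_out) {
  const float lo = x.min(), hi = x.max();
  if (hi > lo) {
    if (scale_out) *scale_out = 1.0f / (hi - lo);
    return (x - lo) / (hi - lo);
  }
  if (scale_out) *scale_out = 0.0f;
  return fmat(x.n_rows, x.n_cols, fill::zeros);
}

// training loss on one slice pair, both already living in the same
// normalized frame (the triplet's joint x1/x2 min-max); exact gradient
static void slice_loss_train(const fmat& yhat, const fmat& ytarget,
                             float lambda, double* mae_out, double* gmae_out,
                             fmat* dyhat) {
  const double P = (double)yhat.n_elem;
  fmat diff = yhat - ytarget;
  *mae_out = accu(conv_to<mat>::from(abs(diff))) / P;
  fmat dyn = sign(diff) / (float)P;
  fmat gx = corr3_edge(yhat, SOBEL_X), gy = corr3_edge(yhat, SOBEL_Y);
  fmat mag = sqrt(square(gx) + square(gy));
  fmat tgx = corr3_edge(ytarget, SOBEL_X), tgy = corr3_edge(ytarget, SOBEL_Y);
  fmat tmag = sqrt(square(tgx) + square(tgy));
  fmat gdiff = mag - tmag;
  *gmae_out = accu(conv_to<mat>::from(abs(gdiff))) / P;
  if (dyhat) {
    fmat dmag = sign(gdiff) * (lambda / (float)P);
    fmat safe = mag;
    safe.transform([](float v) { return v > 0.0f ? v : 1.0f; });
    fmat dgx = dmag % gx / safe;
    fmat dgy = dmag % gy / safe;
    dyn += corr3_edge_adj(dgx, SOBEL_X) + corr3_edge_adj(dgy, SOBEL_Y);
    *dyhat = dyn;
  }
}

// evaluation metric on one slice pair: both sides min-max normalized
// per slice (value only, no gradient)
static void slice_loss_eval(const fmat& yhat, const fmat& ytrue, float lambda,
                            double* mae_out, double* gmae_out) {
  fmat yn = mm_norm(yhat, nullptr);
  fmat tn = mm_norm(ytrue, nullptr);
  slice_loss_train(yn, tn, lambda, mae_out, gmae_out, nullptr);
}

// ------------------------------------------------------------- R bindings --

static fcube cube_from_R(const NumericVector& x, int H, int W, int S) {
  if ((size_t)x.size() != (size_t)H * W * S)
    stop("array size mismatch");
  fcube out(H, W, S);
  const double* p = x.begin();
  float* q = out.memptr();
  const size_t n = out.n_elem;
  for (size_t i = 0; i < n; ++i) q[i] = (float)p[i];
  return out;
}

static NumericVector cube_to_R(const fcube& x, int H, int W, int S) {
  NumericVector out((R_xlen_t)x.n_elem);
  const float* q = x.memptr();
  for (size_t i = 0; i < x.n_elem; ++i) out[i] = (double)q[i];
  out.attr("dim") = Rcpp::IntegerVector::create(H, W, S);
  return out;
}

// [[Rcpp::export]]
SEXP unet_create_cpp(int in_ch, int base, int depth, int groups,
                     double slope, bool zero_head) {
  if (base < 1 || depth < 1 || depth > 6 || in_ch < 1)
    stop("invalid architecture parameters");
#ifdef __GLIBC__
  // keep freed large blocks in the heap instead of returning them to the
  // OS: the training loop reallocates similarly sized cubes every iteration
  mallopt(M_MMAP_THRESHOLD, 512 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 512 * 1024 * 1024);
#endif
  Model* m = build_model(in_ch, base, depth, groups, slope, zero_head);
  Rcpp::XPtr<Model> ptr(m, true);
  return ptr;
}

// [[Rcpp::export]]
List unet_meta_cpp(SEXP ptr_) {
  Rcpp::XPtr<Model> M(ptr_);
  Rcpp::IntegerVector widths(M->depth);
  for (int s = 0; s < M->depth; ++s) widths[s] = M->base << s;
  return List::create(
    Named("in_channels") = M->in_ch,
    Named("base_width") = M->base,
    Named("depth") = M->depth,
    Named("group_norm_groups") = M->groups,
    Named("leaky_slope") = M->slope,
    Named("encoder_widths") = widths,
    Named("bottleneck_channels") = M->base << M->depth);
}

// [[Rcpp::export]]
NumericVector unet_forward_cpp(SEXP ptr_, NumericVector x, int H, int W, int N) {
  Rcpp::XPtr<Model> M(ptr_);
  fcube in = cube_from_R(x, H, W, M->in_ch * N);
  fcube S = model_fwd(*M, in, H, W, N, false);
  return cube_to_R(S, H, W, N);
}

// [[Rcpp::export]]
List unet_train_step_cpp(SEXP ptr_, NumericVector x, NumericVector ylin,
                         NumericVector y, int H, int W, int N,
                         double lr, double lambda,
                         double beta1, double beta2, double eps) {
  Rcpp::XPtr<Model> M(ptr_);
  fcube in = cube_from_R(x, H, W, M->in_ch * N);
  fcube yl = cube_from_R(ylin, H, W, N);
  fcube yt = cube_from_R(y, H, W, N);
  fcube S = model_fwd(*M, in, H, W, N, true);
  fcube yhat = S + yl;
  double mae = 0.0, gmae = 0.0;
  fcube dS(H, W, N);
  for (int n = 0; n < N; ++n) {
    double m1, m2;
    fmat d;
    slice_loss_train(yhat.slice(n), yt.slice(n), (float)lambda, &m1, &m2, &d);
    mae += m1; gmae += m2;
    dS.slice(n) = d / (float)N;
  }
  mae /= N; gmae /= N;
  const double loss = mae + lambda * gmae;
  if (!std::isfinite(loss))
    return List::create(Named("loss") = loss, Named("mae") = mae,
                        Named("grad_mae") = gmae);
  model_bwd(*M, dS);
  adam_step(*M, (float)lr, (float)beta1, (float)beta2, (float)eps);
  return List::create(Named("loss") = loss, Named("mae") = mae,
                      Named("grad_mae") = gmae);
}

// [[Rcpp::export]]
List unet_eval_loss_cpp(SEXP ptr_, NumericVector x, NumericVector ylin,
                        NumericVector y, int H, int W, int N, double lambda) {
  Rcpp::XPtr<Model> M(ptr_);
  fcube in = cube_from_R(x, H, W, M->in_ch * N);
  fcube yl = cube_from_R(ylin, H, W, N);
  fcube yt = cube_from_R(y, H, W, N);
  fcube S = model_fwd(*M, in, H, W, N, false);
  fcube yhat = S + yl;
  NumericVector mae(N), gmae(N);
  for (int n = 0; n < N; ++n) {
    double m1, m2;
    slice_loss_eval(yhat.slice(n), yt.slice(n), (float)lambda, &m1, &m2);
    mae[n] = m1; gmae[n] = m2;
  }
  return List::create(Named("mae") = mae, Named("grad_mae") = gmae);
}

// [[Rcpp::export]]
void unet_zero_head_cpp(SEXP ptr_) {
  Rcpp::XPtr<Model> M(ptr_);
  M->head.W.zeros();
  M->head.b.zeros();
}

static NumericMatrix fmat_to_R(const fmat& x) {
  NumericMatrix out(x.n_rows, x.n_cols);
  for (uword j = 0; j < x.n_cols; ++j)
    for (uword i = 0; i < x.n_rows; ++i)
      out(i, j) = x(i, j);
  return out;
}

static fmat fmat_from_R(const NumericMatrix& x) {
  fmat out(x.nrow(), x.ncol());
  for (int j = 0; j < x.ncol(); ++j)
    for (int i = 0; i < x.nrow(); ++i)
      out(i, j) = (float)x(i, j);
  return out;
}

static List unit_to_R(const Unit& u) {
  List out = List::create(
    Named("has_gn") = u.has_gn,
    Named("W") = fmat_to_R(u.conv.W),
    Named("b") = NumericVector(u.conv.b.begin(), u.conv.b.end()),
    Named("cin") = u.conv.Cin,
    Named("cout") = u.conv.Cout);
  if (u.has_gn) {
    out["gamma"] = NumericVector(u.gn.gamma.begin(), u.gn.gamma.end());
    out["beta"] = NumericVector(u.gn.beta.begin(), u.gn.beta.end());
  }
  return out;
}

static void unit_from_R(Unit& u, const List& l) {
  u.conv.W = fmat_from_R(Rcpp::as<NumericMatrix>(l["W"]));
  NumericVector b = l["b"];
  u.conv.b = frowvec(b.size());
  for (int i = 0; i < b.size(); ++i) u.conv.b(i) = (float)b[i];
  if (u.has_gn) {
    NumericVector g = l["gamma"], be = l["beta"];
    for (int i = 0; i < g.size(); ++i) u.gn.gamma(i) = (float)g[i];
    for (int i = 0; i < be.size(); ++i) u.gn.beta(i) = (float)be[i];
  }
}

// [[Rcpp::export]]
List unet_export_cpp(SEXP ptr_) {
  Rcpp::XPtr<Model> M(ptr_);
  List enc(M->enc.size()), bot(M->bot.size()), dec(M->dec.size());
  for (size_t i = 0; i < M->enc.size(); ++i) enc[i] = unit_to_R(M->enc[i]);
  for (size_t i = 0; i < M->bot.size(); ++i) bot[i] = unit_to_R(M->bot[i]);
  for (size_t i = 0; i < M->dec.size(); ++i) dec[i] = unit_to_R(M->dec[i]);
  return List::create(
    Named("in_channels") = M->in_ch,
    Named("base_width") = M->base,
    Named("depth") = M->depth,
    Named("group_norm_groups") = M->groups,
    Named("leaky_slope") = (double)M->slope,
    Named("encoder") = enc,
    Named("bottleneck") = bot,
    Named("decoder") = dec,
    Named("head_W") = fmat_to_R(M->head.W),
    Named("head_b") = NumericVector(M->head.b.begin(), M->head.b.end()));
}

// [[Rcpp::export]]
SEXP unet_import_cpp(List params) {
  const int in_ch = params["in_channels"], base = params["base_width"];
  const int depth = params["depth"], groups = params["group_norm_groups"];
  const double slope = params["leaky_slope"];
  Model* M = build_model(in_ch, base, depth, groups, slope, true);
  List enc = params["encoder"], bot = params["bottleneck"], dec = params["decoder"];
  if ((size_t)enc.size() != M->enc.size() || (size_t)bot.size() != M->bot.size()
      || (size_t)dec.size() != M->dec.size()) {
    delete M;
    stop("parameter list does not match the declared architecture");
  }
  for (size_t i = 0; i < M->enc.size(); ++i) unit_from_R(M->enc[i], enc[i]);
  for (size_t i = 0; i < M->bot.size(); ++i) unit_from_R(M->bot[i], bot[i]);
  for (size_t i = 0; i < M->dec.size(); ++i) unit_from_R(M->dec[i], dec[i]);
  M->head.W = fmat_from_R(Rcpp::as<NumericMatrix>(params["head_W"]));
  NumericVector hb = params["head_b"];
  for (int i = 0; i < hb.size(); ++i) M->head.b(i) = (float)hb[i];
  Rcpp::XPtr<Model> ptr(M, true);
  return ptr;
}

// gradient snapshot after the last training step (testing/diagnostics)
// [[Rcpp::export]]
List unet_grads_cpp(SEXP ptr_) {
  Rcpp::XPtr<Model> M(ptr_);
  auto grad_unit = [](const Unit& u) {
    List l = List::create(Named("dW") = fmat_to_R(u.conv.dW),
                          Named("db") = NumericVector(u.conv.db.begin(),
                                                      u.conv.db.end()));
    if (u.has_gn) {
      l["dgamma"] = NumericVector(u.gn.dgamma.begin(), u.gn.dgamma.end());
      l["dbeta"] = NumericVector(u.gn.dbeta.begin(), u.gn.dbeta.end());
    }
    return l;
  };
  List enc(M->enc.size()), bot(M->bot.size()), dec(M->dec.size());
  for (size_t i = 0; i < M->enc.size(); ++i) enc[i] = grad_unit(M->enc[i]);
  for (size_t i = 0; i < M->bot.size(); ++i) bot[i] = grad_unit(M->bot[i]);
  for (size_t i = 0; i < M->dec.size(); ++i) dec[i] = grad_unit(M->dec[i]);
  return List::create(Named("encoder") = enc, Named("bottleneck") = bot,
                      Named("decoder") = dec,
                      Named("head_dW") = fmat_to_R(M->head.dW),
                      Named("head_db") = NumericVector(M->head.db.begin(),
                                                       M->head.db.end()));
}

// [[Rcpp::export]]
void unet_randomize_head_cpp(SEXP ptr_, double sd) {
  Rcpp::XPtr<Model> M(ptr_);
  for (uword j = 0; j < M->head.W.n_cols; ++j)
    for (uword i = 0; i < M->head.W.n_rows; ++i)
      M->head.W(i, j) = (float)(R::norm_rand() * sd);
}
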