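// Compact 3D U-Net engine in single precision.
//
// Feature maps are stored channels-first as arma::fmat (C rows, one column
// per voxel); voxels are ordered x-fastest (R column-major array order).
// 3x3x3 convolutions with zero padding 1 are realised as 27 shifted BLAS
// sgemm accumulations (one per kernel offset) plus explicit boundary
// corrections, instead of an im2col materialisation: on a single CPU the
// im2col buffers (hundreds of MB per layer) cost more in memory traffic
// than the arithmetic itself, while the shifted formulation keeps the
// operands cache-resident. Blocks are conv -> GroupNorm -> ReLU (twice per
// resolution level), 2x2x2 max pooling down, nearest-neighbour upsampling
// with skip concatenation up, and a 1x1x1 classifier. Forward and backward
// both live here; the optimiser (Adam) lives in R.
#include <RcppArmadillo.h>
#include <map>
#include <array>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::fmat;
using arma::fvec;

struct Dims {
  int d1, d2, d3;
  long n() const { return (long)d1 * d2 * d3; }
  bool operator<(const Dims& o) const {
    return std::tie(d1, d2, d3) < std::tie(o.d1, o.d2, o.d3);
  }
};

// ---- shift plan: per kernel offset, the valid linear-shift range and the
// ---- columns whose x/y neighbour wraps across row/plane boundaries -------

struct OffsetPlan {
  std::array<long, 27> shift, lo, hi;   // valid destination range [lo, hi)
  std::array<std::vector<long>, 27> bad; // destinations needing correction
};

static const OffsetPlan& plan_for(const Dims& d) {
  static std::map<Dims, OffsetPlan> cache;
  auto it = cache.find(d);
  if (it != cache.end()) return it->second;
  OffsetPlan p;
  int k = 0;
  for (int oz = -1; oz <= 1; ++oz)
    for (int oy = -1; oy <= 1; ++oy)
      for (int ox = -1; ox <= 1; ++ox, ++k) {
        long sh = ox + (long)d.d1 * (oy + (long)d.d2 * oz);
        p.shift[k] = sh;
        p.lo[k] = std::max(0L, -sh);
        p.hi[k] = std::min((long)d.n(), d.n() - sh);
        auto& bad = p.bad[k];
        for (int z = 0; z < d.d3; ++z) {
          if (z + oz < 0 || z + oz >= d.d3) continue; // outside [lo, hi)
          for (int y = 0; y < d.d2; ++y) {
            bool ybad = (y + oy < 0 || y + oy >= d.d2);
            long base = (long)d.d1 * (y + (long)d.d2 * z);
            if (ybad) {
              for (int x = 0; x < d.d1; ++x) {
                long v = base + x;
                if (v >= p.lo[k] && v < p.hi[k]) bad.push_back(v);
              }
            } else if (ox != 0) {
              int x = (ox < 0) ? 0 : d.d1 - 1;
              long v = base + x;
              if (v >= p.lo[k] && v < p.hi[k]) bad.push_back(v);
            }
          }
        }
      }
  return cache.emplace(d, std::move(p)).first->second;
}

// Thin wrappers over BLAS sgemm operating on raw column-major panels.
static void sgemm_nn(int m, long n, int k, float alpha, const float* A,
                     int lda, const float* B, int ldb, float beta, float* C,
                     int ldc) {
  if (n <= 0) return;
  arma::blas_int M = m, N = (arma::blas_int)n, K = k, LDA = lda, LDB = ldb,
                 LDC = ldc;
  arma::blas::gemm<float>("N", "N", &M, &N, &K, &alpha, A, &LDA, B, &LDB,
                          &beta, C, &LDC);
}
static void sgemm_tn(int m, long n, int k, float alpha, const float* A,
                     int lda, const float* B, int ldb, float beta, float* C,
                     int ldc) {
  if (n <= 0) return;
  arma::blas_int M = m, N = (arma::blas_int)n, K = k, LDA = lda, LDB = ldb,
                 LDC = ldc;
  arma::blas::gemm<float>("T", "N", &M, &N, &K, &alpha, A, &LDA, B, &LDB,
                          &beta, C, &LDC);
}
static void sgemm_nt(int m, int n, long k, float alpha, const float* A,
                     int lda, const float* B, int ldb, float beta, float* C,
                     int ldc) {
  if (k <= 0 && beta == 1.0f) return;
  arma::blas_int M = m, N = n, K = (arma::blas_int)std::max(0L, k), LDA = lda,
                 LDB = ldb, LDC = ldc;
  arma::blas::gemm<float>("N", "T", &M, &N, &K, &alpha, A, &LDA, B, &LDB,
                          &beta, C, &LDC);
}

// ---- 3x3x3 convolution via shifted gemms --------------------------------

// Z = W (*) X + b. W: Cout x 27*Cin, offset-major column blocks. The
// central offset (shift 0, full range) runs first with beta = 0, so Z needs
// no zero-initialisation; the bias is added afterwards.
static void conv3_fwd(const fmat& W, const fvec& b, const fmat& X,
                      const Dims& d, fmat& Z) {
  const int Cin = X.n_rows, Cout = W.n_rows;
  const long N = X.n_cols;
  const OffsetPlan& pl = plan_for(d);
  Z.set_size(Cout, N);
  fmat gath, corr;
  for (int kk = 0; kk < 27; ++kk) {
    int k = (kk == 0) ? 13 : (kk <= 13 ? kk - 1 : kk); // central offset first
    const float* Wk = W.colptr((arma::uword)k * Cin);
    long lo = pl.lo[k], hi = pl.hi[k], sh = pl.shift[k];
    sgemm_nn(Cout, hi - lo, Cin, 1.0f, Wk, Cout, X.colptr(lo + sh), Cin,
             (kk == 0) ? 0.0f : 1.0f, Z.colptr(lo), Cout);
    const auto& bad = pl.bad[k];
    if (bad.empty()) continue;
    gath.set_size(Cin, bad.size());
    for (size_t i = 0; i < bad.size(); ++i)
      std::memcpy(gath.colptr(i), X.colptr(bad[i] + sh), Cin * sizeof(float));
    corr = fmat(const_cast<float*>(Wk), Cout, Cin, false, true) * gath;
    for (size_t i = 0; i < bad.size(); ++i) {
      float* zc = Z.colptr(bad[i]);
      const float* cc = corr.colptr(i);
      for (int c = 0; c < Cout; ++c) zc[c] -= cc[c];
    }
  }
  Z.each_col() += b;
}

// dX = W^T (*)^T dZ (adjoint of conv3_fwd); dX must be pre-sized (not
// zeroed: the central offset runs first with beta = 0 over the full range).
static void conv3_bwd_data(const fmat& W, const fmat& dZ, const Dims& d,
                           fmat& dX) {
  const int Cout = W.n_rows, Cin = dX.n_rows;
  const OffsetPlan& pl = plan_for(d);
  fmat gath, corr;
  for (int kk = 0; kk < 27; ++kk) {
    int k = (kk == 0) ? 13 : (kk <= 13 ? kk - 1 : kk);
    const float* Wk = W.colptr((arma::uword)k * Cin);
    long lo = pl.lo[k], hi = pl.hi[k], sh = pl.shift[k];
    sgemm_tn(Cin, hi - lo, Cout, 1.0f, Wk, Cout, dZ.colptr(lo), Cout,
             (kk == 0) ? 0.0f : 1.0f, dX.colptr(lo + sh), Cin);
    const auto& bad = pl.bad[k];
    if (bad.empty()) continue;
    gath.set_size(Cout, bad.size());
    for (size_t i = 0; i < bad.size(); ++i)
      std::memcpy(gath.colptr(i), dZ.colptr(bad[i]), Cout * sizeof(float));
    corr = fmat(const_cast<float*>(Wk), Cout, Cin, false, true).t() * gath;
    for (size_t i = 0; i < bad.size(); ++i) {
      float* xc = dX.colptr(bad[i] + sh);
      const float* cc = corr.colptr(i);
      for (int c = 0; c < Cin; ++c) xc[c] -= cc[c];
    }
  }
}

// dW = dZ (*) X^T and db = rowsum(dZ), written into flat gradient storage.
static void conv3_bwd_weights(const fmat& X, const fmat& dZ, const Dims& d,
                              float* dW, float* db) {
  const int Cin = X.n_rows, Cout = dZ.n_rows;
  const OffsetPlan& pl = plan_for(d);
  fmat gz, gx, corr;
  for (int k = 0; k < 27; ++k) {
    long lo = pl.lo[k], hi = pl.hi[k], sh = pl.shift[k];
    float* dWk = dW + (long)k * Cin * Cout;
    sgemm_nt(Cout, Cin, hi - lo, 1.0f, dZ.colptr(lo), Cout,
             X.colptr(lo + sh), Cin, 0.0f, dWk, Cout);
    const auto& bad = pl.bad[k];
    if (!bad.empty()) {
      gz.set_size(Cout, bad.size());
      gx.set_size(Cin, bad.size());
      for (size_t i = 0; i < bad.size(); ++i) {
        std::memcpy(gz.colptr(i), dZ.colptr(bad[i]), Cout * sizeof(float));
        std::memcpy(gx.colptr(i), X.colptr(bad[i] + sh), Cin * sizeof(float));
      }
      corr = gz * gx.t();
      for (long j = 0; j < (long)Cin * Cout; ++j) dWk[j] -= corr[j];
    }
  }
  const long N = dZ.n_cols;
  std::vector<double> acc(Cout, 0.0);
  const float* z = dZ.memptr();
  for (long v = 0; v < N; ++v)
    for (int c = 0; c < Cout; ++c) acc[c] += z[v * Cout + c];
  for (int c = 0; c < Cout; ++c) db[c] = (float)acc[c];
}

// ---- layer bookkeeping --------------------------------------------------

struct ConvSpec {
  int cout, cin, kernel; // kernel: 27 or 1
  bool gn;               // GroupNorm + ReLU after the convolution?
  long w_off, b_off, g_off, be_off;
};

static int gn_groups_for(int channels, int pref) {
  int g = std::min(channels, pref);
  while (g > 1 && channels % g != 0) --g;
  return g;
}

static std::vector<ConvSpec> make_specs(int n_levels, int base, int in_ch,
                                        int n_classes, long* total) {
  std::vector<ConvSpec> specs;
  auto add = [&](int cout, int cin, int kernel, bool gn) {
    ConvSpec s;
    s.cout = cout; s.cin = cin; s.kernel = kernel; s.gn = gn;
    specs.push_back(s);
  };
  int prev = in_ch;
  for (int i = 0; i < n_levels; ++i) {
    int ch = base << i;
    add(ch, prev, 27, true);
    add(ch, ch, 27, true);
    prev = ch;
  }
  for (int i = n_levels - 2; i >= 0; --i) {
    int ch = base << i;
    add(ch, (base << (i + 1)) + ch, 27, true);
    add(ch, ch, 27, true);
  }
  add(n_classes, base, 1, false);
  long off = 0;
  for (auto& s : specs) {
    s.w_off = off; off += (long)s.cout * s.cin * s.kernel;
    s.b_off = off; off += s.cout;
    if (s.gn) { s.g_off = off; off += s.cout; s.be_off = off; off += s.cout; }
    else { s.g_off = s.be_off = -1; }
  }
  *total = off;
  return specs;
}

// [[Rcpp::export(name = ".unet_layout")]]
List unet_layout(int n_levels, int base_channels, int in_channels, int n_classes) {
  long total = 0;
  auto specs = make_specs(n_levels, base_channels, in_channels, n_classes, &total);
  int L = specs.size();
  IntegerVector cout(L), cin(L), kernel(L), gn(L);
  NumericVector w_off(L), b_off(L), g_off(L), be_off(L);
  for (int i = 0; i < L; ++i) {
    cout[i] = specs[i].cout; cin[i] = specs[i].cin; kernel[i] = specs[i].kernel;
    gn[i] = specs[i].gn;
    w_off[i] = specs[i].w_off; b_off[i] = specs[i].b_off;
    g_off[i] = specs[i].g_off; be_off[i] = specs[i].be_off;
  }
  return List::create(_["cout"] = cout, _["cin"] = cin, _["kernel"] = kernel,
                      _["gn"] = gn, _["w_offset"] = w_off, _["b_offset"] = b_off,
                      _["gamma_offset"] = g_off, _["beta_offset"] = be_off,
                      _["n_params"] = (double)total);
}

// ---- group norm + ReLU, single-pass loops -------------------------------

static const float GN_EPS = 1e-5f;

struct ConvCtx {
  fmat xhat;      // normalised pre-activation (ReLU mask is recomputed
                  // from gamma * xhat + beta > 0 in the backward pass)
  fvec istd;      // per-group inverse SD
  int groups;
};

// Z -> A = relu(gamma * xhat + beta); fills ctx with xhat and stats.
static void gn_relu_fwd(fmat& Z, const fvec& gamma, const fvec& beta, int g,
                        ConvCtx& ctx, fmat& A) {
  const int C = Z.n_rows, cg = C / g;
  const long N = Z.n_cols;
  std::vector<double> s1(g, 0.0), s2(g, 0.0);
  const float* z = Z.memptr();
  for (long v = 0; v < N; ++v) {
    const float* col = z + v * C;
    for (int c = 0; c < C; ++c) {
      double x = col[c];
      s1[c / cg] += x;
      s2[c / cg] += x * x;
    }
  }
  ctx.groups = g;
  ctx.istd.set_size(g);
  std::vector<float> mu(g);
  for (int j = 0; j < g; ++j) {
    double m = s1[j] / ((double)cg * N);
    double var = s2[j] / ((double)cg * N) - m * m;
    mu[j] = (float)m;
    ctx.istd[j] = 1.0f / std::sqrt((float)var + GN_EPS);
  }
  ctx.xhat.set_size(C, N);
  A.set_size(C, N);
  float* xh = ctx.xhat.memptr();
  float* a = A.memptr();
  float* zz = Z.memptr();
  for (long v = 0; v < N; ++v) {
    long o = v * C;
    for (int c = 0; c < C; ++c) {
      float h = (zz[o + c] - mu[c / cg]) * ctx.istd[c / cg];
      xh[o + c] = h;
      float y = gamma[c] * h + beta[c];
      a[o + c] = y > 0.0f ? y : 0.0f;
    }
  }
}

// dA -> dZ (in place), plus dgamma/dbeta.
static void gn_relu_bwd(fmat& dA, const fvec& gamma, const fvec& beta,
                        const ConvCtx& ctx, float* dgamma, float* dbeta) {
  const int C = dA.n_rows, g = ctx.groups, cg = C / g;
  const long N = dA.n_cols;
  const float* xh = ctx.xhat.memptr();
  float* da = dA.memptr();
  std::vector<double> dg(C, 0.0), db(C, 0.0), m1(g, 0.0), m2(g, 0.0);
  for (long v = 0; v < N; ++v) {
    long o = v * C;
    for (int c = 0; c < C; ++c) {
      bool on = gamma[c] * xh[o + c] + beta[c] > 0.0f;
      float d = on ? da[o + c] : 0.0f;
      da[o + c] = d;
      dg[c] += (double)d * xh[o + c];
      db[c] += d;
      float dxh = d * gamma[c];
      m1[c / cg] += dxh;
      m2[c / cg] += (double)dxh * xh[o + c];
    }
  }
  for (int c = 0; c < C; ++c) { dgamma[c] = (float)dg[c]; dbeta[c] = (float)db[c]; }
  std::vector<float> f1(g), f2(g);
  for (int j = 0; j < g; ++j) {
    f1[j] = (float)(m1[j] / ((double)cg * N));
    f2[j] = (float)(m2[j] / ((double)cg * N));
  }
  for (long v = 0; v < N; ++v) {
    long o = v * C;
    for (int c = 0; c < C; ++c) {
      int j = c / cg;
      float dxh = da[o + c] * gamma[c];
      da[o + c] = (dxh - f1[j] - xh[o + c] * f2[j]) * ctx.istd[j];
    }
  }
}

// ---- pooling / upsampling ----------------------------------------------

static void maxpool_fwd(const fmat& X, const Dims& d, fmat& Y, arma::umat& idx,
                        Dims& dout) {
  dout = {d.d1 / 2, d.d2 / 2, d.d3 / 2};
  const int C = X.n_rows;
  Y.set_size(C, dout.n());
  idx.set_size(C, dout.n());
  long v = 0;
  for (int z = 0; z < dout.d3; ++z)
    for (int y = 0; y < dout.d2; ++y)
      for (int x = 0; x < dout.d1; ++x, ++v) {
        float* yc = Y.colptr(v);
        arma::uword* ic = idx.colptr(v);
        bool first = true;
        for (int cz = 0; cz <= 1; ++cz)
          for (int cy = 0; cy <= 1; ++cy)
            for (int cx = 0; cx <= 1; ++cx) {
              long s = (2 * x + cx) +
                       (long)d.d1 * ((2 * y + cy) + (long)d.d2 * (2 * z + cz));
              const float* xc = X.colptr(s);
              if (first) {
                for (int c = 0; c < C; ++c) { yc[c] = xc[c]; ic[c] = s; }
                first = false;
              } else {
                for (int c = 0; c < C; ++c)
                  if (xc[c] > yc[c]) { yc[c] = xc[c]; ic[c] = s; }
              }
            }
      }
}

static void maxpool_bwd(const fmat& dY, const arma::umat& idx, const Dims& din,
                        fmat& dX) {
  dX.zeros(dY.n_rows, din.n());
  const int C = dY.n_rows;
  for (arma::uword v = 0; v < dY.n_cols; ++v) {
    const float* dyc = dY.colptr(v);
    const arma::uword* ic = idx.colptr(v);
    for (int c = 0; c < C; ++c) dX(c, ic[c]) += dyc[c];
  }
}

static void upsample_fwd(const fmat& X, const Dims& d, fmat& Y, Dims& dout) {
  dout = {d.d1 * 2, d.d2 * 2, d.d3 * 2};
  const int C = X.n_rows;
  Y.set_size(C, dout.n());
  long v = 0;
  for (int z = 0; z < dout.d3; ++z)
    for (int y = 0; y < dout.d2; ++y)
      for (int x = 0; x < dout.d1; ++x, ++v)
        std::memcpy(Y.colptr(v),
                    X.colptr((x / 2) + (long)d.d1 * ((y / 2) + (long)d.d2 * (z / 2))),
                    C * sizeof(float));
}

static void upsample_bwd(const fmat& dY, const Dims& dout, fmat& dX) {
  Dims din = {dout.d1 / 2, dout.d2 / 2, dout.d3 / 2};
  const int C = dY.n_rows;
  dX.zeros(C, din.n());
  long v = 0;
  for (int z = 0; z < dout.d3; ++z)
    for (int y = 0; y < dout.d2; ++y)
      for (int x = 0; x < dout.d1; ++x, ++v) {
        float* xc = dX.colptr((x / 2) + (long)din.d1 * ((y / 2) + (long)din.d2 * (z / 2)));
        const float* yc = dY.colptr(v);
        for (int c = 0; c < C; ++c) xc[c] += yc[c];
      }
}

// ---- full network -------------------------------------------------------

struct NetState {
  std::vector<ConvSpec> specs;
  long n_params;
  int n_levels, base, in_ch, n_classes, gn_pref;
};

static NetState init_state(List cfg) {
  NetState st;
  st.n_levels = as<int>(cfg["n_levels"]);
  st.base = as<int>(cfg["base_channels"]);
  st.in_ch = as<int>(cfg["in_channels"]);
  st.n_classes = as<int>(cfg["n_classes"]);
  st.gn_pref = as<int>(cfg["gn_groups"]);
  st.specs = make_specs(st.n_levels, st.base, st.in_ch, st.n_classes, &st.n_params);
  return st;
}

static fmat get_W(const fvec& p, const ConvSpec& s) {
  return fmat(const_cast<float*>(p.memptr()) + s.w_off, s.cout,
              (arma::uword)s.cin * s.kernel, false, true);
}
static fvec get_v(const fvec& p, long off, int n) {
  return fvec(const_cast<float*>(p.memptr()) + off, n, false, true);
}

// One conv unit forward: X -> A (and Z context when training).
static void conv_unit_fwd(const fvec& p, const ConvSpec& sp, int gn_pref,
                          const Dims& d, const fmat& X, fmat& A, ConvCtx& ctx,
                          bool keep) {
  fmat Z;
  if (sp.kernel == 27)
    conv3_fwd(get_W(p, sp), get_v(p, sp.b_off, sp.cout), X, d, Z);
  else {
    Z = get_W(p, sp) * X;
    Z.each_col() += get_v(p, sp.b_off, sp.cout);
  }
  if (!sp.gn) { A = std::move(Z); return; }
  int g = gn_groups_for(sp.cout, gn_pref);
  gn_relu_fwd(Z, get_v(p, sp.g_off, sp.cout), get_v(p, sp.be_off, sp.cout),
              g, ctx, A);
  if (!keep) ctx = ConvCtx();
}

struct FwdCache {
  std::vector<fmat> act;         // input of each conv layer
  std::vector<ConvCtx> ctx;
  std::vector<arma::umat> pool_idx;
  std::vector<Dims> dims_at;     // grid of each conv layer
  fmat logits;
};

static void forward(const fvec& p, const NetState& st, const fmat& x0,
                    const Dims& d0, bool keep, FwdCache& fc) {
  const int L = st.n_levels;
  fc.act.assign(st.specs.size(), fmat());
  fc.ctx.assign(st.specs.size(), ConvCtx());
  fc.pool_idx.assign(std::max(0, L - 1), arma::umat());
  fc.dims_at.assign(st.specs.size(), d0);
  std::vector<fmat> skips(L);
  Dims d = d0;
  fmat cur = x0;
  int li = 0;
  for (int i = 0; i < L; ++i) {
    for (int cpos = 0; cpos < 2; ++cpos, ++li) {
      fmat out;
      if (keep) fc.act[li] = cur;
      fc.dims_at[li] = d;
      conv_unit_fwd(p, st.specs[li], st.gn_pref, d, cur, out, fc.ctx[li], keep);
      cur = std::move(out);
    }
    if (i < L - 1) {
      skips[i] = cur;
      fmat pooled;
      arma::umat idx;
      Dims dnew;
      maxpool_fwd(cur, d, pooled, idx, dnew);
      if (keep) fc.pool_idx[i] = std::move(idx);
      cur = std::move(pooled);
      d = dnew;
    }
  }
  for (int i = L - 2; i >= 0; --i) {
    fmat up;
    Dims dnew;
    upsample_fwd(cur, d, up, dnew);
    d = dnew;
    cur = arma::join_cols(up, skips[i]);
    skips[i].reset();
    for (int cpos = 0; cpos < 2; ++cpos, ++li) {
      fmat out;
      if (keep) fc.act[li] = cur;
      fc.dims_at[li] = d;
      conv_unit_fwd(p, st.specs[li], st.gn_pref, d, cur, out, fc.ctx[li], keep);
      cur = std::move(out);
    }
  }
  const ConvSpec& fin = st.specs.back();
  if (keep) fc.act[li] = cur;
  fc.dims_at[li] = d;
  ConvCtx dummy;
  conv_unit_fwd(p, fin, st.gn_pref, d, cur, fc.logits, dummy, false);
}

static void softmax_cols(fmat& Z) {
  arma::frowvec mx = arma::max(Z, 0);
  Z.each_row() -= mx;
  Z = arma::exp(Z);
  arma::frowvec s = arma::sum(Z, 0);
  Z.each_row() /= s;
}

// [[Rcpp::export(name = ".unet_infer")]]
NumericMatrix unet_infer(NumericVector params, NumericVector x,
                         IntegerVector dims, List cfg) {
  NetState st = init_state(cfg);
  fvec p(params.size());
  for (long i = 0; i < (long)params.size(); ++i) p[i] = (float)params[i];
  Dims d0 = {dims[0], dims[1], dims[2]};
  fmat x0(st.in_ch, d0.n());
  for (long i = 0; i < (long)x.size(); ++i) x0[i] = (float)x[i];
  FwdCache fc;
  forward(p, st, x0, d0, false, fc);
  softmax_cols(fc.logits);
  NumericMatrix out(st.n_classes, d0.n());
  for (arma::uword i = 0; i < fc.logits.n_elem; ++i) out[i] = fc.logits[i];
  return out;
}

// Combined loss: mean voxel cross-entropy + (1 - mean soft Dice over
// classes, squared denominator). Returns loss terms and the full gradient.
// [[Rcpp::export(name = ".unet_loss_grad")]]
List unet_loss_grad(NumericVector params, NumericVector x, IntegerVector labels,
                    IntegerVector dims, List cfg, double ce_weight,
                    double dice_weight) {
  NetState st = init_state(cfg);
  fvec p(params.size());
  for (long i = 0; i < (long)params.size(); ++i) p[i] = (float)params[i];
  Dims d0 = {dims[0], dims[1], dims[2]};
  const long N = d0.n();
  fmat x0(st.in_ch, N);
  for (long i = 0; i < (long)x.size(); ++i) x0[i] = (float)x[i];

  FwdCache fc;
  forward(p, st, x0, d0, true, fc);
  const int K = st.n_classes;
  fmat P = fc.logits;
  softmax_cols(P);

  double ce = 0.0;
  for (long v = 0; v < N; ++v) {
    float pv = std::max(P(labels[v], v), 1e-12f);
    ce -= std::log((double)pv);
  }
  ce /= (double)N;

  const double EPS = 1e-5;
  std::vector<double> num(K, 0.0), den(K, EPS);
  {
    const float* pm = P.memptr();
    for (long v = 0; v < N; ++v) {
      int gl = labels[v];
      const float* pc = pm + v * K;
      for (int k = 0; k < K; ++k) {
        double pk = pc[k];
        den[k] += pk * pk;
        if (k == gl) { num[k] += 2.0 * pk; den[k] += 1.0; }
      }
    }
  }
  double mean_dice = 0.0;
  for (int k = 0; k < K; ++k) mean_dice += num[k] / den[k];
  mean_dice /= K;
  double loss = ce_weight * ce + dice_weight * (1.0 - mean_dice);

  // gradient wrt logits (CE folded directly; Dice through softmax)
  fmat dZ(K, N, arma::fill::zeros);
  {
    std::vector<float> a(K), bb(K);
    for (int k = 0; k < K; ++k) {
      a[k] = (float)(-dice_weight / K * 2.0 / den[k]);
      bb[k] = (float)(-dice_weight / K * (-2.0 * num[k] / (den[k] * den[k])));
    }
    const float* pm = P.memptr();
    float* dzm = dZ.memptr();
    float wn = (float)(ce_weight / (double)N);
    for (long v = 0; v < N; ++v) {
      const float* pc = pm + v * K;
      float* dc = dzm + v * K;
      int gl = labels[v];
      if (dice_weight != 0) {
        float dot = 0.0f;
        float dp[16]; // n_classes is small (<= 16 supported here)
        for (int k = 0; k < K; ++k) {
          dp[k] = bb[k] * pc[k] + ((k == gl) ? a[k] : 0.0f);
          dot += dp[k] * pc[k];
        }
        for (int k = 0; k < K; ++k) dc[k] = pc[k] * (dp[k] - dot);
      }
      if (ce_weight != 0) {
        for (int k = 0; k < K; ++k) dc[k] += wn * pc[k];
        dc[gl] -= wn;
      }
    }
  }

  // backward
  fvec grad(st.n_params, arma::fill::zeros);
  const int L = st.n_levels;
  int li = (int)st.specs.size() - 1;
  fmat dcur;
  {
    const ConvSpec& sp = st.specs[li]; // 1x1 classifier
    fmat W = get_W(p, sp);
    const fmat& X = fc.act[li];
    fmat dW = dZ * X.t();
    std::memcpy(grad.memptr() + sp.w_off, dW.memptr(),
                dW.n_elem * sizeof(float));
    fvec db = arma::sum(dZ, 1);
    std::memcpy(grad.memptr() + sp.b_off, db.memptr(),
                sp.cout * sizeof(float));
    dcur = W.t() * dZ;
    dZ.reset();
    --li;
  }
  std::vector<fmat> dskip(L);
  for (int lev = 0; lev < L - 1; ++lev) { // decoder levels, shallowest first
    for (int cpos = 1; cpos >= 0; --cpos, --li) {
      const ConvSpec& sp = st.specs[li];
      const Dims& d = fc.dims_at[li];
      gn_relu_bwd(dcur, get_v(p, sp.g_off, sp.cout),
                  get_v(p, sp.be_off, sp.cout), fc.ctx[li],
                  grad.memptr() + sp.g_off, grad.memptr() + sp.be_off);
      conv3_bwd_weights(fc.act[li], dcur, d, grad.memptr() + sp.w_off,
                        grad.memptr() + sp.b_off);
      fmat dX(sp.cin, fc.act[li].n_cols, arma::fill::none);
      conv3_bwd_data(get_W(p, sp), dcur, d, dX);
      dcur = std::move(dX);
      fc.act[li].reset();
      fc.ctx[li] = ConvCtx();
    }
    int up_ch = st.base << (lev + 1);
    fmat dup = dcur.rows(0, up_ch - 1);
    dskip[lev] = dcur.rows(up_ch, dcur.n_rows - 1);
    Dims dhere = fc.dims_at[li + 1];
    fmat ddeep;
    upsample_bwd(dup, dhere, ddeep);
    dcur = std::move(ddeep);
  }
  for (int i = L - 1; i >= 0; --i) {
    if (i < L - 1) {
      Dims dfull = fc.dims_at[2 * i];
      fmat dpool;
      maxpool_bwd(dcur, fc.pool_idx[i], dfull, dpool);
      dcur = dpool + dskip[i];
      dskip[i].reset();
    }
    for (int cpos = 1; cpos >= 0; --cpos) {
      int lj = 2 * i + cpos;
      const ConvSpec& sp = st.specs[lj];
      const Dims& d = fc.dims_at[lj];
      gn_relu_bwd(dcur, get_v(p, sp.g_off, sp.cout),
                  get_v(p, sp.be_off, sp.cout), fc.ctx[lj],
                  grad.memptr() + sp.g_off, grad.memptr() + sp.be_off);
      conv3_bwd_weights(fc.act[lj], dcur, d, grad.memptr() + sp.w_off,
                        grad.memptr() + sp.b_off);
      bool need_dx = !(i == 0 && cpos == 0);
      if (need_dx) {
        fmat dX(sp.cin, fc.act[lj].n_cols, arma::fill::none);
        conv3_bwd_data(get_W(p, sp), dcur, d, dX);
        dcur = std::move(dX);
      }
      fc.act[lj].reset();
      fc.ctx[lj] = ConvCtx();
    }
  }

  NumericVector gout(grad.n_elem);
  for (arma::uword i = 0; i < grad.n_elem; ++i) gout[i] = grad[i];
  return List::create(_["loss"] = loss, _["ce"] = ce,
                      _["soft_dice"] = mean_dice, _["grad"] = gout);
}
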