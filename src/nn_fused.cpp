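// Fused training step for the curve regressor: forward, loss, backward and
// Adam update in one call, using plain C++ buffers to avoid per-layer R
// allocations. The parameter layout matches the R-side traversal
// (.build_pmap): shared conv1 W,b / bn1 gamma,beta / conv2 W,b / bn2
// gamma,beta, then head_beta conv1..point, then head_bfi likewise.
// Running statistics live in a separate vector: for each of the 6 BN
// layers (same order), rmean then rvar.

#include <Rcpp.h>
#define USE_FC_LEN_T
#include <Rconfig.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
# define FCONE
#endif
#include <cmath>
#include <cstring>
#include <vector>
using namespace Rcpp;

namespace {

inline void gemm2(const char *ta, const char *tb, int m, int n, int k,
                  const double *A, int lda, const double *B, int ldb,
                  double beta, double *C, int ldc) {
  const double one = 1.0;
  F77_CALL(dgemm)(ta, tb, &m, &n, &k, &one, A, &lda, B, &ldb, &beta,
                  C, &ldc FCONE FCONE);
}

struct ConvDims {
  int k, stride, cin, cout, Lin, Lo, pl;
  int wsize() const { return k * cin * cout; }
};

ConvDims make_conv(int k, int stride, int cin, int cout, int Lin) {
  ConvDims d;
  d.k = k; d.stride = stride; d.cin = cin; d.cout = cout; d.Lin = Lin;
  d.Lo = (Lin + stride - 1) / stride;
  int pad = (d.Lo - 1) * stride + k - Lin;
  d.pl = (pad > 0 ? pad : 0) / 2;
  return d;
}

// im2col: X (B,Lin,Cin) -> cols (B*Lo, k*Cin)
void im2col(const double *x, int B, const ConvDims &d, double *cols) {
  const int M = B * d.Lo;
  for (int c = 0; c < d.cin; ++c) {
    const double *xc = x + (size_t)c * B * d.Lin;
    for (int j = 0; j < d.k; ++j) {
      double *dst0 = cols + ((size_t)(j * d.cin + c)) * M;
      for (int lo = 0; lo < d.Lo; ++lo) {
        int li = lo * d.stride + j - d.pl;
        double *dst = dst0 + (size_t)lo * B;
        if (li < 0 || li >= d.Lin) std::memset(dst, 0, B * sizeof(double));
        else std::memcpy(dst, xc + (size_t)li * B, B * sizeof(double));
      }
    }
  }
}

// col2im accumulate: dcols (B*Lo, k*Cin) -> dX (B,Lin,Cin), dX zeroed first
void col2im(const double *dcols, int B, const ConvDims &d, double *dx) {
  const int M = B * d.Lo;
  std::memset(dx, 0, (size_t)B * d.Lin * d.cin * sizeof(double));
  for (int c = 0; c < d.cin; ++c) {
    double *xc = dx + (size_t)c * B * d.Lin;
    for (int j = 0; j < d.k; ++j) {
      const double *src0 = dcols + ((size_t)(j * d.cin + c)) * M;
      for (int lo = 0; lo < d.Lo; ++lo) {
        int li = lo * d.stride + j - d.pl;
        if (li < 0 || li >= d.Lin) continue;
        const double *src = src0 + (size_t)lo * B;
        double *dst = xc + (size_t)li * B;
        for (int b = 0; b < B; ++b) dst[b] += src[b];
      }
    }
  }
}

struct Buffers {
  std::vector<double> cols, y, xhat, dcols, dx;
};

// one conv (linear or sigmoid) forward into out (B*Lo*Cout)
void conv_fw(const double *x, int B, const ConvDims &d, const double *W,
             const double *bias, int act, std::vector<double> &cols,
             double *out) {
  const int M = B * d.Lo, K = d.k * d.cin;
  cols.resize((size_t)M * K);
  im2col(x, B, d, cols.data());
  gemm2("N", "N", M, d.cout, K, cols.data(), M, W, K, 0.0, out, M);
  for (int n = 0; n < d.cout; ++n) {
    double *yn = out + (size_t)n * M;
    double b = bias[n];
    for (int m = 0; m < M; ++m) yn[m] += b;
  }
  if (act == 2)
    for (size_t i = 0; i < (size_t)M * d.cout; ++i)
      out[i] = 1.0 / (1.0 + std::exp(-out[i]));
}

// conv backward: dY in dy (masked by act already), fills dW, db, dX
void conv_bw(const double *dy, const std::vector<double> &cols, int B,
             const ConvDims &d, const double *W, double *dW, double *db,
             double *dx, std::vector<double> &dcols) {
  const int M = B * d.Lo, K = d.k * d.cin;
  for (int n = 0; n < d.cout; ++n) {
    const double *zn = dy + (size_t)n * M;
    double acc = 0.0;
    for (int m = 0; m < M; ++m) acc += zn[m];
    db[n] = acc;
  }
  gemm2("T", "N", K, d.cout, M, cols.data(), M, dy, M, 0.0, dW, K);
  dcols.resize((size_t)M * K);
  gemm2("N", "T", M, K, d.cout, dy, M, W, K, 0.0, dcols.data(), M);
  col2im(dcols.data(), B, d, dx);
}

// BN + fused ReLU forward (training: batch stats; inference: running)
void bn_fw(const double *x, int B, int L, int C, const double *gamma,
           const double *beta, double *rmean, double *rvar, double momentum,
           bool train, double *xhat, double *istd_out, double *out) {
  const int N = B * L;
  for (int c = 0; c < C; ++c) {
    const double *xc = x + (size_t)c * N;
    double m, v;
    if (train) {
      double s = 0.0;
      for (int i = 0; i < N; ++i) s += xc[i];
      m = s / N;
      double sv = 0.0;
      for (int i = 0; i < N; ++i) { double dd = xc[i] - m; sv += dd * dd; }
      v = sv / N;
      rmean[c] = (1.0 - momentum) * rmean[c] + momentum * m;
      rvar[c] = (1.0 - momentum) * rvar[c] + momentum * v;
    } else { m = rmean[c]; v = rvar[c]; }
    double is = 1.0 / std::sqrt(v + 1e-5);
    istd_out[c] = is;
    double g = gamma[c], be = beta[c];
    double *xhc = xhat + (size_t)c * N, *oc = out + (size_t)c * N;
    for (int i = 0; i < N; ++i) {
      double h = (xc[i] - m) * is;
      xhc[i] = h;
      double o = g * h + be;
      oc[i] = o < 0 ? 0.0 : o;   // fused ReLU
    }
  }
}

// BN + ReLU backward; dY masked by the stored post-ReLU output
void bn_bw(const double *dy, const double *yout, const double *xhat,
           const double *istd, const double *gamma, int B, int L, int C,
           double *dg, double *dbe, double *dx) {
  const int N = B * L;
  for (int c = 0; c < C; ++c) {
    const double *dyc = dy + (size_t)c * N, *xhc = xhat + (size_t)c * N,
                 *yc = yout + (size_t)c * N;
    double sg = 0.0, sb = 0.0;
    for (int i = 0; i < N; ++i) {
      double d = yc[i] <= 0 ? 0.0 : dyc[i];
      sg += d * xhc[i]; sb += d;
    }
    dg[c] = sg; dbe[c] = sb;
    double g = gamma[c], is = istd[c];
    double mg = sg / N, mb = sb / N;
    double *dxc = dx + (size_t)c * N;
    for (int i = 0; i < N; ++i) {
      double d = yc[i] <= 0 ? 0.0 : dyc[i];
      dxc[i] = g * is * (d - mb - xhc[i] * mg);
    }
  }
}

struct NetDims {
  ConvDims sc1, sc2, hc1, hc2, hp;
  int f1, f2, h1, h2, Lin;
  // parameter offsets in traversal order
  int off[30]; int n_par;
  void init(int k, int s, int f1_, int f2_, int h1_, int h2_, int Lin_) {
    f1 = f1_; f2 = f2_; h1 = h1_; h2 = h2_; Lin = Lin_;
    sc1 = make_conv(k, s, 1, f1, Lin);
    sc2 = make_conv(k, s, f1, f2, sc1.Lo);
    hc1 = make_conv(k, s, f2, h1, sc2.Lo);
    hc2 = make_conv(k, s, h1, h2, hc1.Lo);
    hp = make_conv(1, 1, h2, 1, hc2.Lo);
    int sizes[] = { sc1.wsize(), f1, f1, f1, sc2.wsize(), f2, f2, f2,
                    hc1.wsize(), h1, h1, h1, hc2.wsize(), h2, h2, h2,
                    hp.wsize(), 1,
                    hc1.wsize(), h1, h1, h1, hc2.wsize(), h2, h2, h2,
                    hp.wsize(), 1 };
    int o = 0;
    for (int i = 0; i < 28; ++i) { off[i] = o; o += sizes[i]; }
    off[28] = o; n_par = o;
  }
};

// scratch for one head pass
struct HeadState {
  std::vector<double> c1y, b1x, b1i, b1y, c2y, b2x, b2i, b2y, py;
  std::vector<double> c1cols, c2cols, pcols;
};

} // namespace

// [[Rcpp::export(name = ".nn_train_batch")]]
double nn_train_batch(NumericMatrix X, NumericMatrix Y, NumericVector theta,
                      NumericVector m_ad, NumericVector v_ad,
                      NumericVector running, IntegerVector ispec,
                      double lr, double momentum, int t_ad) {
  const int B = X.nrow();
  NetDims nd;
  nd.init(ispec[0], ispec[1], ispec[2], ispec[3], ispec[4], ispec[5],
          ispec[6]);
  double *th = theta.begin();
  double *run = running.begin();
  // running layout: 6 BNs x (rmean, rvar): shared bn1, bn2; hb bn1, bn2; hf bn1, bn2
  double *r_sb1 = run, *r_sb2 = r_sb1 + 2 * nd.f1,
         *r_bb1 = r_sb2 + 2 * nd.f2, *r_bb2 = r_bb1 + 2 * nd.h1,
         *r_fb1 = r_bb2 + 2 * nd.h2, *r_fb2 = r_fb1 + 2 * nd.h1;
  // shared forward
  std::vector<double> x0((size_t)B * nd.Lin);
  std::memcpy(x0.data(), X.begin(), x0.size() * sizeof(double));
  std::vector<double> sc1y((size_t)B * nd.sc1.Lo * nd.f1),
      sb1x(sc1y.size()), sb1y(sc1y.size());
  std::vector<double> sb1i(nd.f1), sb2i(nd.f2);
  std::vector<double> sc1cols, sc2cols;
  conv_fw(x0.data(), B, nd.sc1, th + nd.off[0], th + nd.off[1], 0, sc1cols,
          sc1y.data());
  bn_fw(sc1y.data(), B, nd.sc1.Lo, nd.f1, th + nd.off[2], th + nd.off[3],
        r_sb1, r_sb1 + nd.f1, momentum, true, sb1x.data(), sb1i.data(),
        sb1y.data());
  std::vector<double> sc2y((size_t)B * nd.sc2.Lo * nd.f2),
      sb2x(sc2y.size()), sb2y(sc2y.size());
  conv_fw(sb1y.data(), B, nd.sc2, th + nd.off[4], th + nd.off[5], 0, sc2cols,
          sc2y.data());
  bn_fw(sc2y.data(), B, nd.sc2.Lo, nd.f2, th + nd.off[6], th + nd.off[7],
        r_sb2, r_sb2 + nd.f2, momentum, true, sb2x.data(), sb2i.data(),
        sb2y.data());

  // heads forward
  auto head_fw = [&](int base, double *rb1, double *rb2, HeadState &hs,
                     std::vector<double> &b1i, std::vector<double> &b2i) {
    hs.c1y.resize((size_t)B * nd.hc1.Lo * nd.h1);
    hs.b1x.resize(hs.c1y.size()); hs.b1y.resize(hs.c1y.size());
    b1i.resize(nd.h1);
    conv_fw(sb2y.data(), B, nd.hc1, th + nd.off[base], th + nd.off[base + 1],
            0, hs.c1cols, hs.c1y.data());
    bn_fw(hs.c1y.data(), B, nd.hc1.Lo, nd.h1, th + nd.off[base + 2],
          th + nd.off[base + 3], rb1, rb1 + nd.h1, momentum, true,
          hs.b1x.data(), b1i.data(), hs.b1y.data());
    hs.c2y.resize((size_t)B * nd.hc2.Lo * nd.h2);
    hs.b2x.resize(hs.c2y.size()); hs.b2y.resize(hs.c2y.size());
    b2i.resize(nd.h2);
    conv_fw(hs.b1y.data(), B, nd.hc2, th + nd.off[base + 4],
            th + nd.off[base + 5], 0, hs.c2cols, hs.c2y.data());
    bn_fw(hs.c2y.data(), B, nd.hc2.Lo, nd.h2, th + nd.off[base + 6],
          th + nd.off[base + 7], rb2, rb2 + nd.h2, momentum, true,
          hs.b2x.data(), b2i.data(), hs.b2y.data());
    hs.py.resize((size_t)B * nd.hp.Lo);
    conv_fw(hs.b2y.data(), B, nd.hp, th + nd.off[base + 8],
            th + nd.off[base + 9], 2, hs.pcols, hs.py.data());
  };
  HeadState hb, hf;
  std::vector<double> hb1i, hb2i, hf1i, hf2i;
  head_fw(8, r_bb1, r_bb2, hb, hb1i, hb2i);
  head_fw(18, r_fb1, r_fb2, hf, hf1i, hf2i);

  // loss and output gradient
  double loss = 0.0;
  std::vector<double> dob(B), dof(B);
  for (int b = 0; b < B; ++b) {
    double eb = hb.py[b] - Y(b, 0), ef = hf.py[b] - Y(b, 1);
    loss += eb * eb + ef * ef;
    dob[b] = 2.0 * eb / B;
    dof[b] = 2.0 * ef / B;
  }
  loss /= B;

  // backward
  NumericVector grad(theta.size());
  double *gr = grad.begin();
  std::vector<double> dsh((size_t)B * nd.sc2.Lo * nd.f2, 0.0);
  auto head_bw = [&](int base, HeadState &hs, std::vector<double> &b1i,
                     std::vector<double> &b2i, std::vector<double> &dout) {
    // sigmoid grad
    std::vector<double> dp(B);
    for (int b = 0; b < B; ++b)
      dp[b] = dout[b] * hs.py[b] * (1.0 - hs.py[b]);
    std::vector<double> d_b2y((size_t)B * nd.hc2.Lo * nd.h2), dc;
    conv_bw(dp.data(), hs.pcols, B, nd.hp, th + nd.off[base + 8],
            gr + nd.off[base + 8], gr + nd.off[base + 9], d_b2y.data(), dc);
    std::vector<double> d_c2y(hs.c2y.size());
    bn_bw(d_b2y.data(), hs.b2y.data(), hs.b2x.data(), b2i.data(),
          th + nd.off[base + 6], B, nd.hc2.Lo, nd.h2,
          gr + nd.off[base + 6], gr + nd.off[base + 7], d_c2y.data());
    std::vector<double> d_b1y((size_t)B * nd.hc1.Lo * nd.h1);
    conv_bw(d_c2y.data(), hs.c2cols, B, nd.hc2, th + nd.off[base + 4],
            gr + nd.off[base + 4], gr + nd.off[base + 5], d_b1y.data(), dc);
    std::vector<double> d_c1y(hs.c1y.size());
    bn_bw(d_b1y.data(), hs.b1y.data(), hs.b1x.data(), b1i.data(),
          th + nd.off[base + 2], B, nd.hc1.Lo, nd.h1,
          gr + nd.off[base + 2], gr + nd.off[base + 3], d_c1y.data());
    std::vector<double> d_in((size_t)B * nd.sc2.Lo * nd.f2);
    conv_bw(d_c1y.data(), hs.c1cols, B, nd.hc1, th + nd.off[base],
            gr + nd.off[base], gr + nd.off[base + 1], d_in.data(), dc);
    for (size_t i = 0; i < dsh.size(); ++i) dsh[i] += d_in[i];
  };
  head_bw(8, hb, hb1i, hb2i, dob);
  head_bw(18, hf, hf1i, hf2i, dof);

  std::vector<double> d_sc2y(sc2y.size()), dc;
  bn_bw(dsh.data(), sb2y.data(), sb2x.data(), sb2i.data(), th + nd.off[6],
        B, nd.sc2.Lo, nd.f2, gr + nd.off[6], gr + nd.off[7], d_sc2y.data());
  std::vector<double> d_sb1y(sc1y.size());
  conv_bw(d_sc2y.data(), sc2cols, B, nd.sc2, th + nd.off[4], gr + nd.off[4],
          gr + nd.off[5], d_sb1y.data(), dc);
  std::vector<double> d_sc1y(sc1y.size());
  bn_bw(d_sb1y.data(), sb1y.data(), sb1x.data(), sb1i.data(), th + nd.off[2],
        B, nd.sc1.Lo, nd.f1, gr + nd.off[2], gr + nd.off[3], d_sc1y.data());
  std::vector<double> d_x0(x0.size());
  conv_bw(d_sc1y.data(), sc1cols, B, nd.sc1, th + nd.off[0], gr + nd.off[0],
          gr + nd.off[1], d_x0.data(), dc);

  // Adam in place
  double *mm = m_ad.begin(), *vv = v_ad.begin();
  double c1 = 1.0 - std::pow(0.9, t_ad), c2 = 1.0 - std::pow(0.999, t_ad);
  for (int i = 0; i < nd.n_par; ++i) {
    mm[i] = 0.9 * mm[i] + 0.1 * gr[i];
    vv[i] = 0.999 * vv[i] + 0.001 * gr[i] * gr[i];
    th[i] -= lr * (mm[i] / c1) / (std::sqrt(vv[i] / c2) + 1e-8);
  }
  return loss;
}

// [[Rcpp::export(name = ".nn_forward_fused")]]
NumericMatrix nn_forward_fused(NumericMatrix X, NumericVector theta,
                               NumericVector running, IntegerVector ispec) {
  const int B = X.nrow();
  NetDims nd;
  nd.init(ispec[0], ispec[1], ispec[2], ispec[3], ispec[4], ispec[5],
          ispec[6]);
  double *th = theta.begin();
  double *run = running.begin();
  double *r_sb1 = run, *r_sb2 = r_sb1 + 2 * nd.f1,
         *r_bb1 = r_sb2 + 2 * nd.f2, *r_bb2 = r_bb1 + 2 * nd.h1,
         *r_fb1 = r_bb2 + 2 * nd.h2, *r_fb2 = r_fb1 + 2 * nd.h1;
  std::vector<double> x0((size_t)B * nd.Lin);
  std::memcpy(x0.data(), X.begin(), x0.size() * sizeof(double));
  std::vector<double> cols, t1((size_t)B * nd.sc1.Lo * nd.f1),
      t1b(t1.size()), t1x(t1.size()), i1(nd.f1);
  conv_fw(x0.data(), B, nd.sc1, th + nd.off[0], th + nd.off[1], 0, cols,
          t1.data());
  bn_fw(t1.data(), B, nd.sc1.Lo, nd.f1, th + nd.off[2], th + nd.off[3],
        r_sb1, r_sb1 + nd.f1, 0.0, false, t1x.data(), i1.data(), t1b.data());
  std::vector<double> t2((size_t)B * nd.sc2.Lo * nd.f2), t2b(t2.size()),
      t2x(t2.size()), i2(nd.f2);
  conv_fw(t1b.data(), B, nd.sc2, th + nd.off[4], th + nd.off[5], 0, cols,
          t2.data());
  bn_fw(t2.data(), B, nd.sc2.Lo, nd.f2, th + nd.off[6], th + nd.off[7],
        r_sb2, r_sb2 + nd.f2, 0.0, false, t2x.data(), i2.data(), t2b.data());
  NumericMatrix out(B, 2);
  auto head = [&](int base, double *rb1, double *rb2, int colidx) {
    std::vector<double> h1((size_t)B * nd.hc1.Lo * nd.h1), h1b(h1.size()),
        h1x(h1.size()), ih1(nd.h1);
    conv_fw(t2b.data(), B, nd.hc1, th + nd.off[base], th + nd.off[base + 1],
            0, cols, h1.data());
    bn_fw(h1.data(), B, nd.hc1.Lo, nd.h1, th + nd.off[base + 2],
          th + nd.off[base + 3], rb1, rb1 + nd.h1, 0.0, false, h1x.data(),
          ih1.data(), h1b.data());
    std::vector<double> h2((size_t)B * nd.hc2.Lo * nd.h2), h2b(h2.size()),
        h2x(h2.size()), ih2(nd.h2);
    conv_fw(h1b.data(), B, nd.hc2, th + nd.off[base + 4],
            th + nd.off[base + 5], 0, cols, h2.data());
    bn_fw(h2.data(), B, nd.hc2.Lo, nd.h2, th + nd.off[base + 6],
          th + nd.off[base + 7], rb2, rb2 + nd.h2, 0.0, false, h2x.data(),
          ih2.data(), h2b.data());
    std::vector<double> p((size_t)B);
    conv_fw(h2b.data(), B, nd.hp, th + nd.off[base + 8],
            th + nd.off[base + 9], 2, cols, p.data());
    for (int b = 0; b < B; ++b) out(b, colidx) = p[b];
  };
  head(8, r_bb1, r_bb2, 0);
  head(18, r_fb1, r_fb2, 1);
  return out;
}
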