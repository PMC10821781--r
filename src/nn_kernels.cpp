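// Minimal 1D-CNN kernels: strided "same"-padded convolution and batch
// normalization, forward and backward. Activations are fused into the
// convolution (0 = linear, 1 = ReLU, 2 = sigmoid). Arrays are column-major
// with shape (B, L, C): channel c occupies a contiguous B*L block.

#include <Rcpp.h>
#define USE_FC_LEN_T
#include <Rconfig.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
# define FCONE
#endif
#include <cmath>
#include <cstring>
using namespace Rcpp;

static const double ONE = 1.0, ZERO = 0.0;

// C = alpha op(A) op(B) + beta C, column-major
static inline void gemm(const char *ta, const char *tb, int m, int n, int k,
                        double alpha, const double *A, int lda,
                        const double *B, int ldb, double beta,
                        double *Cm, int ldc) {
  F77_CALL(dgemm)(ta, tb, &m, &n, &k, &alpha, A, &lda, B, &ldb, &beta,
                  Cm, &ldc FCONE FCONE);
}

static inline void same_pad(int L, int k, int s, int &Lo, int &pl) {
  Lo = (L + s - 1) / s;
  int pad = (Lo - 1) * s + k - L;
  if (pad < 0) pad = 0;
  pl = pad / 2;
}

// [[Rcpp::export(name = ".nn_conv_fw")]]
List nn_conv_fw(NumericVector X, int B, int L, int C,
                NumericMatrix W, NumericVector bias, int k, int stride,
                int act) {
  int Lo, pl;
  same_pad(L, k, stride, Lo, pl);
  const int Cout = W.ncol();
  const int M = B * Lo, K = k * C;
  NumericMatrix cols(M, K);
  const double *x = X.begin();
  double *cl = cols.begin();
  // cols[(b, lo), j*C + c] = X[b, lo*stride + j - pl, c]
  for (int c = 0; c < C; ++c) {
    const double *xc = x + (size_t)c * B * L;
    for (int j = 0; j < k; ++j) {
      double *dst0 = cl + ((size_t)(j * C + c)) * M;
      for (int lo = 0; lo < Lo; ++lo) {
        int li = lo * stride + j - pl;
        double *dst = dst0 + (size_t)lo * B;
        if (li < 0 || li >= L) {
          std::memset(dst, 0, B * sizeof(double));
        } else {
          std::memcpy(dst, xc + (size_t)li * B, B * sizeof(double));
        }
      }
    }
  }
  NumericVector Y((size_t)M * Cout);
  double *yp = Y.begin();
  gemm("N", "N", M, Cout, K, 1.0, cl, M, W.begin(), K, 0.0, yp, M);
  for (int n = 0; n < Cout; ++n) {
    double *yn = yp + (size_t)n * M;
    double bn = bias[n];
    for (int m = 0; m < M; ++m) yn[m] += bn;
  }
  if (act == 1) {
    for (size_t i = 0; i < (size_t)M * Cout; ++i) if (yp[i] < 0) yp[i] = 0;
  } else if (act == 2) {
    for (size_t i = 0; i < (size_t)M * Cout; ++i) yp[i] = 1.0 / (1.0 + std::exp(-yp[i]));
  }
  Y.attr("dim") = IntegerVector::create(B, Lo, Cout);
  return List::create(_["Y"] = Y, _["cols"] = cols,
                      _["Lo"] = Lo, _["pl"] = pl);
}

// [[Rcpp::export(name = ".nn_conv_bw")]]
List nn_conv_bw(NumericVector dY, NumericVector Y, NumericMatrix cols,
                int B, int L, int C, NumericMatrix W, int k, int stride,
                int act, int Lo, int pl) {
  const int Cout = W.ncol();
  const int M = B * Lo, K = k * C;
  // dZ = dY * act'(Y), in place copy
  NumericVector dZ(clone(dY));
  double *dz = dZ.begin();
  const double *yp = Y.begin();
  if (act == 1) {
    for (size_t i = 0; i < (size_t)M * Cout; ++i) if (yp[i] <= 0) dz[i] = 0;
  } else if (act == 2) {
    for (size_t i = 0; i < (size_t)M * Cout; ++i) dz[i] *= yp[i] * (1.0 - yp[i]);
  }
  NumericMatrix dW(K, Cout);
  NumericVector db(Cout);
  const double *cl = cols.begin();
  for (int n = 0; n < Cout; ++n) {
    const double *zn = dz + (size_t)n * M;
    double acc = 0.0;
    for (int m = 0; m < M; ++m) acc += zn[m];
    db[n] = acc;
  }
  gemm("T", "N", K, Cout, M, 1.0, cl, M, dz, M, 0.0, dW.begin(), K);
  // dcols = dZ W^T, then scatter back to dX
  std::vector<double> dcols((size_t)M * K);
  gemm("N", "T", M, K, Cout, 1.0, dz, M, W.begin(), K, 0.0, dcols.data(), M);
  NumericVector dX((size_t)B * L * C);  // zero-initialized
  double *dx = dX.begin();
  for (int c = 0; c < C; ++c) {
    double *xc = dx + (size_t)c * B * L;
    for (int j = 0; j < k; ++j) {
      const double *src0 = dcols.data() + ((size_t)(j * C + c)) * M;
      for (int lo = 0; lo < Lo; ++lo) {
        int li = lo * stride + j - pl;
        if (li < 0 || li >= L) continue;
        const double *src = src0 + (size_t)lo * B;
        double *dst = xc + (size_t)li * B;
        for (int b = 0; b < B; ++b) dst[b] += src[b];
      }
    }
  }
  dX.attr("dim") = IntegerVector::create(B, L, C);
  return List::create(_["dW"] = dW, _["db"] = db, _["dX"] = dX);
}

// [[Rcpp::export(name = ".nn_bn_fw")]]
List nn_bn_fw(NumericVector X, int B, int L, int C,
              NumericVector gamma, NumericVector beta,
              NumericVector use_mean, NumericVector use_var,
              double eps, bool compute_stats, int act) {
  const int N = B * L;
  NumericVector Y((size_t)N * C), xhat((size_t)N * C);
  NumericVector mu(C), var(C), istd(C);
  const double *x = X.begin();
  double *y = Y.begin(), *xh = xhat.begin();
  for (int c = 0; c < C; ++c) {
    const double *xc = x + (size_t)c * N;
    double m, v;
    if (compute_stats) {
      double s = 0.0;
      for (int i = 0; i < N; ++i) s += xc[i];
      m = s / N;
      double sv = 0.0;
      for (int i = 0; i < N; ++i) { double d = xc[i] - m; sv += d * d; }
      v = sv / N;
    } else {
      m = use_mean[c]; v = use_var[c];
    }
    mu[c] = m; var[c] = v;
    double is = 1.0 / std::sqrt(v + eps);
    istd[c] = is;
    double g = gamma[c], be = beta[c];
    double *yc = y + (size_t)c * N, *xhc = xh + (size_t)c * N;
    for (int i = 0; i < N; ++i) {
      double h = (xc[i] - m) * is;
      xhc[i] = h;
      double o = g * h + be;
      yc[i] = (act == 1 && o < 0) ? 0.0 : o;
    }
  }
  Y.attr("dim") = IntegerVector::create(B, L, C);
  return List::create(_["Y"] = Y, _["xhat"] = xhat, _["mu"] = mu,
                      _["var"] = var, _["istd"] = istd);
}

// [[Rcpp::export(name = ".nn_bn_bw")]]
List nn_bn_bw(NumericVector dY, NumericVector Yout, NumericVector xhat,
              NumericVector istd, NumericVector gamma, int B, int L, int C,
              int act) {
  const int N = B * L;
  NumericVector dX((size_t)N * C), dg(C), dbe(C);
  NumericVector dYm(clone(dY));
  if (act == 1) {
    const double *yo = Yout.begin();
    double *dm = dYm.begin();
    for (size_t i = 0; i < (size_t)N * C; ++i) if (yo[i] <= 0) dm[i] = 0;
  }
  const double *dy = dYm.begin(), *xh = xhat.begin();
  double *dx = dX.begin();
  for (int c = 0; c < C; ++c) {
    const double *dyc = dy + (size_t)c * N, *xhc = xh + (size_t)c * N;
    double sg = 0.0, sb = 0.0;
    for (int i = 0; i < N; ++i) { sg += dyc[i] * xhc[i]; sb += dyc[i]; }
    dg[c] = sg; dbe[c] = sb;
    double g = gamma[c], is = istd[c];
    double mg = sg / N, mb = sb / N;
    double *dxc = dx + (size_t)c * N;
    for (int i = 0; i < N; ++i)
      dxc[i] = g * is * (dyc[i] - mb - xhc[i] * mg);
  }
  dX.attr("dim") = IntegerVector::create(B, L, C);
  return List::create(_["dX"] = dX, _["dg"] = dg, _["dbe"] = dbe);
}

// fused Adam update, in place on the parameter vector
// [[Rcpp::export(name = ".nn_adam")]]
void nn_adam(NumericVector p, NumericVector g, NumericVector m,
             NumericVector v, double lr, double b1, double b2,
             double eps, int t) {
  const size_t n = p.size();
  double c1 = 1.0 - std::pow(b1, t), c2 = 1.0 - std::pow(b2, t);
  double *pp = p.begin(), *mm = m.begin(), *vv = v.begin();
  const double *gg = g.begin();
  for (size_t i = 0; i < n; ++i) {
    mm[i] = b1 * mm[i] + (1.0 - b1) * gg[i];
    vv[i] = b2 * vv[i] + (1.0 - b2) * gg[i] * gg[i];
    pp[i] -= lr * (mm[i] / c1) / (std::sqrt(vv[i] / c2) + eps);
  }
}
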