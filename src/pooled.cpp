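// In-place variants of the training hot loops, writing into caller-owned
// buffers so the optimisation loop reuses memory instead of re-allocating
// tens of megabytes per step. The R side owns a small buffer pool per fit;
// these functions are the only writers of pooled buffers.
#define USE_FC_LEN_T
#include <Rcpp.h>
#include <Rconfig.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
# define FCONE
#endif
using namespace Rcpp;

static void im2col_core(const double* xd, double* md, int H, int W, int N,
                        int C, int pad) {
  const int Hp = H + 2 * pad, Wp = W + 2 * pad;
  const int oh = Hp - 2, ow = Wp - 2;
  const R_xlen_t rows = (R_xlen_t)oh * ow * N;
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < 3; ++kj) {
      for (int ki = 0; ki < 3; ++ki) {
        const int col = ki + 3 * kj + 9 * c;
        double* mp = md + (R_xlen_t)col * rows;
        R_xlen_t r = 0;
        for (int s = 0; s < N; ++s) {
          const double* xs = xd + ((R_xlen_t)c * N + s) * H * W;
          for (int b = 0; b < ow; ++b) {
            const int j = b + kj - pad;
            if (j < 0 || j >= W) {
              for (int a = 0; a < oh; ++a, ++r) mp[r] = 0.0;
              continue;
            }
            const double* xc = xs + (R_xlen_t)j * H;
            for (int a = 0; a < oh; ++a, ++r) {
              const int i = a + ki - pad;
              mp[r] = (i >= 0 && i < H) ? xc[i] : 0.0;
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
void im2col_pad_into(NumericMatrix m, NumericVector x, IntegerVector dims,
                     int pad) {
  const int H = dims[0], W = dims[1], N = dims[2], C = dims[3];
  const int oh = H + 2 * pad - 2, ow = W + 2 * pad - 2;
  if ((R_xlen_t)m.nrow() != (R_xlen_t)oh * ow * N || m.ncol() != 9 * C)
    stop("im2col buffer has the wrong shape");
  im2col_core(x.begin(), m.begin(), H, W, N, C, pad);
}

// dW = m^T (rows x 9C)^T . dm (rows x Cout); db = colSums(dm);
// dcol (rows x 9C) = dm . W2^T, written into the pooled buffer
// [[Rcpp::export]]
List conv_bwd_gemms(NumericMatrix m, NumericVector dm, NumericVector w2,
                    int cout, NumericMatrix dcol, bool need_dx) {
  const int rows = m.nrow(), ninec = m.ncol();
  NumericMatrix dW(ninec, cout);
  NumericVector db(cout);
  const double one = 1.0, zero = 0.0;
  // dW (9C x cout) = m^T (9C x rows) . dm (rows x cout)
  F77_CALL(dgemm)("T", "N", &ninec, &cout, &rows, &one, m.begin(), &rows,
                  REAL(dm), &rows, &zero, dW.begin(), &ninec FCONE FCONE);
  for (int c = 0; c < cout; ++c) {
    const double* d = REAL(dm) + (R_xlen_t)c * rows;
    double s = 0.0;
    for (int i = 0; i < rows; ++i) s += d[i];
    db[c] = s;
  }
  if (need_dx) {
    if (dcol.nrow() != rows || dcol.ncol() != ninec)
      stop("dcol buffer has the wrong shape");
    // dcol (rows x 9C) = dm (rows x cout) . w2^T (cout x 9C)
    F77_CALL(dgemm)("N", "T", &rows, &ninec, &cout, &one, REAL(dm), &rows,
                    REAL(w2), &ninec, &zero, dcol.begin(), &rows FCONE FCONE);
  }
  return List::create(_["W"] = dW, _["b"] = db);
}

// [[Rcpp::export]]
void col2im_unpad_into(NumericVector dx, NumericMatrix dcol,
                       IntegerVector dims, int pad) {
  const int H = dims[0], W = dims[1], N = dims[2], C = dims[3];
  const int Hp = H + 2 * pad, Wp = W + 2 * pad;
  const int oh = Hp - 2, ow = Wp - 2;
  const R_xlen_t rows = (R_xlen_t)oh * ow * N;
  if (dx.size() != (R_xlen_t)H * W * N * C) stop("dx buffer has the wrong size");
  std::fill(dx.begin(), dx.end(), 0.0);
  const double* dd = dcol.begin();
  double* xd = dx.begin();
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < 3; ++kj) {
      for (int ki = 0; ki < 3; ++ki) {
        const int col = ki + 3 * kj + 9 * c;
        const double* dp = dd + (R_xlen_t)col * rows;
        R_xlen_t r = 0;
        for (int s = 0; s < N; ++s) {
          double* xs = xd + ((R_xlen_t)c * N + s) * H * W;
          for (int b = 0; b < ow; ++b) {
            const int j = b + kj - pad;
            if (j < 0 || j >= W) { r += oh; continue; }
            double* xc = xs + (R_xlen_t)j * H;
            for (int a = 0; a < oh; ++a, ++r) {
              const int i = a + ki - pad;
              if (i >= 0 && i < H) xc[i] += dp[r];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
List bn_relu_train_into(NumericVector out, NumericVector xhat, NumericVector x,
                        int n, NumericVector gamma, NumericVector beta,
                        double eps, bool want_xhat) {
  const int C = x.size() / n;
  if (out.size() != x.size() || (want_xhat && xhat.size() != x.size()))
    stop("bn buffer has the wrong size");
  NumericVector mu(C), var(C), rstd(C);
  const double* xd = x.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = xd + (R_xlen_t)c * n;
    double s = 0.0, s2 = 0.0;
    for (int i = 0; i < n; ++i) s += xc[i];
    const double m = s / n;
    for (int i = 0; i < n; ++i) { const double d = xc[i] - m; s2 += d * d; }
    mu[c] = m;
    var[c] = s2 / n;
    rstd[c] = 1.0 / std::sqrt(var[c] + eps);
    const double g = gamma[c], b = beta[c], r = rstd[c];
    double* oc = out.begin() + (R_xlen_t)c * n;
    double* hc = want_xhat ? xhat.begin() + (R_xlen_t)c * n : nullptr;
    for (int i = 0; i < n; ++i) {
      const double h = (xc[i] - m) * r;
      if (hc) hc[i] = h;
      const double y = g * h + b;
      oc[i] = y > 0.0 ? y : 0.0;
    }
  }
  return List::create(_["mu"] = mu, _["var"] = var, _["rstd"] = rstd);
}

// [[Rcpp::export]]
List bn_relu_backward_into(NumericVector dx, NumericVector dy,
                           NumericVector out, NumericVector xhat, int n,
                           NumericVector gamma, NumericVector rstd) {
  const int C = dy.size() / n;
  if (dx.size() != dy.size()) stop("dx buffer has the wrong size");
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double* dyc = dy.begin() + (R_xlen_t)c * n;
    const double* oc = out.begin() + (R_xlen_t)c * n;
    const double* hc = xhat.begin() + (R_xlen_t)c * n;
    double sg = 0.0, sb = 0.0;
    for (int i = 0; i < n; ++i) {
      const double d = oc[i] > 0.0 ? dyc[i] : 0.0;
      sg += d * hc[i];
      sb += d;
    }
    dgamma[c] = sg;
    dbeta[c] = sb;
    const double g = gamma[c], r = rstd[c];
    const double mh = sg / n, mb = sb / n;
    double* dxc = dx.begin() + (R_xlen_t)c * n;
    for (int i = 0; i < n; ++i) {
      const double d = oc[i] > 0.0 ? dyc[i] : 0.0;
      dxc[i] = r * g * (d - mb - hc[i] * mh);
    }
  }
  return List::create(_["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
void maxpool2_into(NumericVector out, IntegerVector wh, NumericVector x,
                   IntegerVector dims) {
  const int H = dims[0], W = dims[1], NC = dims[2] * dims[3];
  const int oh = H / 2, ow = W / 2;
  if (out.size() != (R_xlen_t)oh * ow * NC) stop("pool buffer wrong size");
  const double* xd = x.begin();
  double* od = out.begin();
  int* wd = wh.begin();
  R_xlen_t r = 0;
  for (int p = 0; p < NC; ++p) {
    const double* xs = xd + (R_xlen_t)p * H * W;
    for (int b = 0; b < ow; ++b) {
      const double* c0 = xs + (R_xlen_t)(2 * b) * H;
      const double* c1 = xs + (R_xlen_t)(2 * b + 1) * H;
      for (int a = 0; a < oh; ++a, ++r) {
        const int i = 2 * a;
        double best = c0[i]; int q = 1;
        if (c0[i + 1] > best) { best = c0[i + 1]; q = 2; }
        if (c1[i] > best) { best = c1[i]; q = 3; }
        if (c1[i + 1] > best) { best = c1[i + 1]; q = 4; }
        od[r] = best;
        wd[r] = q;
      }
    }
  }
}

// [[Rcpp::export]]
void maxpool2_backward_into(NumericVector dx, NumericVector dout,
                            IntegerVector wh, IntegerVector dims) {
  const int H = dims[0], W = dims[1], NC = dims[2] * dims[3];
  const int oh = H / 2, ow = W / 2;
  if (dx.size() != (R_xlen_t)H * W * NC) stop("pool dx buffer wrong size");
  std::fill(dx.begin(), dx.end(), 0.0);
  const double* dd = dout.begin();
  const int* wd = wh.begin();
  double* xd = dx.begin();
  R_xlen_t r = 0;
  for (int p = 0; p < NC; ++p) {
    double* xs = xd + (R_xlen_t)p * H * W;
    for (int b = 0; b < ow; ++b) {
      for (int a = 0; a < oh; ++a, ++r) {
        const int q = wd[r];
        const int i = 2 * a + ((q == 2 || q == 4) ? 1 : 0);
        const int j = 2 * b + ((q >= 3) ? 1 : 0);
        xs[(R_xlen_t)j * H + i] += dd[r];
      }
    }
  }
}
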