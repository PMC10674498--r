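// Minimal conv-net primitives (im2col convolution + max pooling) backing the
// residual Zernike regressor. Layout: activations are R arrays [H, W, C, N]
// (column-major, H fastest); weights are matrices (F, C*k*k) with patch rows
// ordered c-major then kw then kh (kh fastest).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int H, int k, int stride, int pad) {
  return (H + 2 * pad - k) / stride + 1;
}

static NumericVector alloc4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static IntegerVector alloc4i(int a, int b, int c, int d) {
  IntegerVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static void im2col(const double* x, int H, int W, int C, int k, int stride,
                   int pad, int Ho, int Wo, arma::mat& col) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int wo = 0; wo < Wo; ++wo) {
      int w0 = wo * stride - pad;
      for (int ho = 0; ho < Ho; ++ho) {
        int h0 = ho * stride - pad;
        double* dst = col.colptr(ho + (size_t)Ho * wo) + (size_t)c * k * k;
        for (int kw = 0; kw < k; ++kw) {
          int w = w0 + kw;
          if (w < 0 || w >= W) {
            for (int kh = 0; kh < k; ++kh) dst[kw * k + kh] = 0.0;
            continue;
          }
          const double* xcw = xc + (size_t)H * w;
          for (int kh = 0; kh < k; ++kh) {
            int h = h0 + kh;
            dst[kw * k + kh] = (h >= 0 && h < H) ? xcw[h] : 0.0;
          }
        }
      }
    }
  }
}

static void col2im(const arma::mat& col, int H, int W, int C, int k,
                   int stride, int pad, int Ho, int Wo, double* dx) {
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)c * H * W;
    for (int wo = 0; wo < Wo; ++wo) {
      int w0 = wo * stride - pad;
      for (int ho = 0; ho < Ho; ++ho) {
        int h0 = ho * stride - pad;
        const double* src = col.colptr(ho + (size_t)Ho * wo) + (size_t)c * k * k;
        for (int kw = 0; kw < k; ++kw) {
          int w = w0 + kw;
          if (w < 0 || w >= W) continue;
          double* xcw = xc + (size_t)H * w;
          for (int kh = 0; kh < k; ++kh) {
            int h = h0 + kh;
            if (h >= 0 && h < H) xcw[h] += src[kw * k + kh];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
List conv_fwd(NumericVector x, NumericMatrix Wm, NumericVector b,
              int k, int stride, int pad, bool want_cols) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int F = Wm.nrow(), Ckk = Wm.ncol();
  if (Ckk != C * k * k) stop("weight shape mismatch");
  int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  arma::mat Wmat(Wm.begin(), F, Ckk, false);
  arma::vec bv(b.begin(), F, false);

  NumericVector out = alloc4(Ho, Wo, F, N);
  NumericVector cols;
  if (want_cols) cols = NumericVector(Dimension(Ckk, Ho * Wo, N));

  arma::mat col(Ckk, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, k, stride, pad,
           Ho, Wo, col);
    arma::mat o = col.t() * Wmat.t();           // (HoWo) x F
    o.each_row() += bv.t();
    std::copy(o.begin(), o.end(), out.begin() + (size_t)n * Ho * Wo * F);
    if (want_cols)
      std::copy(col.begin(), col.end(),
                cols.begin() + (size_t)n * Ckk * Ho * Wo);
  }
  if (want_cols) return List::create(_["out"] = out, _["cols"] = cols);
  return List::create(_["out"] = out);
}

// [[Rcpp::export]]
List conv_bwd(NumericVector dout, NumericVector cols, NumericMatrix Wm,
              IntegerVector xdim, int k, int stride, int pad) {
  IntegerVector d = dout.attr("dim");
  int Ho = d[0], Wo = d[1], F = d[2], N = d[3];
  int H = xdim[0], W = xdim[1], C = xdim[2];
  int Ckk = C * k * k;
  arma::mat Wmat(Wm.begin(), F, Ckk, false);

  NumericVector dx = alloc4(H, W, C, N);
  arma::mat dW(F, Ckk, arma::fill::zeros);
  arma::vec db(F, arma::fill::zeros);

  for (int n = 0; n < N; ++n) {
    arma::mat D(const_cast<double*>(dout.begin()) + (size_t)n * Ho * Wo * F,
                (size_t)Ho * Wo, F, false);
    arma::mat col(const_cast<double*>(cols.begin()) + (size_t)n * Ckk * Ho * Wo,
                  Ckk, (size_t)Ho * Wo, false);
    dW += D.t() * col.t();
    db += arma::sum(D, 0).t();
    arma::mat dcol = Wmat.t() * D.t();          // Ckk x HoWo
    col2im(dcol, H, W, C, k, stride, pad, Ho, Wo,
           dx.begin() + (size_t)n * H * W * C);
  }
  return List::create(_["dx"] = dx, _["dW"] = wrap(dW), _["db"] = wrap(db));
}

// [[Rcpp::export]]
List maxpool_fwd(NumericVector x, int k, int stride) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int Ho = out_size(H, k, stride, 0), Wo = out_size(W, k, stride, 0);
  NumericVector out = alloc4(Ho, Wo, C, N);
  IntegerVector arg = alloc4i(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + ((size_t)n * C + c) * H * W;
      double* oc = out.begin() + ((size_t)n * C + c) * Ho * Wo;
      int* ac = arg.begin() + ((size_t)n * C + c) * Ho * Wo;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -1e300; int bi = 0;
          for (int kw = 0; kw < k; ++kw)
            for (int kh = 0; kh < k; ++kh) {
              int h = ho * stride + kh, w = wo * stride + kw;
              if (h < H && w < W) {
                double v = xc[h + (size_t)H * w];
                if (v > best) { best = v; bi = h + H * w; }
              }
            }
          oc[ho + (size_t)Ho * wo] = best;
          ac[ho + (size_t)Ho * wo] = bi;
        }
    }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd(NumericVector dout, IntegerVector argmax,
                          IntegerVector xdim) {
  IntegerVector d = dout.attr("dim");
  int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  int H = xdim[0], W = xdim[1];
  NumericVector dx = alloc4(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* doc = dout.begin() + ((size_t)n * C + c) * Ho * Wo;
      const int* ac = argmax.begin() + ((size_t)n * C + c) * Ho * Wo;
      double* dxc = dx.begin() + ((size_t)n * C + c) * H * W;
      for (size_t i = 0; i < (size_t)Ho * Wo; ++i) dxc[ac[i]] += doc[i];
    }
  return dx;
}

// Batch normalization over [H, W, C, N] activations: statistics per channel
// across H, W and N. Forward returns the normalized activations (xhat) and
// per-channel sd for the backward pass.

// [[Rcpp::export]]
List bn_fwd_cpp(NumericVector x, NumericVector gamma, NumericVector beta,
                NumericVector run_mean, NumericVector run_var,
                bool training, double eps) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  size_t HW = (size_t)H * W, CS = HW, NS = (size_t)C * HW;
  arma::vec mu(C), var(C);
  if (training) {
    mu.zeros(); var.zeros();
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < C; ++c) {
        const double* p = x.begin() + n * NS + c * CS;
        double s = 0, s2 = 0;
        for (size_t i = 0; i < HW; ++i) { s += p[i]; s2 += p[i] * p[i]; }
        mu[c] += s; var[c] += s2;
      }
    double m = (double)HW * N;
    mu /= m; var = var / m - mu % mu;
  } else {
    mu = arma::vec(run_mean.begin(), C);
    var = arma::vec(run_var.begin(), C);
  }
  arma::vec sd = arma::sqrt(var + eps);
  NumericVector xhat = alloc4(H, W, C, N), out = alloc4(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + n * NS + c * CS;
      double* ph = xhat.begin() + n * NS + c * CS;
      double* po = out.begin() + n * NS + c * CS;
      double mc = mu[c], isd = 1.0 / sd[c], g = gamma[c], b = beta[c];
      for (size_t i = 0; i < HW; ++i) {
        ph[i] = (p[i] - mc) * isd;
        po[i] = g * ph[i] + b;
      }
    }
  return List::create(_["out"] = out, _["xhat"] = xhat,
                      _["sd"] = wrap(sd), _["mu"] = wrap(mu),
                      _["var"] = wrap(var));
}

// [[Rcpp::export]]
List bn_bwd_cpp(NumericVector dout, NumericVector xhat, NumericVector sd,
                NumericVector gamma) {
  IntegerVector d = dout.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  size_t HW = (size_t)H * W, CS = HW, NS = (size_t)C * HW;
  arma::vec dgamma(C, arma::fill::zeros), dbeta(C, arma::fill::zeros);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* pd = dout.begin() + n * NS + c * CS;
      const double* ph = xhat.begin() + n * NS + c * CS;
      double sg = 0, sb = 0;
      for (size_t i = 0; i < HW; ++i) { sg += pd[i] * ph[i]; sb += pd[i]; }
      dgamma[c] += sg; dbeta[c] += sb;
    }
  double m = (double)HW * N;
  NumericVector dx = alloc4(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* pd = dout.begin() + n * NS + c * CS;
      const double* ph = xhat.begin() + n * NS + c * CS;
      double* px = dx.begin() + n * NS + c * CS;
      double gs = gamma[c] / sd[c];
      double a = dbeta[c] / m, b = dgamma[c] / m;
      for (size_t i = 0; i < HW; ++i)
        px[i] = gs * (pd[i] - a - ph[i] * b);
    }
  return List::create(_["dx"] = dx, _["dgamma"] = wrap(dgamma),
                      _["dbeta"] = wrap(dbeta));
}
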