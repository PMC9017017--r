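// Convolution primitives: 3x3 same-padding convolution (full and depthwise).
// Feature maps arrive as R arrays with dim = c(N, H, W, C), column-major
// with the batch index fastest.  A spatial shift by (di, dj) is then a
// constant flat-index shift of N*di + N*H*dj, and for each output column w
// the valid rows form one contiguous span — so every kernel tap is a GEMM
// on subview rows, with no buffer copies at all.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::mat tap_full(const NumericVector& w, int i, int j,
                                 int Cin, int Cout) {
  arma::mat Wk(Cin, Cout);
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      Wk(ci, co) = w[i + 3 * j + 9 * (ci + (size_t)Cin * co)];
  return Wk;
}

// [[Rcpp::export]]
NumericVector cpp_conv3_fwd(NumericVector x, NumericVector w,
                            Nullable<NumericVector> bias,
                            int N, int H, int W, int Cin, int Cout) {
  const size_t M = (size_t)N * H * W;
  const arma::mat X(const_cast<double*>(x.begin()), M, Cin, false, true);
  NumericVector out(M * Cout);
  arma::mat Y(out.begin(), M, Cout, false, true);
  for (int dj = -1; dj <= 1; ++dj) for (int di = -1; di <= 1; ++di) {
    const arma::mat Wk = tap_full(w, di + 1, dj + 1, Cin, Cout);
    const int h0 = std::max(0, -di), h1 = H - std::max(0, di);
    const int w0 = std::max(0, -dj), w1 = W - std::max(0, dj);
    if (h1 <= h0) continue;
    const size_t len = (size_t)N * (h1 - h0);
    for (int wo = w0; wo < w1; ++wo) {
      const size_t qd = (size_t)N * H * wo + (size_t)N * h0;
      const size_t qs = (size_t)N * H * (wo + dj) + (size_t)N * (h0 + di);
      Y.rows(qd, qd + len - 1) += X.rows(qs, qs + len - 1) * Wk;
    }
  }
  if (bias.isNotNull()) {
    NumericVector b(bias);
    for (int co = 0; co < Cout; ++co) Y.col(co) += b[co];
  }
  out.attr("dim") = IntegerVector::create(N, H, W, Cout);
  return out;
}

// [[Rcpp::export]]
List cpp_conv3_bwd(NumericVector x, NumericVector w, NumericVector dy,
                   int N, int H, int W, int Cin, int Cout, bool has_bias) {
  const size_t M = (size_t)N * H * W;
  const arma::mat X(const_cast<double*>(x.begin()), M, Cin, false, true);
  const arma::mat dY(const_cast<double*>(dy.begin()), M, Cout, false, true);
  NumericVector dxv(M * Cin);
  arma::mat dX(dxv.begin(), M, Cin, false, true);
  NumericVector dwv(9 * (size_t)Cin * Cout);
  for (int dj = -1; dj <= 1; ++dj) for (int di = -1; di <= 1; ++di) {
    const arma::mat Wk = tap_full(w, di + 1, dj + 1, Cin, Cout);
    const arma::mat WkT = Wk.t();
    arma::mat dWk(Cin, Cout, arma::fill::zeros);
    const int h0 = std::max(0, -di), h1 = H - std::max(0, di);
    const int w0 = std::max(0, -dj), w1 = W - std::max(0, dj);
    if (h1 <= h0) continue;
    const size_t len = (size_t)N * (h1 - h0);
    for (int wo = w0; wo < w1; ++wo) {
      const size_t qd = (size_t)N * H * wo + (size_t)N * h0;
      const size_t qs = (size_t)N * H * (wo + dj) + (size_t)N * (h0 + di);
      dWk += X.rows(qs, qs + len - 1).t() * dY.rows(qd, qd + len - 1);
      dX.rows(qs, qs + len - 1) += dY.rows(qd, qd + len - 1) * WkT;
    }
    for (int co = 0; co < Cout; ++co)
      for (int ci = 0; ci < Cin; ++ci)
        dwv[(di + 1) + 3 * (dj + 1) + 9 * (ci + (size_t)Cin * co)] = dWk(ci, co);
  }
  dwv.attr("dim") = IntegerVector::create(3, 3, Cin, Cout);
  dxv.attr("dim") = IntegerVector::create(N, H, W, Cin);
  List out = List::create(Named("dx") = dxv, Named("dw") = dwv);
  if (has_bias) {
    arma::rowvec db = arma::sum(dY, 0);
    out["db"] = NumericVector(db.begin(), db.end());
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_dw3_fwd(NumericVector x, NumericVector w,
                          Nullable<NumericVector> bias,
                          int N, int H, int W, int C) {
  const size_t M = (size_t)N * H * W;
  NumericVector out(M * C);
  double* yp = out.begin();
  const double* xp = x.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + M * (size_t)c;
    double* yc = yp + M * (size_t)c;
    const double b0 = bias.isNotNull() ? NumericVector(bias)[c] : 0.0;
    if (b0 != 0.0) for (size_t q = 0; q < M; ++q) yc[q] = b0;
    for (int dj = -1; dj <= 1; ++dj) for (int di = -1; di <= 1; ++di) {
      const double wk = w[(di + 1) + 3 * (dj + 1) + 9 * c];
      const int h0 = std::max(0, -di), h1 = H - std::max(0, di);
      const int w0 = std::max(0, -dj), w1 = W - std::max(0, dj);
      if (h1 <= h0) continue;
      const size_t len = (size_t)N * (h1 - h0);
      for (int wo = w0; wo < w1; ++wo) {
        double* d = yc + (size_t)N * H * wo + (size_t)N * h0;
        const double* s = xc + (size_t)N * H * (wo + dj) + (size_t)N * (h0 + di);
        for (size_t q = 0; q < len; ++q) d[q] += wk * s[q];
      }
    }
  }
  out.attr("dim") = IntegerVector::create(N, H, W, C);
  return out;
}

// [[Rcpp::export]]
List cpp_dw3_bwd(NumericVector x, NumericVector w, NumericVector dy,
                 int N, int H, int W, int C, bool has_bias) {
  const size_t M = (size_t)N * H * W;
  NumericVector dxv(M * C);
  NumericVector dwv(9 * (size_t)C);
  NumericVector dbv(C);
  const double* xp = x.begin();
  const double* dyp = dy.begin();
  double* dxp = dxv.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + M * (size_t)c;
    const double* gc = dyp + M * (size_t)c;
    double* dxc = dxp + M * (size_t)c;
    for (int dj = -1; dj <= 1; ++dj) for (int di = -1; di <= 1; ++di) {
      const double wk = w[(di + 1) + 3 * (dj + 1) + 9 * c];
      double acc = 0.0;
      const int h0 = std::max(0, -di), h1 = H - std::max(0, di);
      const int w0 = std::max(0, -dj), w1 = W - std::max(0, dj);
      if (h1 <= h0) continue;
      const size_t len = (size_t)N * (h1 - h0);
      for (int wo = w0; wo < w1; ++wo) {
        const size_t qd = (size_t)N * H * wo + (size_t)N * h0;
        const size_t qs = (size_t)N * H * (wo + dj) + (size_t)N * (h0 + di);
        const double* g = gc + qd;
        const double* s = xc + qs;
        double* dxs = dxc + qs;
        for (size_t q = 0; q < len; ++q) {
          acc += s[q] * g[q];
          dxs[q] += wk * g[q];
        }
      }
      dwv[(di + 1) + 3 * (dj + 1) + 9 * c] = acc;
    }
    if (has_bias) {
      double s = 0.0;
      for (size_t q = 0; q < M; ++q) s += gc[q];
      dbv[c] = s;
    }
  }
  dwv.attr("dim") = IntegerVector::create(3, 3, C);
  dxv.attr("dim") = IntegerVector::create(N, H, W, C);
  List out = List::create(Named("dx") = dxv, Named("dw") = dwv);
  if (has_bias) out["db"] = dbv;
  return out;
}

// per-channel affine map y = scale[c] * x + shift[c] (batch-norm core)
// [[Rcpp::export]]
NumericVector cpp_channel_affine(NumericVector x, NumericVector scale,
                                 NumericVector shift, int M, int C) {
  NumericVector y(x.size());
  for (int c = 0; c < C; ++c) {
    const double s = scale[c], t = shift[c];
    const double* xc = x.begin() + (size_t)M * c;
    double* yc = y.begin() + (size_t)M * c;
    for (int q = 0; q < M; ++q) yc[q] = s * xc[q] + t;
  }
  y.attr("dim") = x.attr("dim");
  return y;
}

// fused ReLU forward / backward
// [[Rcpp::export]]
NumericVector cpp_relu_fwd(NumericVector x) {
  NumericVector y(x.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  const size_t n = x.size();
  for (size_t q = 0; q < n; ++q) yp[q] = xp[q] > 0 ? xp[q] : 0;
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_relu_bwd(NumericVector y, NumericVector dy) {
  NumericVector dx(dy.size());
  const double* yp = y.begin();
  const double* gp = dy.begin();
  double* dp = dx.begin();
  const size_t n = dy.size();
  for (size_t q = 0; q < n; ++q) dp[q] = yp[q] > 0 ? gp[q] : 0;
  dx.attr("dim") = dy.attr("dim");
  return dx;
}
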