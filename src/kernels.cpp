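// Fused batch-normalization and ReLU kernels.
//
// Inputs are (channels x N) matrices where N = length * batch; fusing the
// per-channel statistics, normalization and affine transform into single
// column-major passes avoids the many full-array temporaries an R-level
// implementation would allocate inside the training loop.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List bn_forward_cpp(const NumericMatrix& x, const NumericVector& gamma,
                    const NumericVector& beta, double eps) {
  const int C = x.nrow(), N = x.ncol();
  NumericVector mu(C), var(C), invstd(C);
  NumericMatrix y(C, N), xhat(C, N);
  const double* xp = x.begin();
  double* mup = mu.begin();
  double* varp = var.begin();
  for (int j = 0; j < N; ++j) {
    const double* col = xp + (size_t)j * C;
    for (int c = 0; c < C; ++c) mup[c] += col[c];
  }
  for (int c = 0; c < C; ++c) mup[c] /= N;
  for (int j = 0; j < N; ++j) {
    const double* col = xp + (size_t)j * C;
    for (int c = 0; c < C; ++c) {
      const double d = col[c] - mup[c];
      varp[c] += d * d;
    }
  }
  for (int c = 0; c < C; ++c) {
    varp[c] /= N;
    invstd[c] = 1.0 / std::sqrt(varp[c] + eps);
  }
  double* yp = y.begin();
  double* xhp = xhat.begin();
  const double* isp = invstd.begin();
  const double* gp = gamma.begin();
  const double* bp = beta.begin();
  for (int j = 0; j < N; ++j) {
    const size_t off = (size_t)j * C;
    const double* col = xp + off;
    for (int c = 0; c < C; ++c) {
      const double xh = (col[c] - mup[c]) * isp[c];
      xhp[off + c] = xh;
      yp[off + c] = gp[c] * xh + bp[c];
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["mu"] = mu,
                      _["var"] = var, _["invstd"] = invstd);
}

// [[Rcpp::export]]
List bn_backward_cpp(const NumericMatrix& dy, const NumericMatrix& xhat,
                     const NumericVector& invstd, const NumericVector& gamma) {
  const int C = dy.nrow(), N = dy.ncol();
  NumericVector dgamma(C), dbeta(C);
  NumericMatrix dx(C, N);
  const double* dyp = dy.begin();
  const double* xhp = xhat.begin();
  double* dgp = dgamma.begin();
  double* dbp = dbeta.begin();
  for (int j = 0; j < N; ++j) {
    const size_t off = (size_t)j * C;
    for (int c = 0; c < C; ++c) {
      dgp[c] += dyp[off + c] * xhp[off + c];
      dbp[c] += dyp[off + c];
    }
  }
  std::vector<double> mg(C), mb(C), gis(C);
  for (int c = 0; c < C; ++c) {
    mg[c] = dgp[c] * gamma[c] / N;
    mb[c] = dbp[c] * gamma[c] / N;
    gis[c] = gamma[c] * invstd[c];
  }
  double* dxp = dx.begin();
  const double* isp = invstd.begin();
  for (int j = 0; j < N; ++j) {
    const size_t off = (size_t)j * C;
    for (int c = 0; c < C; ++c)
      dxp[off + c] = gis[c] * dyp[off + c] -
                     isp[c] * (mb[c] + xhp[off + c] * mg[c]);
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
NumericVector relu_forward_cpp(const NumericVector& x) {
  const R_xlen_t n = x.size();
  NumericVector y(n);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (R_xlen_t i = 0; i < n; ++i) yp[i] = xp[i] > 0 ? xp[i] : 0.0;
  return y;
}

// [[Rcpp::export]]
NumericVector relu_backward_cpp(const NumericVector& dy,
                                const NumericVector& y) {
  const R_xlen_t n = dy.size();
  NumericVector dx(n);
  const double* dp = dy.begin();
  const double* yp = y.begin();
  double* op = dx.begin();
  for (R_xlen_t i = 0; i < n; ++i) op[i] = yp[i] > 0 ? dp[i] : 0.0;
  return dx;
}
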