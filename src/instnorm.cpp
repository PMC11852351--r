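// Instance normalization: per-channel standardization over the spatial
// grid with learned scale/shift. Single-pass C++ loops; these layers sit
// between every convolution so the R-level overhead matters.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_instnorm_fw(NumericVector x, NumericVector gamma,
                     NumericVector beta, double eps) {
  IntegerVector dm = x.attr("dim");
  const size_t nsp = (size_t)dm[0] * dm[1] * dm[2];
  const int nc = dm[3];
  NumericVector y(x.size()), mu(nc), istd(nc);
  y.attr("dim") = dm;
  for (int c = 0; c < nc; ++c) {
    const double *xc = x.begin() + nsp * c;
    double s = 0, s2 = 0;
    for (size_t i = 0; i < nsp; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
    const double m = s / nsp;
    const double v = s2 / nsp - m * m;
    const double is = 1.0 / std::sqrt((v > 0 ? v : 0) + eps);
    mu[c] = m; istd[c] = is;
    const double a = gamma[c] * is;
    const double b = beta[c] - a * m;
    double *yc = y.begin() + nsp * c;
    for (size_t i = 0; i < nsp; ++i) yc[i] = a * xc[i] + b;
  }
  return List::create(_["y"] = y, _["mu"] = mu, _["istd"] = istd);
}

// [[Rcpp::export]]
List cpp_instnorm_bw(NumericVector x, NumericVector mu, NumericVector istd,
                     NumericVector gamma, NumericVector gy) {
  IntegerVector dm = x.attr("dim");
  const size_t nsp = (size_t)dm[0] * dm[1] * dm[2];
  const int nc = dm[3];
  NumericVector gx(x.size()), ggamma(nc), gbeta(nc);
  gx.attr("dim") = dm;
  for (int c = 0; c < nc; ++c) {
    const double *xc = x.begin() + nsp * c;
    const double *gc = gy.begin() + nsp * c;
    const double m = mu[c], is = istd[c];
    double sg = 0, sgx = 0;
    for (size_t i = 0; i < nsp; ++i) {
      sg += gc[i];
      sgx += gc[i] * (xc[i] - m) * is;
    }
    ggamma[c] = sgx; gbeta[c] = sg;
    const double m1 = sg / nsp, m2 = sgx / nsp;
    const double ga = gamma[c] * is;
    double *go = gx.begin() + nsp * c;
    for (size_t i = 0; i < nsp; ++i)
      go[i] = ga * (gc[i] - m1 - (xc[i] - m) * is * m2);
  }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}
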