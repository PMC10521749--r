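// Elementwise layer kernels: per-(channel, sample) affine maps and moments
// for batch normalization, leaky rectifier forward/backward. Activations
// are viewed as (nvox, C*N) column-major; coefficient vectors have length
// C*N (channel fastest).
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".chan_affine")]]
NumericVector chan_affine(NumericVector x, double nvox_, NumericVector mult,
                          NumericVector off) {
  const size_t nvox = (size_t)nvox_, ncol = mult.size();
  NumericVector out(x.size());
  for (size_t c = 0; c < ncol; ++c) {
    const double m = mult[c], o = off[c];
    const double *xp = x.begin() + c * nvox;
    double *op = out.begin() + c * nvox;
    for (size_t i = 0; i < nvox; ++i) op[i] = m * xp[i] + o;
  }
  out.attr("dim") = x.attr("dim");
  return out;
}

// [[Rcpp::export(name = ".chan_moments")]]
List chan_moments(NumericVector x, double nvox_) {
  const size_t nvox = (size_t)nvox_, ncol = x.size() / nvox;
  NumericVector m(ncol), m2(ncol);
  for (size_t c = 0; c < ncol; ++c) {
    const double *xp = x.begin() + c * nvox;
    double s = 0, s2 = 0;
    for (size_t i = 0; i < nvox; ++i) { s += xp[i]; s2 += xp[i] * xp[i]; }
    m[c] = s / nvox; m2[c] = s2 / nvox;
  }
  return List::create(_["mean"] = m, _["meansq"] = m2);
}

// [[Rcpp::export(name = ".chan_sums")]]
List chan_sums(NumericVector gy, NumericVector xhat, double nvox_) {
  const size_t nvox = (size_t)nvox_, ncol = gy.size() / nvox;
  NumericVector s(ncol), sx(ncol);
  for (size_t c = 0; c < ncol; ++c) {
    const double *gp = gy.begin() + c * nvox;
    const double *xp = xhat.begin() + c * nvox;
    double a = 0, b = 0;
    for (size_t i = 0; i < nvox; ++i) { a += gp[i]; b += gp[i] * xp[i]; }
    s[c] = a; sx[c] = b;
  }
  return List::create(_["sum"] = s, _["sumx"] = sx);
}

// out = a * gy + b * xhat + c, coefficients per column
// [[Rcpp::export(name = ".bn_bwd_fuse")]]
NumericVector bn_bwd_fuse(NumericVector gy, NumericVector xhat, double nvox_,
                          NumericVector a, NumericVector b, NumericVector c) {
  const size_t nvox = (size_t)nvox_, ncol = a.size();
  NumericVector out(gy.size());
  for (size_t col = 0; col < ncol; ++col) {
    const double ac = a[col], bc = b[col], cc = c[col];
    const double *gp = gy.begin() + col * nvox;
    const double *xp = xhat.begin() + col * nvox;
    double *op = out.begin() + col * nvox;
    for (size_t i = 0; i < nvox; ++i) op[i] = ac * gp[i] + bc * xp[i] + cc;
  }
  out.attr("dim") = gy.attr("dim");
  return out;
}

// [[Rcpp::export(name = ".lrelu_fwd")]]
NumericVector lrelu_fwd(NumericVector x, double slope) {
  NumericVector out(x.size());
  const double *xp = x.begin(); double *op = out.begin();
  const size_t n = x.size();
  for (size_t i = 0; i < n; ++i) op[i] = xp[i] > 0 ? xp[i] : slope * xp[i];
  out.attr("dim") = x.attr("dim");
  return out;
}

// gradient through the rectifier, using the cached output sign
// [[Rcpp::export(name = ".lrelu_bwd")]]
NumericVector lrelu_bwd(NumericVector gy, NumericVector y, double slope) {
  NumericVector out(gy.size());
  const double *gp = gy.begin(), *yp = y.begin();
  double *op = out.begin();
  const size_t n = gy.size();
  for (size_t i = 0; i < n; ++i) op[i] = yp[i] > 0 ? gp[i] : slope * gp[i];
  out.attr("dim") = gy.attr("dim");
  return out;
}
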