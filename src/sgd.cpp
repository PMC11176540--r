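#include <Rcpp.h>
using namespace Rcpp;

// One fused SGD update: w - lr * (g + wd * w) in a single pass.  Gradient
// finiteness is screened with a cheap checksum (the sum of a vector with any
// NaN/Inf is itself non-finite); only on suspicion is the per-element check
// run, so a spurious overflow of the checksum cannot raise a false error.

// [[Rcpp::export]]
NumericVector sgd_update(NumericVector p, NumericVector g, double lr, double wd) {
  if (p.size() != g.size()) stop("parameter/gradient length mismatch");
  NumericVector out(p.size());
  const double *__restrict__ pp = p.begin(), *__restrict__ pg = g.begin();
  double *__restrict__ po = out.begin();
  const double a = 1.0 - lr * wd;
  double chk = 0;
  for (R_xlen_t i = 0; i < p.size(); ++i) {
    chk += pg[i];
    po[i] = a * pp[i] - lr * pg[i];
  }
  if (!std::isfinite(chk)) {
    for (R_xlen_t i = 0; i < p.size(); ++i)
      if (!std::isfinite(pg[i])) stop("non-finite gradient");
  }
  if (!Rf_isNull(p.attr("dim"))) out.attr("dim") = p.attr("dim");
  return out;
}
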