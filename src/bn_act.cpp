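#include <Rcpp.h>
using namespace Rcpp;

// Channel-wise batch-normalization primitives for conv features (N,C,H,W):
// statistics pool over batch and both spatial dimensions.  The backward
// recomputes the normalized values from the cached mean/var instead of
// storing them, halving the memory traffic of the train step.

// [[Rcpp::export]]
List bn_conv_stats(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int N = d[0], C = d[1], H = d[2], W = d[3];
  const double m = (double)N * H * W;
  NumericVector mean(C), var(C);
  const double *px = x.begin();
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int c = 0; c < C; ++c) {
        const double *src = px + (R_xlen_t)N * (c + (R_xlen_t)C * (h + (R_xlen_t)H * w));
        double s = 0, s2 = 0;
        for (int n = 0; n < N; ++n) { s += src[n]; s2 += src[n] * src[n]; }
        mean[c] += s; var[c] += s2;
      }
  for (int c = 0; c < C; ++c) {
    mean[c] /= m;
    var[c] = var[c] / m - mean[c] * mean[c];
    if (var[c] < 0) var[c] = 0;            // guard against roundoff
  }
  return List::create(_["mean"] = mean, _["var"] = var);
}

// [[Rcpp::export]]
NumericVector bn_conv_apply(NumericVector x, NumericVector gamma,
                            NumericVector beta, NumericVector mean,
                            NumericVector var, double eps) {
  IntegerVector d = x.attr("dim");
  const int N = d[0], C = d[1], H = d[2], W = d[3];
  NumericVector out((R_xlen_t)N * C * H * W);
  out.attr("dim") = d;
  std::vector<double> a(C), b(C);
  for (int c = 0; c < C; ++c) {
    a[c] = gamma[c] / std::sqrt(var[c] + eps);
    b[c] = beta[c] - a[c] * mean[c];
  }
  const double *px = x.begin();
  double *po = out.begin();
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int c = 0; c < C; ++c) {
        const R_xlen_t off = (R_xlen_t)N * (c + (R_xlen_t)C * (h + (R_xlen_t)H * w));
        const double ac = a[c], bc = b[c];
        for (int n = 0; n < N; ++n) po[off + n] = ac * px[off + n] + bc;
      }
  return out;
}

// [[Rcpp::export]]
List bn_conv_bwd(NumericVector x, NumericVector gamma, NumericVector mean,
                 NumericVector var, double eps, NumericVector g) {
  IntegerVector d = x.attr("dim");
  const int N = d[0], C = d[1], H = d[2], W = d[3];
  const double m = (double)N * H * W;
  NumericVector ggamma(C), gbeta(C);
  NumericVector gx((R_xlen_t)N * C * H * W);
  gx.attr("dim") = d;
  std::vector<double> istd(C);
  for (int c = 0; c < C; ++c) istd[c] = 1.0 / std::sqrt(var[c] + eps);
  const double *px = x.begin(), *pg = g.begin();
  // pass 1: per-channel sums of g and g * xhat
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int c = 0; c < C; ++c) {
        const R_xlen_t off = (R_xlen_t)N * (c + (R_xlen_t)C * (h + (R_xlen_t)H * w));
        const double mu = mean[c], is = istd[c];
        double s1 = 0, s2 = 0;
        for (int n = 0; n < N; ++n) {
          s1 += pg[off + n];
          s2 += pg[off + n] * (px[off + n] - mu) * is;
        }
        gbeta[c] += s1; ggamma[c] += s2;
      }
  // pass 2: gx = gamma * istd * (g - mean(g) - xhat * mean(g*xhat))
  double *pgx = gx.begin();
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int c = 0; c < C; ++c) {
        const R_xlen_t off = (R_xlen_t)N * (c + (R_xlen_t)C * (h + (R_xlen_t)H * w));
        const double mu = mean[c], is = istd[c], gc = gamma[c] * is;
        const double mg = gbeta[c] / m, mgx = ggamma[c] / m;
        for (int n = 0; n < N; ++n) {
          const double xhat = (px[off + n] - mu) * is;
          pgx[off + n] = gc * (pg[off + n] - mg - xhat * mgx);
        }
      }
  return List::create(_["grad_input"] = gx, _["grad_gamma"] = ggamma,
                      _["grad_beta"] = gbeta);
}

// TanhReLU fast paths: single-pass elementwise evaluation.

// [[Rcpp::export]]
NumericVector tanhrelu_eval(NumericVector x, double a, bool cc) {
  NumericVector out(x.size());
  const double ta = std::tanh(a), *px = x.begin();
  double *po = out.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    const double v = px[i];
    if (std::fabs(v) <= a) po[i] = std::tanh(v);
    else if (cc) po[i] = (v > 0 ? ta + 0.5 * (v - a) : -ta + 0.5 * (v + a));
    else po[i] = 0.5 * v;
  }
  if (!Rf_isNull(x.attr("dim"))) out.attr("dim") = x.attr("dim");
  return out;
}

// [[Rcpp::export]]
NumericVector tanhrelu_grad_eval(NumericVector x, double a) {
  NumericVector out(x.size());
  const double *px = x.begin();
  double *po = out.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    const double v = px[i];
    if (std::fabs(v) <= a) { const double t = std::tanh(v); po[i] = 1 - t * t; }
    else po[i] = 0.5;
  }
  if (!Rf_isNull(x.attr("dim"))) out.attr("dim") = x.attr("dim");
  return out;
}
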