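#include <Rcpp.h>
using namespace Rcpp;

// Direct depthwise convolution kernels (one k x k filter per channel,
// valid padding, stride 1, cross-correlation).  Each channel's plane is
// copied into a contiguous scratch buffer first; because the batch
// dimension is fastest, the (n, oh) block for a fixed output column is one
// contiguous span of N*OH doubles, so the inner loops are simple
// vectorizable axpy/dot operations.

static void gather_plane(const double *px, double *buf, int c,
                         int N, int C, R_xlen_t HW) {
  for (R_xlen_t s = 0; s < HW; ++s)
    memcpy(buf + (R_xlen_t)N * s, px + (R_xlen_t)N * (c + (R_xlen_t)C * s),
           N * sizeof(double));
}

static void scatter_plane(double *px, const double *buf, int c,
                          int N, int C, R_xlen_t HW) {
  for (R_xlen_t s = 0; s < HW; ++s)
    memcpy(px + (R_xlen_t)N * (c + (R_xlen_t)C * s), buf + (R_xlen_t)N * s,
           N * sizeof(double));
}

// [[Rcpp::export]]
NumericVector depthwise_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector d = x.attr("dim");
  const int N = d[0], C = d[1], H = d[2], W = d[3];
  IntegerVector dw = w.attr("dim");            // (C, 1, k, k)
  const int k = dw[2];
  const int OH = H - k + 1, OW = W - k + 1;
  NumericVector out((R_xlen_t)N * C * OH * OW);
  out.attr("dim") = IntegerVector::create(N, C, OH, OW);
  static std::vector<double> in, oc;
  if ((R_xlen_t)in.size() < (R_xlen_t)N * H * W) in.resize((R_xlen_t)N * H * W);
  if ((R_xlen_t)oc.size() < (R_xlen_t)N * OH * OW) oc.resize((R_xlen_t)N * OH * OW);
  const double *pw = w.begin(), *pb = b.begin();
  const int span = N * OH;
  for (int c = 0; c < C; ++c) {
    gather_plane(x.begin(), in.data(), c, N, C, (R_xlen_t)H * W);
    for (int ow = 0; ow < OW; ++ow) {
      double *__restrict__ dst = oc.data() + (R_xlen_t)span * ow;
      const double bc = pb[c];
      for (int i = 0; i < span; ++i) dst[i] = bc;
      for (int kj = 0; kj < k; ++kj)
        for (int ki = 0; ki < k; ++ki) {
          const double wv = pw[c + (R_xlen_t)C * ((R_xlen_t)ki + (R_xlen_t)k * kj)];
          const double *__restrict__ src =
            in.data() + (R_xlen_t)N * (ki + (R_xlen_t)H * (ow + kj));
          for (int i = 0; i < span; ++i) dst[i] += wv * src[i];
        }
    }
    scatter_plane(out.begin(), oc.data(), c, N, C, (R_xlen_t)OH * OW);
  }
  return out;
}

// `need_input_grad = false` (first-layer case) skips the input-gradient
// accumulation entirely and returns a zero grad_input placeholder.

// [[Rcpp::export]]
List depthwise_bwd(NumericVector x, NumericVector w, NumericVector g,
                   bool need_input_grad = true) {
  IntegerVector d = x.attr("dim");
  const int N = d[0], C = d[1], H = d[2], W = d[3];
  IntegerVector dw = w.attr("dim");
  const int k = dw[2];
  const int OH = H - k + 1, OW = W - k + 1;
  NumericVector gx((R_xlen_t)N * C * H * W);
  gx.attr("dim") = IntegerVector::create(N, C, H, W);
  NumericVector gw((R_xlen_t)C * k * k);
  gw.attr("dim") = IntegerVector::create(C, 1, k, k);
  NumericVector gb(C);
  static std::vector<double> in, gc, gxc;
  if ((R_xlen_t)in.size() < (R_xlen_t)N * H * W) in.resize((R_xlen_t)N * H * W);
  if ((R_xlen_t)gc.size() < (R_xlen_t)N * OH * OW) gc.resize((R_xlen_t)N * OH * OW);
  if ((R_xlen_t)gxc.size() < (R_xlen_t)N * H * W) gxc.resize((R_xlen_t)N * H * W);
  const double *pw = w.begin();
  double *pgw = gw.begin(), *pgb = gb.begin();
  const int span = N * OH;
  for (int c = 0; c < C; ++c) {
    gather_plane(x.begin(), in.data(), c, N, C, (R_xlen_t)H * W);
    gather_plane(g.begin(), gc.data(), c, N, C, (R_xlen_t)OH * OW);
    if (need_input_grad)
      std::fill(gxc.begin(), gxc.begin() + (R_xlen_t)N * H * W, 0.0);
    double acc_b = 0;
    for (R_xlen_t i = 0; i < (R_xlen_t)N * OH * OW; ++i) acc_b += gc[i];
    pgb[c] = acc_b;
    for (int ow = 0; ow < OW; ++ow) {
      const double *__restrict__ gsrc = gc.data() + (R_xlen_t)span * ow;
      for (int kj = 0; kj < k; ++kj)
        for (int ki = 0; ki < k; ++ki) {
          const R_xlen_t wi = c + (R_xlen_t)C * ((R_xlen_t)ki + (R_xlen_t)k * kj);
          const double wv = pw[wi];
          const R_xlen_t off = (R_xlen_t)N * (ki + (R_xlen_t)H * (ow + kj));
          const double *__restrict__ src = in.data() + off;
          double s0 = 0, s1 = 0, s2 = 0, s3 = 0;
          int i = 0;
          if (need_input_grad) {
            double *__restrict__ gdst = gxc.data() + off;
            for (; i + 3 < span; i += 4) {
              s0 += gsrc[i] * src[i];
              s1 += gsrc[i + 1] * src[i + 1];
              s2 += gsrc[i + 2] * src[i + 2];
              s3 += gsrc[i + 3] * src[i + 3];
              gdst[i] += gsrc[i] * wv;
              gdst[i + 1] += gsrc[i + 1] * wv;
              gdst[i + 2] += gsrc[i + 2] * wv;
              gdst[i + 3] += gsrc[i + 3] * wv;
            }
            for (; i < span; ++i) { s0 += gsrc[i] * src[i]; gdst[i] += gsrc[i] * wv; }
          } else {
            for (; i + 3 < span; i += 4) {
              s0 += gsrc[i] * src[i];
              s1 += gsrc[i + 1] * src[i + 1];
              s2 += gsrc[i + 2] * src[i + 2];
              s3 += gsrc[i + 3] * src[i + 3];
            }
            for (; i < span; ++i) s0 += gsrc[i] * src[i];
          }
          pgw[wi] += s0 + s1 + s2 + s3;
        }
    }
    if (need_input_grad)
      scatter_plane(gx.begin(), gxc.data(), c, N, C, (R_xlen_t)H * W);
  }
  return List::create(_["grad_input"] = gx, _["grad_weights"] = gw,
                      _["grad_biases"] = gb);
}
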