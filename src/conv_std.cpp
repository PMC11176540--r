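#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
# define FCONE
#endif
using namespace Rcpp;

// Standard (all-channel) valid stride-1 cross-correlation, forward and
// backward: patch extraction into persistent scratch buffers, BLAS dgemm
// for the contractions, and direct NCHW scatter of the result.  Weights are
// (F, C, k, k); patch columns are ordered q = kj + k*ki + k*k*c.  Scratch
// buffers persist across calls (R is single-threaded) so the training loop
// does not pay for fresh page allocation at every mini-batch; the backward
// can reuse the forward's patch matrix when the caller guarantees the input
// is unchanged (reuse_cols).

static std::vector<double> buf_P, buf_W2, buf_OM, buf_G, buf_GW2, buf_Gcols;
static int lastN = -1, lastC = -1, lastH = -1, lastW = -1, lastk = -1;

static void grow(std::vector<double> &v, R_xlen_t n) {
  if ((R_xlen_t)v.size() < n) v.resize(n);
}

static void build_cols(const double *px, double *P, int N, int C, int H, int W, int k) {
  const int OH = H - k + 1, OW = W - k + 1;
  const R_xlen_t M = (R_xlen_t)N * OH * OW;
  for (int c = 0; c < C; ++c)
    for (int ki = 0; ki < k; ++ki)
      for (int kj = 0; kj < k; ++kj) {
        double *col = P + ((R_xlen_t)kj + k * ki + (R_xlen_t)k * k * c) * M;
        for (int ow = 0; ow < OW; ++ow)
          for (int oh = 0; oh < OH; ++oh) {
            const double *src = px + (R_xlen_t)N * (c + (R_xlen_t)C * ((oh + ki) + (R_xlen_t)H * (ow + kj)));
            memcpy(col + (R_xlen_t)N * (oh + (R_xlen_t)OH * ow), src, N * sizeof(double));
          }
      }
}

// weight tensor (F,C,k,k) -> K x F matrix, K = C*k*k, row q = kj + k*ki + k*k*c
static void build_wmat(const double *pw, double *W2, int F, int C, int k) {
  for (int f = 0; f < F; ++f)
    for (int c = 0; c < C; ++c)
      for (int ki = 0; ki < k; ++ki)
        for (int kj = 0; kj < k; ++kj)
          W2[(R_xlen_t)kj + k * ki + (R_xlen_t)k * k * c + (R_xlen_t)C * k * k * f] =
            pw[f + (R_xlen_t)F * (c + (R_xlen_t)C * ((R_xlen_t)ki + (R_xlen_t)k * kj))];
}

// [[Rcpp::export]]
NumericVector conv_std_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector d = x.attr("dim"), dw = w.attr("dim");
  const int N = d[0], C = d[1], H = d[2], W = d[3];
  const int F = dw[0], k = dw[2];
  const int OH = H - k + 1, OW = W - k + 1;
  const R_xlen_t M = (R_xlen_t)N * OH * OW, K = (R_xlen_t)C * k * k;
  NumericVector out((R_xlen_t)N * F * OH * OW);
  out.attr("dim") = IntegerVector::create(N, F, OH, OW);
  grow(buf_P, M * K); grow(buf_W2, K * F); grow(buf_OM, M * F);
  build_cols(x.begin(), buf_P.data(), N, C, H, W, k);
  lastN = N; lastC = C; lastH = H; lastW = W; lastk = k;
  build_wmat(w.begin(), buf_W2.data(), F, C, k);
  const double one = 1.0, zero = 0.0;
  const int Mi = (int)M, Ki = (int)K;
  F77_CALL(dgemm)("N", "N", &Mi, &F, &Ki, &one, buf_P.data(), &Mi,
                  buf_W2.data(), &Ki, &zero, buf_OM.data(), &Mi FCONE FCONE);
  double *po = out.begin();
  const double *pb = b.begin();
  for (int ow = 0; ow < OW; ++ow)
    for (int oh = 0; oh < OH; ++oh)
      for (int f = 0; f < F; ++f) {
        const double *src = buf_OM.data() + (R_xlen_t)N * (oh + (R_xlen_t)OH * ow) + M * f;
        double *dst = po + (R_xlen_t)N * (f + (R_xlen_t)F * (oh + (R_xlen_t)OH * ow));
        const double bf = pb[f];
        for (int n = 0; n < N; ++n) dst[n] = src[n] + bf;
      }
  return out;
}

// [[Rcpp::export]]
List conv_std_bwd(NumericVector x, NumericVector w, NumericVector g,
                  bool reuse_cols = false) {
  IntegerVector d = x.attr("dim"), dw = w.attr("dim");
  const int N = d[0], C = d[1], H = d[2], W = d[3];
  const int F = dw[0], k = dw[2];
  const int OH = H - k + 1, OW = W - k + 1;
  const R_xlen_t M = (R_xlen_t)N * OH * OW, K = (R_xlen_t)C * k * k;
  grow(buf_P, M * K); grow(buf_W2, K * F); grow(buf_G, M * F);
  grow(buf_GW2, K * F); grow(buf_Gcols, M * K);
  if (!(reuse_cols && N == lastN && C == lastC && H == lastH && W == lastW && k == lastk)) {
    build_cols(x.begin(), buf_P.data(), N, C, H, W, k);
    lastN = N; lastC = C; lastH = H; lastW = W; lastk = k;
  }
  build_wmat(w.begin(), buf_W2.data(), F, C, k);
  // gather grad_out (N,F,OH,OW) into M x F column-form
  const double *pg = g.begin();
  for (int ow = 0; ow < OW; ++ow)
    for (int oh = 0; oh < OH; ++oh)
      for (int f = 0; f < F; ++f)
        memcpy(buf_G.data() + (R_xlen_t)N * (oh + (R_xlen_t)OH * ow) + M * f,
               pg + (R_xlen_t)N * (f + (R_xlen_t)F * (oh + (R_xlen_t)OH * ow)),
               N * sizeof(double));
  NumericVector gb(F);
  for (int f = 0; f < F; ++f) {
    double s = 0;
    const double *col = buf_G.data() + M * f;
    for (R_xlen_t r = 0; r < M; ++r) s += col[r];
    gb[f] = s;
  }
  const double one = 1.0, zero = 0.0;
  const int Mi = (int)M, Ki = (int)K;
  F77_CALL(dgemm)("T", "N", &Ki, &F, &Mi, &one, buf_P.data(), &Mi,
                  buf_G.data(), &Mi, &zero, buf_GW2.data(), &Ki FCONE FCONE);
  F77_CALL(dgemm)("N", "T", &Mi, &Ki, &F, &one, buf_G.data(), &Mi,
                  buf_W2.data(), &Ki, &zero, buf_Gcols.data(), &Mi FCONE FCONE);
  NumericVector gw((R_xlen_t)F * C * k * k);
  gw.attr("dim") = IntegerVector::create(F, C, k, k);
  double *pgw = gw.begin();
  for (int f = 0; f < F; ++f)
    for (int c = 0; c < C; ++c)
      for (int ki = 0; ki < k; ++ki)
        for (int kj = 0; kj < k; ++kj)
          pgw[f + (R_xlen_t)F * (c + (R_xlen_t)C * ((R_xlen_t)ki + (R_xlen_t)k * kj))] =
            buf_GW2[(R_xlen_t)kj + k * ki + (R_xlen_t)k * k * c + K * f];
  NumericVector gx((R_xlen_t)N * C * H * W);
  gx.attr("dim") = IntegerVector::create(N, C, H, W);
  double *pgx = gx.begin();
  for (int c = 0; c < C; ++c)
    for (int ki = 0; ki < k; ++ki)
      for (int kj = 0; kj < k; ++kj) {
        const double *col = buf_Gcols.data() + ((R_xlen_t)kj + k * ki + (R_xlen_t)k * k * c) * M;
        for (int ow = 0; ow < OW; ++ow)
          for (int oh = 0; oh < OH; ++oh) {
            double *dst = pgx + (R_xlen_t)N * (c + (R_xlen_t)C * ((oh + ki) + (R_xlen_t)H * (ow + kj)));
            const double *src = col + (R_xlen_t)N * (oh + (R_xlen_t)OH * ow);
            for (int n = 0; n < N; ++n) dst[n] += src[n];
          }
      }
  // reuse contract is one-shot: a later backward must rebuild unless its
  // forward ran in between
  lastN = -1;
  return List::create(_["grad_input"] = gx, _["grad_weights"] = gw,
                      _["grad_biases"] = gb);
}
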