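// Convolution lowering kernels: im2col and its adjoint.
//
// Feature maps are [C, H, W, B] column-major doubles. im2col lowers a
// padded map to the [C*k^2, outH*outW*B] matrix whose product with the
// weight matrix is the convolution; col2im scatter-adds the matrix back
// (the exact adjoint, used by the backward pass).

#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix im2col_cpp(const NumericVector& xp, int C, int Hp, int Wp,
                         int B, int k, int s, int oh, int ow) {
  const R_xlen_t nrow = (R_xlen_t)C * k * k;
  NumericMatrix out(nrow, (R_xlen_t)oh * ow * B);
  const double* x = xp.begin();
  double* o = out.begin();
  for (int b = 0; b < B; ++b)
    for (int w = 0; w < ow; ++w)
      for (int h = 0; h < oh; ++h) {
        R_xlen_t col = h + (R_xlen_t)oh * (w + (R_xlen_t)ow * b);
        double* oc = o + col * nrow;
        for (int dj = 0; dj < k; ++dj)
          for (int di = 0; di < k; ++di) {
            const double* src = x + (R_xlen_t)C *
              ((h * s + di) + (R_xlen_t)Hp * ((w * s + dj) + (R_xlen_t)Wp * b));
            std::memcpy(oc + (R_xlen_t)C * (di + k * dj), src,
                        C * sizeof(double));
          }
      }
  return out;
}

// [[Rcpp::export]]
NumericVector col2im_cpp(const NumericMatrix& dm, int C, int Hp, int Wp,
                         int B, int k, int s, int oh, int ow) {
  NumericVector out((R_xlen_t)C * Hp * Wp * B);  // zero-initialised
  const double* m = dm.begin();
  double* o = out.begin();
  const R_xlen_t nrow = (R_xlen_t)C * k * k;
  for (int b = 0; b < B; ++b)
    for (int w = 0; w < ow; ++w)
      for (int h = 0; h < oh; ++h) {
        R_xlen_t col = h + (R_xlen_t)oh * (w + (R_xlen_t)ow * b);
        const double* mc = m + col * nrow;
        for (int dj = 0; dj < k; ++dj)
          for (int di = 0; di < k; ++di) {
            double* dst = o + (R_xlen_t)C *
              ((h * s + di) + (R_xlen_t)Hp * ((w * s + dj) + (R_xlen_t)Wp * b));
            const double* src = mc + (R_xlen_t)C * (di + k * dj);
            for (int c = 0; c < C; ++c) dst[c] += src[c];
          }
      }
  return out;
}

// [[Rcpp::export]]
List maxpool_fwd_cpp(const NumericVector& xp, int C, int Hp, int Wp, int B,
                     int k, int s, int oh, int ow) {
  NumericVector best((R_xlen_t)C * oh * ow * B);
  IntegerVector arg((R_xlen_t)C * oh * ow * B);
  const double* x = xp.begin();
  double* bs = best.begin();
  int* ag = arg.begin();
  for (int b = 0; b < B; ++b)
    for (int w = 0; w < ow; ++w)
      for (int h = 0; h < oh; ++h) {
        R_xlen_t o = (R_xlen_t)C * (h + (R_xlen_t)oh * (w + (R_xlen_t)ow * b));
        for (int c = 0; c < C; ++c) { bs[o + c] = R_NegInf; ag[o + c] = 0; }
        for (int dj = 0; dj < k; ++dj)
          for (int di = 0; di < k; ++di) {
            const double* src = x + (R_xlen_t)C *
              ((h * s + di) + (R_xlen_t)Hp * ((w * s + dj) + (R_xlen_t)Wp * b));
            int tap = 1 + di + k * dj;
            for (int c = 0; c < C; ++c)
              if (src[c] > bs[o + c]) { bs[o + c] = src[c]; ag[o + c] = tap; }
          }
      }
  return List::create(_["best"] = best, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd_cpp(const NumericVector& dy, const IntegerVector& arg,
                              int C, int Hp, int Wp, int B, int k, int s,
                              int oh, int ow) {
  NumericVector out((R_xlen_t)C * Hp * Wp * B);
  const double* d = dy.begin();
  const int* ag = arg.begin();
  double* o = out.begin();
  for (int b = 0; b < B; ++b)
    for (int w = 0; w < ow; ++w)
      for (int h = 0; h < oh; ++h) {
        R_xlen_t oo = (R_xlen_t)C * (h + (R_xlen_t)oh * (w + (R_xlen_t)ow * b));
        for (int c = 0; c < C; ++c) {
          int tap = ag[oo + c] - 1;
          int di = tap % k, dj = tap / k;
          o[(R_xlen_t)C * ((h * s + di) +
                           (R_xlen_t)Hp * ((w * s + dj) + (R_xlen_t)Wp * b)) + c] +=
            d[oo + c];
        }
      }
  return out;
}
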