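#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for a 2-state chain (state 0 = nonIBD, 1 = IBD)
// with marker-specific transition stay-probabilities. e0/e1: emission
// likelihoods per marker; stay0/stay1: probability of remaining in state
// 0/1 across the gap preceding marker t (length L-1); prior1: stationary
// probability of state 1 at the first marker.
// [[Rcpp::export]]
NumericVector ibd_forward_backward(NumericVector e0, NumericVector e1,
                                   NumericVector stay0, NumericVector stay1,
                                   double prior1) {
  int L = e0.size();
  NumericVector a0(L), a1(L), b0(L), b1(L), scale(L), post(L);
  a0[0] = (1.0 - prior1) * e0[0];
  a1[0] = prior1 * e1[0];
  scale[0] = a0[0] + a1[0];
  a0[0] /= scale[0];
  a1[0] /= scale[0];
  for (int t = 1; t < L; ++t) {
    double s0 = stay0[t - 1], s1 = stay1[t - 1];
    a0[t] = (a0[t - 1] * s0 + a1[t - 1] * (1.0 - s1)) * e0[t];
    a1[t] = (a0[t - 1] * (1.0 - s0) + a1[t - 1] * s1) * e1[t];
    scale[t] = a0[t] + a1[t];
    if (scale[t] <= 0) scale[t] = DBL_MIN;
    a0[t] /= scale[t];
    a1[t] /= scale[t];
  }
  b0[L - 1] = 1.0;
  b1[L - 1] = 1.0;
  for (int t = L - 2; t >= 0; --t) {
    double s0 = stay0[t], s1 = stay1[t];
    b0[t] = (s0 * e0[t + 1] * b0[t + 1] +
             (1.0 - s0) * e1[t + 1] * b1[t + 1]) / scale[t + 1];
    b1[t] = ((1.0 - s1) * e0[t + 1] * b0[t + 1] +
             s1 * e1[t + 1] * b1[t + 1]) / scale[t + 1];
  }
  for (int t = 0; t < L; ++t) {
    double p0 = a0[t] * b0[t], p1 = a1[t] * b1[t];
    post[t] = p1 / (p0 + p1);
  }
  return post;
}
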