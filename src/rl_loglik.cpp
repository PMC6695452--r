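#include <Rcpp.h>
using namespace Rcpp;

// Forward-pass log-likelihood of a single-condition choice sequence under
// the delta-rule / softmax model. `variant`: 1 = chosen only,
// 2 = unchosen updated toward (1 - R), 3 = unchosen decays toward 0.
// The choice log-probability is accumulated before the value update.
// [[Rcpp::export]]
double rl_loglik_cpp(IntegerVector chosen, NumericVector reward,
                     double alpha, double beta, int variant, double v0) {
  int n = chosen.size();
  if (reward.size() != n) stop("chosen and reward lengths differ");
  if (beta <= 0) stop("beta must be > 0");
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]");
  double v1 = v0, v2 = v0, ll = 0.0;
  const double floor_p = 1e-12;
  for (int t = 0; t < n; ++t) {
    int c = chosen[t];
    if (c != 1 && c != 2) stop("chosen must be 1 or 2");
    double z1 = v1 / beta, z2 = v2 / beta;
    double m = z1 > z2 ? z1 : z2;
    double e1 = std::exp(z1 - m), e2 = std::exp(z2 - m);
    double p = (c == 1 ? e1 : e2) / (e1 + e2);
    if (p < floor_p) p = floor_p;
    ll += std::log(p);
    double r = reward[t];
    if (c == 1) {
      v1 += alpha * (r - v1);
      if (variant == 2) v2 += alpha * ((1.0 - r) - v2);
      else if (variant == 3) v2 += alpha * (0.0 - v2);
    } else {
      v2 += alpha * (r - v2);
      if (variant == 2) v1 += alpha * ((1.0 - r) - v1);
      else if (variant == 3) v1 += alpha * (0.0 - v1);
    }
  }
  return ll;
}
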