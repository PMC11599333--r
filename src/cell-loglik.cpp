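#include <Rcpp.h>
using namespace Rcpp;

// Bernoulli log-likelihood over all species-site cells of the unified
// affinity model. eta are the logit-linear predictors of the two submodels;
// the composition is logit(DDA) = (eta_sp + eta_site)/2,
// q = clamp((1-DDA)*suit, eps, 1-eps), logit(p) = logit(q) + delta.
// [[Rcpp::export]]
double cell_loglik(NumericVector eta_sp, NumericVector eta_site,
                   NumericVector suit, IntegerVector prab,
                   double delta, double eps) {
  const int S = eta_sp.size(), N = eta_site.size();
  const double ed = std::exp(delta);
  double ll = 0.0;
  for (int s = 0; s < N; ++s) {
    const double es = eta_site[s];
    const int off = s * S;
    for (int i = 0; i < S; ++i) {
      const double l = 0.5 * (eta_sp[i] + es);
      const double one_minus_dda = 1.0 / (1.0 + std::exp(l));
      double q = one_minus_dda * suit[off + i];
      if (q < eps) q = eps; else if (q > 1.0 - eps) q = 1.0 - eps;
      const double p = q * ed / (1.0 + q * (ed - 1.0));
      ll += prab[off + i] ? std::log(p) : std::log1p(-p);
    }
  }
  return ll;
}
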