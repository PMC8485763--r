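#include <Rcpp.h>
using namespace Rcpp;

// Panjer recursion for a compound-Poisson count distribution.
//
// X = sum of M iid clone sizes, M ~ Poisson(m), clone-size law h_0..h_nmax
// (h_0 > 0 arises when only a fraction of each culture is plated, so a
// mutation can contribute zero observed colonies).  Returns p_0..p_nmax.
//
//   p_0 = exp(-m * (1 - h_0))
//   p_n = (m/n) * sum_{j=1}^{n} j * h_j * p_{n-j}
//
// [[Rcpp::export]]
NumericVector panjer_pmf(double m, NumericVector h) {
  const int nmax = h.size() - 1;
  NumericVector p(nmax + 1);
  p[0] = std::exp(-m * (1.0 - h[0]));
  for (int n = 1; n <= nmax; ++n) {
    double s = 0.0;
    for (int j = 1; j <= n; ++j) s += j * h[j] * p[n - j];
    p[n] = m * s / n;
  }
  return p;
}

// Binomial(epsilon) thinning of the Lea-Coulson clone-size law
// q_y = 1/(y*(y+1)), y >= 1.  Returns h_k = sum_{y=1}^{ymax} q_y *
// dbinom(k, y, epsilon) for k = 0..nmax; the y-tail beyond ymax is bounded
// by the caller.  The binomial pmf is evaluated by the multiplicative
// recurrence in k, in log space to avoid underflow for large y.
//
// [[Rcpp::export]]
NumericVector thin_clone_law(double eps, int nmax, int ymax) {
  NumericVector h(nmax + 1);
  const double leps = std::log(eps), l1me = std::log1p(-eps);
  for (int y = 1; y <= ymax; ++y) {
    const double qy = 1.0 / (static_cast<double>(y) * (y + 1.0));
    double lb = y * l1me;  // log dbinom(0, y, eps)
    const int kmax = y < nmax ? y : nmax;
    for (int k = 0; k <= kmax; ++k) {
      if (lb > -745.0) h[k] += qy * std::exp(lb);
      if (k < kmax)
        lb += std::log(static_cast<double>(y - k) / (k + 1.0)) + leps - l1me;
    }
  }
  return h;
}
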