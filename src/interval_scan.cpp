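#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Exhaustive O(n^2) scan for the best-scoring contiguous interval under
// the fuzzy-zero interval score  mean(x) / sqrt(sigma^2/n + sigma_g^2).
// With sigma_g = 0 this is the classical interval score sum/(sigma*sqrt(n)).
// Ties on |score| resolve to the leftmost start, then the shortest
// interval (first encountered in the i-ascending, j-ascending scan).
// Returns 0-based half-open probe indices.
// [[Rcpp::export]]
List best_interval_cpp(NumericVector x, double sigma, double sigma_g) {
  const int n = x.size();
  if (n < 1) stop("empty interval");
  std::vector<double> cs(n + 1, 0.0);
  for (int i = 0; i < n; ++i) cs[i + 1] = cs[i] + x[i];
  const double s2 = sigma * sigma, g2 = sigma_g * sigma_g;
  double best = -1.0;
  int bi = 0, bj = 1;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j <= n; ++j) {
      const double m = (double)(j - i);
      const double sc = (cs[j] - cs[i]) / m / std::sqrt(s2 / m + g2);
      const double a = std::fabs(sc);
      if (a > best) { best = a; bi = i; bj = j; }
    }
  }
  const double m = (double)(bj - bi);
  const double sc = (cs[bj] - cs[bi]) / m / std::sqrt(s2 / m + g2);
  return List::create(_["start"] = bi, _["end"] = bj, _["score"] = sc);
}
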