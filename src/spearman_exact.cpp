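// Exact two-sided permutation p-value for the Spearman rank correlation.
// Enumerates distinct arrangements of the y ranks (next_permutation over the
// sorted multiset); with mid-rank ties every distinct arrangement corresponds
// to the same number of underlying permutations, so uniform weighting over
// distinct arrangements gives the exact permutation p-value.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export(name = ".spearman_exact_p_cpp")]]
double spearman_exact_p_cpp(NumericVector rx, NumericVector ry) {
  const int n = rx.size();
  double mx = 0, my = 0;
  for (int i = 0; i < n; ++i) { mx += rx[i]; my += ry[i]; }
  mx /= n; my /= n;
  double sx = 0, sy = 0, sxy = 0;
  for (int i = 0; i < n; ++i) {
    sx += (rx[i] - mx) * (rx[i] - mx);
    sy += (ry[i] - my) * (ry[i] - my);
    sxy += (rx[i] - mx) * (ry[i] - my);
  }
  if (sx <= 0 || sy <= 0) return NA_REAL;
  const double denom = std::sqrt(sx * sy);
  const double robs = std::abs(sxy / denom);
  const double tol = 1e-12;

  std::vector<double> perm(ry.begin(), ry.end());
  std::sort(perm.begin(), perm.end());
  long long total = 0, extreme = 0;
  do {
    double s = 0;
    for (int i = 0; i < n; ++i) s += (rx[i] - mx) * (perm[i] - my);
    ++total;
    if (std::abs(s) / denom >= robs - tol) ++extreme;
  } while (std::next_permutation(perm.begin(), perm.end()));
  return (double)extreme / (double)total;
}
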