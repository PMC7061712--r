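#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Exhaustive search over the pairwise-comparison classifiers
// 1[x_i - x_j >= 0], i != j. For each ordered pair the weight vector is
// w = alpha (e_i - e_j), t = 0, and the soft-margin objective reduces to
// a one-dimensional convex problem in the scale alpha >= 0:
//   reg == 2:  g(a) = a^2   + C * sum_k max(0, 1 - a s_k)   (0.5||w||^2 = a^2)
//   reg == 1:  g(a) = 2 a   + C * sum_k max(0, 1 - a s_k)   (||w||_1  = 2 a)
// with s_k = y_k (x_k[i] - x_k[j]), y in {+1,-1}. g is piecewise
// quadratic/linear with kinks at a = 1/s_k for s_k > 0; the exact
// minimiser is found by walking the kinks in ascending order.
//
// Returns the lexicographically smallest ordered pair (strict improvement
// required) minimising the objective. alpha = 0 (zero weight vector
// optimal) is flagged degenerate; predictions of the pair rule do not
// depend on alpha, so callers may report the model at any alpha > 0.

struct OneD {
  double alpha, value;
};

static OneD solve_1d(const std::vector<double>& s, double C, int reg) {
  const int m = (int)s.size();
  double S = 0.0;                       // sum over active hinges at a = 0+
  std::vector< std::pair<double,double> > kinks;  // (breakpoint, s value)
  kinks.reserve(m);
  for (int k = 0; k < m; ++k) {
    S += s[k];
    if (s[k] > 0.0) kinks.push_back(std::make_pair(1.0 / s[k], s[k]));
  }
  std::sort(kinks.begin(), kinks.end());

  double prev = 0.0, alpha = -1.0, curS = S;
  for (size_t q = 0; q <= kinks.size(); ++q) {
    double upper = (q < kinks.size()) ? kinks[q].first : R_PosInf;
    if (reg == 2) {
      double astar = 0.5 * C * curS;    // zero of g' = 2a - C curS
      if (astar < prev) { alpha = prev; break; }
      if (astar <= upper) { alpha = astar; break; }
    } else {
      double slope = 2.0 - C * curS;    // g' on this segment
      if (slope >= 0.0) { alpha = prev; break; }
      if (!std::isfinite(upper)) { alpha = prev; break; }  // cannot happen: slope > 0 at the end
    }
    prev = upper;
    if (q < kinks.size()) curS -= kinks[q].second;
  }
  if (alpha < 0.0) alpha = 0.0;

  double hinge = 0.0;
  for (int k = 0; k < m; ++k) {
    double v = 1.0 - alpha * s[k];
    if (v > 0.0) hinge += v;
  }
  OneD out;
  out.alpha = alpha;
  out.value = (reg == 2 ? alpha * alpha : 2.0 * alpha) + C * hinge;
  return out;
}

// [[Rcpp::export]]
List mon_search_cpp(NumericMatrix X, NumericVector y, double C, int reg) {
  const int m = X.nrow(), n = X.ncol();
  if (n < 2) stop("pairwise-comparison training needs at least 2 features");
  int best_i = -1, best_j = -1;
  double best_val = R_PosInf, best_alpha = 0.0;
  std::vector<double> s(m);

  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      if (i == j) continue;
      for (int k = 0; k < m; ++k) s[k] = y[k] * (X(k, i) - X(k, j));
      OneD r = solve_1d(s, C, reg);
      if (r.value < best_val - 1e-12) {
        best_val = r.value; best_i = i; best_j = j; best_alpha = r.alpha;
      }
    }
  }
  return List::create(_["i"] = best_i + 1, _["j"] = best_j + 1,
                      _["alpha"] = best_alpha, _["objective"] = best_val,
                      _["degenerate"] = (best_alpha <= 0.0));
}
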