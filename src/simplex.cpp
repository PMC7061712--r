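#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Two-phase dense-tableau simplex for
//   min c'x  s.t.  Eq x = f,  Ge x >= h,  x >= 0.
// Dantzig pricing with a switch to Bland's rule after a burn-in to rule
// out cycling. Problem sizes here are a few hundred variables at most,
// so a dense tableau (flat row-major storage) is adequate.
//
// status: 0 solved, 1 infeasible, 2 unbounded, 3 iteration limit.

// [[Rcpp::export]]
List lp_solve_cpp(NumericVector cvec,
                  NumericMatrix Eq, NumericVector f,
                  NumericMatrix Ge, NumericVector h,
                  int max_iter = 50000, double tol = 1e-9) {
  const int n  = cvec.size();
  const int me = Eq.nrow();
  const int mi = Ge.nrow();
  const int m  = me + mi;
  const int nsurp = mi;
  const int nart  = m;
  const int ncol  = n + nsurp + nart;   // artificial cols at the end
  const int stride = ncol + 1;          // last entry of each row: RHS

  // rows: constraints with nonnegative RHS
  std::vector<double> T((size_t)m * stride, 0.0);
  for (int i = 0; i < me; ++i) {
    double sgn = (f[i] < 0.0) ? -1.0 : 1.0;
    double* row = &T[(size_t)i * stride];
    for (int j = 0; j < n; ++j) row[j] = sgn * Eq(i, j);
    row[ncol] = sgn * f[i];
  }
  for (int i = 0; i < mi; ++i) {
    double sgn = (h[i] < 0.0) ? -1.0 : 1.0;
    double* row = &T[(size_t)(me + i) * stride];
    for (int j = 0; j < n; ++j) row[j] = sgn * Ge(i, j);
    row[n + i] = -sgn;                  // surplus
    row[ncol] = sgn * h[i];
  }
  for (int i = 0; i < m; ++i) T[(size_t)i * stride + n + nsurp + i] = 1.0;

  std::vector<int> basis(m);
  for (int i = 0; i < m; ++i) basis[i] = n + nsurp + i;

  // phase-1 reduced costs: d_j = -sum_i T[i][j] for non-artificial cols
  std::vector<double> obj(ncol, 0.0);
  double objval = 0.0;
  for (int i = 0; i < m; ++i) {
    const double* row = &T[(size_t)i * stride];
    for (int j = 0; j < n + nsurp; ++j) obj[j] -= row[j];
    objval -= row[ncol];
  }

  int allowed_cols = ncol;              // phase 2 bars artificials
  int iter = 0;
  const int bland_after = 8 * (m + ncol);

  auto pivot_loop = [&]() -> int {
    // returns 1 optimal, 2 unbounded, 3 iteration limit
    while (true) {
      if (++iter > max_iter) return 3;
      const bool bland = iter > bland_after;
      int pc = -1;
      double bestval = -tol;
      for (int j = 0; j < allowed_cols; ++j) {
        if (obj[j] < bestval) {
          pc = j;
          if (bland) break;
          bestval = obj[j];
        }
      }
      if (pc < 0) return 1;
      int pr = -1;
      double bestratio = 0.0;
      for (int i = 0; i < m; ++i) {
        double a = T[(size_t)i * stride + pc];
        if (a > tol) {
          double ratio = T[(size_t)i * stride + ncol] / a;
          bool tie = (pr >= 0) && std::fabs(ratio - bestratio) < 1e-12;
          // Dantzig mode: on ties kick out the highest-index basic
          // variable (artificials leave first); Bland mode: smallest
          // index, as the anticycling argument requires.
          bool better = (pr < 0) || (ratio < bestratio - 1e-12) ||
                        (tie && (bland ? basis[i] < basis[pr]
                                       : basis[i] > basis[pr]));
          if (better) { pr = i; bestratio = ratio; }
        }
      }
      if (pr < 0) return 2;
      double* prow = &T[(size_t)pr * stride];
      const double pv = prow[pc];
      for (int j = 0; j <= ncol; ++j) prow[j] /= pv;
      for (int i = 0; i < m; ++i) {
        if (i == pr) continue;
        double* row = &T[(size_t)i * stride];
        const double fac = row[pc];
        if (fac != 0.0) {
          for (int j = 0; j <= ncol; ++j) row[j] -= fac * prow[j];
          row[pc] = 0.0;                // exact zero in the pivot column
        }
      }
      const double fac = obj[pc];
      if (fac != 0.0) {
        for (int j = 0; j < ncol; ++j) obj[j] -= fac * prow[j];
        objval -= fac * prow[ncol];
        obj[pc] = 0.0;
      }
      basis[pr] = pc;
    }
  };

  int rc = pivot_loop();
  if (rc == 3) return List::create(_["status"] = 3);
  if (rc == 2) return List::create(_["status"] = 1);  // phase 1 is bounded below by 0
  if (-objval > 1e-7) {
    return List::create(_["status"] = 1);             // infeasible
  }

  // drive artificials out of the basis where possible
  for (int i = 0; i < m; ++i) {
    if (basis[i] >= n + nsurp) {
      double* row = &T[(size_t)i * stride];
      int pc = -1;
      for (int j = 0; j < n + nsurp; ++j) {
        if (std::fabs(row[j]) > 1e-7) { pc = j; break; }
      }
      if (pc >= 0) {
        const double pv = row[pc];
        for (int j = 0; j <= ncol; ++j) row[j] /= pv;
        for (int k = 0; k < m; ++k) {
          if (k == i) continue;
          double* rk = &T[(size_t)k * stride];
          const double fac = rk[pc];
          if (fac != 0.0) {
            for (int j = 0; j <= ncol; ++j) rk[j] -= fac * row[j];
            rk[pc] = 0.0;
          }
        }
        basis[i] = pc;
      }
      // else: redundant row, artificial stays basic at zero
    }
  }

  // phase 2: real costs; artificial columns barred from entering
  allowed_cols = n + nsurp;
  std::fill(obj.begin(), obj.end(), 0.0);
  for (int j = 0; j < n; ++j) obj[j] = cvec[j];
  objval = 0.0;
  for (int i = 0; i < m; ++i) {
    int b = basis[i];
    double cb = (b < n) ? cvec[b] : 0.0;
    if (cb != 0.0) {
      const double* row = &T[(size_t)i * stride];
      for (int j = 0; j < ncol; ++j) obj[j] -= cb * row[j];
      objval -= cb * row[ncol];
    }
  }

  rc = pivot_loop();
  if (rc == 3) return List::create(_["status"] = 3);
  if (rc == 2) return List::create(_["status"] = 2);

  NumericVector x(n);
  for (int i = 0; i < m; ++i) {
    if (basis[i] < n) x[basis[i]] = T[(size_t)i * stride + ncol];
  }
  return List::create(_["status"] = 0, _["x"] = x, _["value"] = -objval,
                      _["iterations"] = iter);
}
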