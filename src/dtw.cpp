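#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

namespace {

// Band membership on 0-based cell indices. width < 0 means unconstrained
// (the forward variant still forbids the target lagging the source).
inline bool in_band(int i, int j, int width, bool forward) {
  if (forward) {
    int d = j - i;
    if (d < 0) return false;
    return width < 0 || d <= width;
  }
  if (width < 0) return true;
  return std::abs(i - j) <= width;
}

inline double local_cost(double x, double y, bool squared) {
  double d = std::fabs(x - y);
  return squared ? d * d : d;
}

// symmetric2 cumulative cost: D(0,0) = c(0,0) with weight 1, diagonal steps
// weighted 2, axis steps 1; cells outside the band stay +Inf.
void fill_cum(const double* a, int n, const double* b, int m,
              int width, bool forward, bool squared, std::vector<double>& D) {
  const double inf = std::numeric_limits<double>::infinity();
  std::fill(D.begin(), D.end(), inf);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      if (!in_band(i, j, width, forward)) continue;
      double c = local_cost(a[i], b[j], squared);
      size_t at = (size_t)i * m + j;
      if (i == 0 && j == 0) { D[at] = c; continue; }
      double best = inf;
      if (i > 0 && j > 0) {
        double v = D[(size_t)(i - 1) * m + (j - 1)] + 2.0 * c;
        if (v < best) best = v;
      }
      if (i > 0) {
        double v = D[(size_t)(i - 1) * m + j] + c;
        if (v < best) best = v;
      }
      if (j > 0) {
        double v = D[(size_t)i * m + (j - 1)] + c;
        if (v < best) best = v;
      }
      D[at] = best;
    }
  }
}

} // namespace

// [[Rcpp::export]]
List cpp_dtw(NumericVector a, NumericVector b, int width, bool forward,
             bool squared, bool want_path) {
  int n = a.size(), m = b.size();
  std::vector<double> D((size_t)n * m);
  fill_cum(REAL(a), n, REAL(b), m, width, forward, squared, D);
  double raw = D[(size_t)n * m - 1];
  bool feasible = std::isfinite(raw);
  IntegerMatrix path(0, 2);
  if (want_path && feasible) {
    std::vector<std::pair<int, int> > rev;
    int i = n - 1, j = m - 1;
    rev.push_back(std::make_pair(i, j));
    while (i > 0 || j > 0) {
      double cur = D[(size_t)i * m + j];
      double c = local_cost(a[i], b[j], squared);
      double eps = 1e-9 * (1.0 + std::fabs(cur));
      // equal-cost predecessors resolved toward the diagonal step
      if (i > 0 && j > 0 &&
          std::fabs(D[(size_t)(i - 1) * m + (j - 1)] + 2.0 * c - cur) <= eps) {
        --i; --j;
      } else if (i > 0 &&
                 std::fabs(D[(size_t)(i - 1) * m + j] + c - cur) <= eps) {
        --i;
      } else if (j > 0) {
        --j;
      } else {
        --i;
      }
      rev.push_back(std::make_pair(i, j));
    }
    path = IntegerMatrix((int)rev.size(), 2);
    for (size_t s = 0; s < rev.size(); ++s) {
      path((int)s, 0) = rev[rev.size() - 1 - s].first + 1;
      path((int)s, 1) = rev[rev.size() - 1 - s].second + 1;
    }
  }
  return List::create(_["raw_cost"] = raw,
                      _["feasible"] = feasible,
                      _["path"] = path);
}

// All-pairs normalized DTW distances between the rows of `traj`
// (symptoms x time). Distances are raw_cost / (N + M) = raw / (2L).
// [[Rcpp::export]]
NumericMatrix cpp_all_pairs(NumericMatrix traj, int width, bool forward,
                            bool squared) {
  int S = traj.nrow(), L = traj.ncol();
  NumericMatrix out(S, S);
  std::vector<double> D((size_t)L * L);
  std::vector<double> rows((size_t)S * L);
  for (int s = 0; s < S; ++s)
    for (int t = 0; t < L; ++t) rows[(size_t)s * L + t] = traj(s, t);
  double norm = 2.0 * L;
  for (int i = 0; i < S; ++i) {
    int j0 = forward ? 0 : i + 1;
    for (int j = j0; j < S; ++j) {
      if (i == j) continue;
      fill_cum(&rows[(size_t)i * L], L, &rows[(size_t)j * L], L,
               width, forward, squared, D);
      double d = D[(size_t)L * L - 1] / norm;
      out(i, j) = d;
      if (!forward) out(j, i) = d;
    }
  }
  return out;
}
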