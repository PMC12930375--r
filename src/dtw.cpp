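#include <Rcpp.h>
using namespace Rcpp;

// Dependent (multivariate) DTW with the classic cumulative recurrence.
// Local cost between frames is the Euclidean distance across all dimensions
// (or its square when `squared` is true, used by the barycenter updates).
// Backtrace tie-breaking is fixed: diagonal, then vertical (advance in a),
// then horizontal, so paths are reproducible across runs and platforms.

static inline double local_cost(const NumericMatrix& a, const NumericMatrix& b,
                                int i, int j, bool squared) {
  double s = 0.0;
  const int d = a.ncol();
  for (int k = 0; k < d; ++k) {
    const double diff = a(i, k) - b(j, k);
    s += diff * diff;
  }
  return squared ? s : std::sqrt(s);
}

static List dtw_backtrace(const std::vector<double>& D, int n, int m,
                          double cost) {
  // D is the (n+1) x (m+1) cumulative matrix in column-major layout with a
  // +inf border at row/col 0; backtrace from (n, m).
  std::vector<int> pi, pj;
  int i = n, j = m;
  pi.push_back(i); pj.push_back(j);
  while (i > 1 || j > 1) {
    const double diag = D[(size_t)(j - 1) * (n + 1) + (i - 1)];
    const double vert = D[(size_t)j * (n + 1) + (i - 1)];
    const double horz = D[(size_t)(j - 1) * (n + 1) + i];
    if (i > 1 && j > 1 && diag <= vert && diag <= horz) {
      --i; --j;
    } else if (i > 1 && (j == 1 || vert <= horz)) {
      --i;
    } else {
      --j;
    }
    pi.push_back(i); pj.push_back(j);
  }
  const int L = (int)pi.size();
  IntegerMatrix path(L, 2);
  for (int s = 0; s < L; ++s) {
    path(s, 0) = pi[L - 1 - s];
    path(s, 1) = pj[L - 1 - s];
  }
  return List::create(_["cost"] = cost, _["path"] = path);
}

// [[Rcpp::export]]
List cpp_dtw(NumericMatrix a, NumericMatrix b, bool squared) {
  const int n = a.nrow(), m = b.nrow();
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> D((size_t)(n + 1) * (m + 1), INF);
  D[0] = 0.0;
  for (int j = 1; j <= m; ++j) {
    for (int i = 1; i <= n; ++i) {
      const double c = local_cost(a, b, i - 1, j - 1, squared);
      const double diag = D[(size_t)(j - 1) * (n + 1) + (i - 1)];
      const double vert = D[(size_t)j * (n + 1) + (i - 1)];
      const double horz = D[(size_t)(j - 1) * (n + 1) + i];
      double best = diag;
      if (vert < best) best = vert;
      if (horz < best) best = horz;
      D[(size_t)j * (n + 1) + i] = c + best;
    }
  }
  return dtw_backtrace(D, n, m, D[(size_t)m * (n + 1) + n]);
}

// [[Rcpp::export]]
List cpp_dtw_from_cost(NumericMatrix M) {
  const int n = M.nrow(), m = M.ncol();
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> D((size_t)(n + 1) * (m + 1), INF);
  D[0] = 0.0;
  for (int j = 1; j <= m; ++j) {
    for (int i = 1; i <= n; ++i) {
      const double diag = D[(size_t)(j - 1) * (n + 1) + (i - 1)];
      const double vert = D[(size_t)j * (n + 1) + (i - 1)];
      const double horz = D[(size_t)(j - 1) * (n + 1) + i];
      double best = diag;
      if (vert < best) best = vert;
      if (horz < best) best = horz;
      D[(size_t)j * (n + 1) + i] = M(i - 1, j - 1) + best;
    }
  }
  return dtw_backtrace(D, n, m, D[(size_t)m * (n + 1) + n]);
}
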