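#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Synchronous damped max-product message update for exact-degree
// b-matching. Messages m[i][j] (from node i to node j) follow
//   m_new[i][j] = -( b-th largest of { W[i][k] + m[k][i] : k != i, j } )
// computed per row from the b-th and (b+1)-th largest entries of
// A[i][k] = W[i][k] + m[k][i]: excluding k = j leaves the b-th largest
// unchanged unless A[i][j] itself sits in the top b, in which case the
// (b+1)-th largest takes its place.
//
// [[Rcpp::export]]
List bp_messages_cpp(NumericMatrix W, int b, double damping, double tol,
                     int max_iter) {
  const int n = W.nrow();
  NumericMatrix M(n, n), Mnew(n, n);
  std::vector<double> row(n);
  bool converged = false;
  int it = 0;
  const double neg_inf = -std::numeric_limits<double>::infinity();

  while (it < max_iter) {
    ++it;
    double delta = 0.0;
    for (int i = 0; i < n; ++i) {
      for (int k = 0; k < n; ++k) {
        row[k] = (k == i) ? neg_inf : W(i, k) + M(k, i);
      }
      std::vector<double> sorted(row);
      std::nth_element(sorted.begin(), sorted.begin() + (b - 1), sorted.end(),
                       std::greater<double>());
      const double t_b = sorted[b - 1];
      double t_b1 = neg_inf;
      if (b < n) {
        std::nth_element(sorted.begin() + b, sorted.begin() + b, sorted.end(),
                         std::greater<double>());
        t_b1 = sorted[b];
      }
      for (int j = 0; j < n; ++j) {
        if (j == i) {
          Mnew(i, j) = 0.0;
          continue;
        }
        const double excl = (row[j] >= t_b) ? t_b1 : t_b;
        Mnew(i, j) = -excl;
      }
    }
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < n; ++j) {
        const double d = std::abs(Mnew(i, j) - M(i, j));
        if (d > delta) delta = d;
        M(i, j) = damping * M(i, j) + (1.0 - damping) * Mnew(i, j);
      }
    }
    if (R_finite(delta) && delta < tol) {
      converged = true;
      break;
    }
  }
  return List::create(_["M"] = M, _["converged"] = converged,
                      _["iterations"] = it);
}
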