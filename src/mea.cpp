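#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Needleman-Wunsch over a posterior grid with zero gap cost:
//   M[i][j] = max(M[i-1][j-1] + p(i,j), M[i-1][j], M[i][j-1])
// p has shape (l1+1) x (l2+1) with a zero boundary row/column.
// [[Rcpp::export]]
double mea_score_cpp(NumericMatrix p) {
  const int n = p.nrow(), m = p.ncol();
  std::vector<double> prev(m, 0.0), cur(m, 0.0);
  for (int i = 1; i < n; ++i) {
    cur[0] = 0.0;
    for (int j = 1; j < m; ++j) {
      double best = prev[j - 1] + p(i, j);
      if (prev[j] > best) best = prev[j];
      if (cur[j - 1] > best) best = cur[j - 1];
      cur[j] = best;
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}

// Same recursion with traceback. Ties resolved diagonal > up > left,
// decided while walking back from (n-1, m-1). Returns the move sequence
// from the top-left: 1 = diagonal (consume both), 2 = up (consume row
// profile), 3 = left (consume column profile).
// [[Rcpp::export]]
IntegerVector mea_traceback_cpp(NumericMatrix p) {
  const int n = p.nrow(), m = p.ncol();
  NumericMatrix M(n, m);
  for (int i = 1; i < n; ++i)
    for (int j = 1; j < m; ++j) {
      double best = M(i - 1, j - 1) + p(i, j);
      if (M(i - 1, j) > best) best = M(i - 1, j);
      if (M(i, j - 1) > best) best = M(i, j - 1);
      M(i, j) = best;
    }
  std::vector<int> rev;
  rev.reserve(n + m);
  int i = n - 1, j = m - 1;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 && M(i, j) == M(i - 1, j - 1) + p(i, j)) {
      rev.push_back(1); --i; --j;
    } else if (i > 0 && M(i, j) == M(i - 1, j)) {
      rev.push_back(2); --i;
    } else {
      rev.push_back(3); --j;
    }
  }
  IntegerVector out(rev.size());
  for (size_t k = 0; k < rev.size(); ++k) out[k] = rev[rev.size() - 1 - k];
  return out;
}
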