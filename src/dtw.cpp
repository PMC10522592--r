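#include <Rcpp.h>
using namespace Rcpp;

// Dynamic time warping over a precomputed local cost matrix.
// Classic symmetric step pattern {(1,0),(0,1),(1,1)}, no window constraint.
// Returns the accumulated distance (sum of local costs along the optimal
// path) and the optimal path as 1-based index pairs, start (1,1) to (n,m),
// both indices non-decreasing.
// [[Rcpp::export]]
List dtw_core(NumericMatrix D) {
  const int n = D.nrow(), m = D.ncol();
  NumericMatrix G(n, m);
  IntegerMatrix from(n, m);  // 0 = diag, 1 = up (i-1), 2 = left (j-1)
  G(0, 0) = D(0, 0);
  for (int i = 1; i < n; ++i) { G(i, 0) = G(i - 1, 0) + D(i, 0); from(i, 0) = 1; }
  for (int j = 1; j < m; ++j) { G(0, j) = G(0, j - 1) + D(0, j); from(0, j) = 2; }
  for (int i = 1; i < n; ++i) {
    for (int j = 1; j < m; ++j) {
      double d = G(i - 1, j - 1), u = G(i - 1, j), l = G(i, j - 1);
      double best = d; int arg = 0;
      if (u < best) { best = u; arg = 1; }
      if (l < best) { best = l; arg = 2; }
      G(i, j) = best + D(i, j);
      from(i, j) = arg;
    }
  }
  std::vector<int> pi, pj;
  int i = n - 1, j = m - 1;
  pi.push_back(i + 1); pj.push_back(j + 1);
  while (i > 0 || j > 0) {
    int f = from(i, j);
    if (f == 0) { --i; --j; }
    else if (f == 1) { --i; }
    else { --j; }
    pi.push_back(i + 1); pj.push_back(j + 1);
  }
  std::reverse(pi.begin(), pi.end());
  std::reverse(pj.begin(), pj.end());
  return List::create(_["distance"] = G(n - 1, m - 1),
                      _["index1"] = wrap(pi), _["index2"] = wrap(pj));
}
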