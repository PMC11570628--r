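#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Dynamic time warping between two 1-D series restricted to an arbitrary
// per-row column window [lo[i], hi[i]] (0-based, inclusive). Classic step
// pattern (diagonal / up / left, unit weights) with absolute-difference
// local cost -- the fastdtw convention. With lo = 0, hi = m - 1 everywhere
// this is the exact full dynamic program. Returns the alignment cost and
// the optimal warping path (0-based row/col indices).
// [[Rcpp::export(name = ".dtw_window")]]
List dtw_window(NumericVector a, NumericVector b,
                IntegerVector lo, IntegerVector hi, bool want_path) {
  const int n = a.size(), m = b.size();
  const double inf = std::numeric_limits<double>::infinity();
  if (n == 0 || m == 0) stop("empty trace");
  if (lo.size() != n || hi.size() != n) stop("window bounds must have one entry per row");

  // Band storage: row i occupies cells lo[i]..hi[i].
  std::vector<int> offset(n);
  std::vector<long long> start(n + 1, 0);
  for (int i = 0; i < n; ++i) {
    if (lo[i] < 0 || hi[i] >= m || lo[i] > hi[i]) stop("window bounds out of range");
    offset[i] = lo[i];
    start[i + 1] = start[i] + (hi[i] - lo[i] + 1);
  }
  std::vector<double> D(start[n], inf);
  std::vector<signed char> bp(want_path ? start[n] : 0, -1); // 0=diag 1=up 2=left

  auto cell = [&](int i, int j) -> double {
    if (i < 0 || j < lo[i] || j > hi[i]) return inf;
    return D[start[i] + (j - offset[i])];
  };

  for (int i = 0; i < n; ++i) {
    for (int j = lo[i]; j <= hi[i]; ++j) {
      double diag, up, left;
      if (i == 0 && j == 0) diag = 0.0;
      else diag = (i > 0 && j > 0) ? cell(i - 1, j - 1) : inf;
      up   = (i > 0) ? cell(i - 1, j) : inf;
      left = (j > 0) ? cell(i, j - 1) : inf;
      double best = diag; signed char move = 0;
      if (up < best)   { best = up;   move = 1; }
      if (left < best) { best = left; move = 2; }
      if (best == inf) continue;
      D[start[i] + (j - offset[i])] = std::abs(a[i] - b[j]) + best;
      if (want_path) bp[start[i] + (j - offset[i])] = move;
    }
  }
  double cost = cell(n - 1, m - 1);
  if (!R_finite(cost)) stop("window does not admit a complete warping path");

  if (!want_path) return List::create(_["cost"] = cost);

  std::vector<int> pi, pj;
  int i = n - 1, j = m - 1;
  while (true) {
    pi.push_back(i); pj.push_back(j);
    if (i == 0 && j == 0) break;
    signed char move = bp[start[i] + (j - offset[i])];
    if (move == 0)      { --i; --j; }
    else if (move == 1) { --i; }
    else                { --j; }
  }
  std::reverse(pi.begin(), pi.end());
  std::reverse(pj.begin(), pj.end());
  return List::create(_["cost"] = cost,
                      _["i"] = IntegerVector(pi.begin(), pi.end()),
                      _["j"] = IntegerVector(pj.begin(), pj.end()));
}
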