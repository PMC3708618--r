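#include <Rcpp.h>
using namespace Rcpp;

// Global affine-gap alignment (Gotoh) of two integer-coded sequences.
// Scoring: matched pair (x, y) adds M(x, y); a gap run of length L costs
// gap_open + (L - 1) * gap_extend (both non-positive).  Traceback ties are
// broken diagonal > up (gap in y) > left (gap in x), giving a deterministic
// alignment.  Codes are 0-based row/column indices into M.

static const double NEG_INF = -1e18;

static inline bool close_to(double a, double b) {
  return std::fabs(a - b) < 1e-9;
}

// [[Rcpp::export]]
List gotoh_align_cpp(IntegerVector x, IntegerVector y, NumericMatrix M,
                     double gap_open, double gap_extend) {
  int m = x.size(), n = y.size();
  // three layers: 0 = pair consumed (diag), 1 = gap in y (up, consumes x),
  // 2 = gap in x (left, consumes y)
  NumericMatrix S(m + 1, n + 1), U(m + 1, n + 1), L(m + 1, n + 1);
  for (int i = 0; i <= m; ++i)
    for (int j = 0; j <= n; ++j) { S(i, j) = U(i, j) = L(i, j) = NEG_INF; }
  S(0, 0) = 0.0;
  for (int i = 1; i <= m; ++i) U(i, 0) = gap_open + (i - 1) * gap_extend;
  for (int j = 1; j <= n; ++j) L(0, j) = gap_open + (j - 1) * gap_extend;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double prev = std::max(S(i - 1, j - 1),
                             std::max(U(i - 1, j - 1), L(i - 1, j - 1)));
      S(i, j) = prev + M(x[i - 1], y[j - 1]);
      U(i, j) = std::max(std::max(S(i - 1, j), L(i - 1, j)) + gap_open,
                         U(i - 1, j) + gap_extend);
      L(i, j) = std::max(std::max(S(i, j - 1), U(i, j - 1)) + gap_open,
                         L(i, j - 1) + gap_extend);
    }
  }
  double best = std::max(S(m, n), std::max(U(m, n), L(m, n)));

  // traceback; layer preference S > U > L realizes diag > up > left
  std::vector<int> ai, bi;  // per column: 1-based residue index, 0 = gap
  int i = m, j = n;
  int layer = close_to(S(m, n), best) ? 0 : (close_to(U(m, n), best) ? 1 : 2);
  while (i > 0 || j > 0) {
    if (layer == 0) {
      ai.push_back(i); bi.push_back(j);
      double target = S(i, j) - M(x[i - 1], y[j - 1]);
      --i; --j;
      if (close_to(S(i, j), target)) layer = 0;
      else if (close_to(U(i, j), target)) layer = 1;
      else layer = 2;
    } else if (layer == 1) {  // gap in y at column, consumes x[i]
      ai.push_back(i); bi.push_back(0);
      double cur = U(i, j);
      --i;
      if (i == 0 && j == 0) break;
      if (close_to(S(i, j) + gap_open, cur)) layer = 0;
      else if (close_to(U(i, j) + gap_extend, cur)) layer = 1;
      else layer = 2;
    } else {  // gap in x, consumes y[j]
      ai.push_back(0); bi.push_back(j);
      double cur = L(i, j);
      --j;
      if (i == 0 && j == 0) break;
      if (close_to(S(i, j) + gap_open, cur)) layer = 0;
      else if (close_to(L(i, j) + gap_extend, cur)) layer = 2;
      else layer = 1;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["score"] = best,
                      _["ai"] = IntegerVector(ai.begin(), ai.end()),
                      _["bi"] = IntegerVector(bi.begin(), bi.end()));
}

// Exhaustive enumeration oracle: walks every global alignment path
// (unmemoised recursion over diag/up/left moves with gap-run bookkeeping)
// and returns the best score.  Exponential; for test use on tiny inputs.
static double enum_best(const IntegerVector& x, const IntegerVector& y,
                        const NumericMatrix& M, double go, double ge,
                        int i, int j, int last /*0 diag,1 up,2 left,-1 none*/) {
  int m = x.size(), n = y.size();
  if (i == m && j == n) return 0.0;
  double best = NEG_INF;
  if (i < m && j < n) {
    double s = M(x[i], y[j]) + enum_best(x, y, M, go, ge, i + 1, j + 1, 0);
    if (s > best) best = s;
  }
  if (i < m) {
    double pen = (last == 1) ? ge : go;
    double s = pen + enum_best(x, y, M, go, ge, i + 1, j, 1);
    if (s > best) best = s;
  }
  if (j < n) {
    double pen = (last == 2) ? ge : go;
    double s = pen + enum_best(x, y, M, go, ge, i, j + 1, 2);
    if (s > best) best = s;
  }
  return best;
}

// [[Rcpp::export]]
double enum_align_score_cpp(IntegerVector x, IntegerVector y, NumericMatrix M,
                            double gap_open, double gap_extend) {
  return enum_best(x, y, M, gap_open, gap_extend, 0, 0, -1);
}
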