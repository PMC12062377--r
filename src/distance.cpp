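#include <Rcpp.h>
#include <climits>
#include <string>
#include <vector>
using namespace Rcpp;

// Unit-cost Levenshtein distance. band < 0 -> full dynamic program.
// In banded mode cells with |i - j| > band are treated as unreachable, so the
// returned value is exact whenever the true distance is <= band and otherwise
// a value > band (a valid lower bound is min(truth, band + 1) semantics is
// handled on the R side by flagging results > band as truncated).
static int lev_core(const std::string& a, const std::string& b, int band) {
  const int n = (int)a.size(), m = (int)b.size();
  if (band >= 0 && std::abs(n - m) > band) return band + 1;
  const int INF = INT_MAX / 4;
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j)
    prev[j] = (band < 0 || j <= band) ? j : INF;
  for (int i = 1; i <= n; ++i) {
    int jlo = 1, jhi = m;
    if (band >= 0) {
      jlo = std::max(1, i - band);
      jhi = std::min(m, i + band);
    }
    std::fill(cur.begin(), cur.end(), INF);
    if (band < 0 || i <= band) cur[0] = i;
    for (int j = jlo; j <= jhi; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      int del = prev[j] == INF ? INF : prev[j] + 1;
      int ins = cur[j - 1] == INF ? INF : cur[j - 1] + 1;
      cur[j] = std::min(sub, std::min(del, ins));
    }
    std::swap(prev, cur);
  }
  int d = prev[m];
  if (band >= 0 && d > band) d = band + 1;
  return d;
}

// [[Rcpp::export]]
int lev_distance_cpp(std::string a, std::string b, int band) {
  return lev_core(a, b, band);
}

// For each query, the minimum Levenshtein distance over all subjects and the
// 0-based index of the (first) argmin. Uses a shrinking band: once a distance
// d is seen, later subjects are scanned with band d (exact values <= d are
// still found; larger ones cannot improve the minimum).
// [[Rcpp::export]]
List min_lev_distance_cpp(CharacterVector queries, CharacterVector subjects) {
  const int nq = queries.size(), ns = subjects.size();
  IntegerVector dmin(nq), amin(nq);
  std::vector<std::string> subj(ns);
  for (int k = 0; k < ns; ++k) subj[k] = as<std::string>(subjects[k]);
  for (int i = 0; i < nq; ++i) {
    std::string q = as<std::string>(queries[i]);
    int best = INT_MAX / 4, arg = -1;
    for (int k = 0; k < ns; ++k) {
      int band = (best == INT_MAX / 4) ? -1 : best;
      int d = lev_core(q, subj[k], band);
      if (d < best) { best = d; arg = k; }
      if (best == 0) break;
    }
    dmin[i] = best;
    amin[i] = arg + 1;  // 1-based for R
  }
  return List::create(_["distance"] = dmin, _["index"] = amin);
}

// Full pairwise distance matrix (queries x subjects), used by small oracles.
// [[Rcpp::export]]
IntegerMatrix lev_distance_matrix_cpp(CharacterVector queries,
                                      CharacterVector subjects) {
  const int nq = queries.size(), ns = subjects.size();
  IntegerMatrix out(nq, ns);
  for (int i = 0; i < nq; ++i) {
    std::string q = as<std::string>(queries[i]);
    for (int k = 0; k < ns; ++k)
      out(i, k) = lev_core(q, as<std::string>(subjects[k]), -1);
  }
  return out;
}

// Glocal alignment of a fragment against a reference: the fragment is aligned
// end to end, reference overhangs at either side are free. Unit mismatch and
// gap costs, so the score is the minimum number of edits against the best-
// matching reference window. Tie-break order: match/mismatch, then deletion
// (gap in fragment), then insertion, which keeps alignments anchored.
// Returns ref start (0-based), a per-column op string over {M,I,D}, and cost.
// [[Rcpp::export]]
List glocal_align_cpp(std::string frag, std::string ref) {
  const int n = (int)frag.size(), m = (int)ref.size();
  std::vector<std::vector<int>> dp(n + 1, std::vector<int>(m + 1, 0));
  // row 0: skipping a reference prefix is free
  for (int i = 1; i <= n; ++i) dp[i][0] = i;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int sub = dp[i - 1][j - 1] + (frag[i - 1] == ref[j - 1] ? 0 : 1);
      int del = dp[i][j - 1] + 1;  // consume ref base, gap in fragment
      int ins = dp[i - 1][j] + 1;  // consume fragment base, gap in ref
      dp[i][j] = std::min(sub, std::min(del, ins));
    }
  }
  // free reference suffix: best cell in the last row
  int jend = m;
  for (int j = 0; j <= m; ++j)
    if (dp[n][j] < dp[n][jend]) jend = j;
  int cost = dp[n][jend];
  // traceback
  std::string ops;
  int i = n, j = jend;
  while (i > 0 || j > 0) {
    if (i == 0) break;  // remaining ref prefix is free
    if (j > 0 && dp[i][j] == dp[i - 1][j - 1] +
                                 (frag[i - 1] == ref[j - 1] ? 0 : 1)) {
      ops.push_back('M'); --i; --j;
    } else if (j > 0 && dp[i][j] == dp[i][j - 1] + 1) {
      ops.push_back('D'); --j;
    } else {
      ops.push_back('I'); --i;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["start"] = j, _["ops"] = ops, _["cost"] = cost);
}
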