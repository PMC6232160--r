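#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Affine-gap local alignment (Smith-Waterman / Gotoh).
// A gap of length L costs gap_open + L * gap_extend (BLAST convention),
// so gap_open and gap_extend are handed in as positive penalties.
// Returns the optimal score, 1-based query/subject intervals, identity /
// mismatch / gap-character counts and the aligned strings.
// [[Rcpp::export]]
List cpp_sw_align(std::string q, std::string s, double match, double mismatch,
                  double gap_open, double gap_extend) {
  const int m = (int) q.size(), n = (int) s.size();
  const double NEG = -1e18;
  const int W = n + 1;
  std::vector<double> M((m + 1) * W, 0.0), X((m + 1) * W, NEG), Y((m + 1) * W, NEG);
  std::vector<signed char> tbM((m + 1) * W, 0), tbX((m + 1) * W, 0), tbY((m + 1) * W, 0);
  double best = 0.0; int bi = 0, bj = 0;
  const double open_cost = gap_open + gap_extend;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const int idx = i * W + j;
      // X: q[i-1] aligned to a gap (gap in subject)
      double fm = M[(i - 1) * W + j] - open_cost;
      double fx = X[(i - 1) * W + j] - gap_extend;
      if (fm >= fx) { X[idx] = fm; tbX[idx] = 0; } else { X[idx] = fx; tbX[idx] = 1; }
      // Y: s[j-1] aligned to a gap (gap in query)
      double gm = M[i * W + (j - 1)] - open_cost;
      double gy = Y[i * W + (j - 1)] - gap_extend;
      if (gm >= gy) { Y[idx] = gm; tbY[idx] = 0; } else { Y[idx] = gy; tbY[idx] = 2; }
      // M: q[i-1] aligned to s[j-1]
      const double sub = (q[i - 1] == s[j - 1]) ? match : mismatch;
      double d = M[(i - 1) * W + (j - 1)]; signed char t = 0;
      if (X[(i - 1) * W + (j - 1)] > d) { d = X[(i - 1) * W + (j - 1)]; t = 1; }
      if (Y[(i - 1) * W + (j - 1)] > d) { d = Y[(i - 1) * W + (j - 1)]; t = 2; }
      double val = d + sub;
      if (val < 0.0) val = 0.0;
      M[idx] = val; tbM[idx] = t;
      if (val > best) { best = val; bi = i; bj = j; }
    }
  }
  std::string aq, as;
  int i = bi, j = bj, state = 0;
  int identities = 0, mismatches = 0, gaps = 0;
  if (best > 0.0) {
    while (i > 0 && j > 0) {
      if (state == 0) {
        if (M[i * W + j] <= 0.0) break;
        const signed char t = tbM[i * W + j];
        aq.push_back(q[i - 1]); as.push_back(s[j - 1]);
        if (q[i - 1] == s[j - 1]) ++identities; else ++mismatches;
        --i; --j;
        state = t;
      } else if (state == 1) {
        const signed char t = tbX[i * W + j];
        aq.push_back(q[i - 1]); as.push_back('-'); ++gaps;
        --i;
        state = (t == 0) ? 0 : 1;
      } else {
        const signed char t = tbY[i * W + j];
        aq.push_back('-'); as.push_back(s[j - 1]); ++gaps;
        --j;
        state = (t == 0) ? 0 : 2;
      }
    }
  }
  std::reverse(aq.begin(), aq.end());
  std::reverse(as.begin(), as.end());
  return List::create(
    _["score"] = best,
    _["query_start"] = (best > 0.0) ? i + 1 : NA_INTEGER,
    _["query_end"] = (best > 0.0) ? bi : NA_INTEGER,
    _["subject_start"] = (best > 0.0) ? j + 1 : NA_INTEGER,
    _["subject_end"] = (best > 0.0) ? bj : NA_INTEGER,
    _["identities"] = identities,
    _["mismatches"] = mismatches,
    _["gaps"] = gaps,
    _["aligned_query"] = aq,
    _["aligned_subject"] = as);
}

// Unit-cost global alignment distance: substitutions + gap characters,
// end gaps included. Equals the Levenshtein distance of the two strings.
// [[Rcpp::export]]
int cpp_nw_mismatches(std::string a, std::string b) {
  const int m = (int) a.size(), n = (int) b.size();
  std::vector<int> prev(n + 1), cur(n + 1);
  for (int j = 0; j <= n; ++j) prev[j] = j;
  for (int i = 1; i <= m; ++i) {
    cur[0] = i;
    for (int j = 1; j <= n; ++j) {
      int d = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      d = std::min(d, prev[j] + 1);
      d = std::min(d, cur[j - 1] + 1);
      cur[j] = d;
    }
    std::swap(prev, cur);
  }
  return prev[n];
}

static inline bool can_pair(char x, char y) {
  return (x == 'A' && y == 'U') || (x == 'U' && y == 'A') ||
         (x == 'G' && y == 'C') || (x == 'C' && y == 'G') ||
         (x == 'G' && y == 'U') || (x == 'U' && y == 'G');
}

// Nussinov base-pair maximization over {AU, GC, GU} with a minimum hairpin
// loop of min_loop unpaired bases. Deterministic traceback: leaving the
// 3'-most base unpaired is preferred, then the 5'-most pairing partner.
// [[Rcpp::export]]
List cpp_nussinov(std::string seq, int min_loop) {
  const int n = (int) seq.size();
  std::vector<std::vector<short> > dp(n, std::vector<short>(n, 0));
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      const int j = i + len - 1;
      short best = dp[i][j - 1];
      for (int k = i; k <= j - min_loop - 1; ++k) {
        if (can_pair(seq[k], seq[j])) {
          short v = (short) (((k > i) ? dp[i][k - 1] : 0) + 1 +
                             ((k + 1 <= j - 1) ? dp[k + 1][j - 1] : 0));
          if (v > best) best = v;
        }
      }
      dp[i][j] = best;
    }
  }
  std::string db(n, '.');
  int npairs = 0;
  std::vector<std::pair<int, int> > st;
  if (n > 1) st.push_back(std::make_pair(0, n - 1));
  while (!st.empty()) {
    const int i = st.back().first, j = st.back().second;
    st.pop_back();
    if (i >= j || j - i < min_loop + 1) continue;
    if (dp[i][j] == dp[i][j - 1]) { st.push_back(std::make_pair(i, j - 1)); continue; }
    for (int k = i; k <= j - min_loop - 1; ++k) {
      if (can_pair(seq[k], seq[j])) {
        short v = (short) (((k > i) ? dp[i][k - 1] : 0) + 1 +
                           ((k + 1 <= j - 1) ? dp[k + 1][j - 1] : 0));
        if (v == dp[i][j]) {
          db[k] = '('; db[j] = ')'; ++npairs;
          if (k > i) st.push_back(std::make_pair(i, k - 1));
          if (k + 1 <= j - 1) st.push_back(std::make_pair(k + 1, j - 1));
          break;
        }
      }
    }
  }
  return List::create(_["dotbracket"] = db, _["pairs"] = npairs);
}
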