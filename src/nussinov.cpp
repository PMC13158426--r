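#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Base-pair weight: 0 if the two bases cannot pair. Watson-Crick plus GU
// wobble. mode 0: every pair scores 1 (pair maximization); mode 1: GC = 3,
// AU = 2, GU = 1 (toy stacking-strength weights).
static inline int pair_weight(char a, char b, int mode) {
  bool gc = (a == 'G' && b == 'C') || (a == 'C' && b == 'G');
  bool au = (a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
            (a == 'A' && b == 'T') || (a == 'T' && b == 'A');
  bool gu = (a == 'G' && b == 'U') || (a == 'U' && b == 'G') ||
            (a == 'G' && b == 'T') || (a == 'T' && b == 'G');
  if (mode == 0) return (gc || au || gu) ? 1 : 0;
  if (gc) return 3;
  if (au) return 2;
  if (gu) return 1;
  return 0;
}

static void traceback(int i, int j, const std::vector<std::vector<int> > &M,
                      const std::string &s, int mode, int min_loop,
                      std::string &db) {
  if (i >= j) return;
  if (M[i][j] == M[i][j - 1]) {  // j unpaired
    traceback(i, j - 1, M, s, mode, min_loop, db);
    return;
  }
  for (int k = i; k <= j - min_loop - 1; ++k) {
    int w = pair_weight(s[k], s[j], mode);
    if (w > 0) {
      int left = (k > i) ? M[i][k - 1] : 0;
      int inner = (k + 1 <= j - 1) ? M[k + 1][j - 1] : 0;
      if (M[i][j] == left + inner + w) {
        db[k] = '(';
        db[j] = ')';
        if (k > i) traceback(i, k - 1, M, s, mode, min_loop, db);
        if (k + 1 <= j - 1) traceback(k + 1, j - 1, M, s, mode, min_loop, db);
        return;
      }
    }
  }
  // fall back (should not happen): treat j as unpaired
  traceback(i, j - 1, M, s, mode, min_loop, db);
}

// [[Rcpp::export(name = ".nussinov_fold")]]
List nussinov_fold(std::string seq, int mode, int min_loop) {
  int n = seq.size();
  std::string db(n, '.');
  if (n == 0) return List::create(_["score"] = 0, _["structure"] = "");
  std::vector<std::vector<int> > M(n, std::vector<int>(n, 0));
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = M[i][j - 1];  // j unpaired
      for (int k = i; k <= j - min_loop - 1; ++k) {
        int w = pair_weight(seq[k], seq[j], mode);
        if (w > 0) {
          int left = (k > i) ? M[i][k - 1] : 0;
          int inner = (k + 1 <= j - 1) ? M[k + 1][j - 1] : 0;
          int cand = left + inner + w;
          if (cand > best) best = cand;
        }
      }
      M[i][j] = best;
    }
  }
  traceback(0, n - 1, M, seq, mode, min_loop, db);
  return List::create(_["score"] = -M[0][n - 1], _["structure"] = db);
}
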