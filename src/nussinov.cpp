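#include <Rcpp.h>
using namespace Rcpp;

// Maximum base-pairing (Nussinov-style) fallback folding engine.
// Pairs: Watson-Crick (AU, GC) plus wobble GU; N pairs with nothing.
// Minimum hairpin size 3 => (i,j) may pair only when j - i >= 4 (0-based).
// Traceback tie-break: prefer leaving j unpaired; otherwise pair j with the
// smallest admissible i. This makes the structure a deterministic function
// of the sequence.

static inline bool can_pair(char a, char b) {
  if (a > b) std::swap(a, b);
  return (a == 'A' && b == 'U') ||
         (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'U');
}

// [[Rcpp::export(name = ".nussinov_fold")]]
List nussinov_fold(std::string seq, int min_hairpin = 3) {
  const int n = seq.size();
  const int h = min_hairpin;
  std::string db(n, '.');
  if (n == 0) return List::create(_["db"] = db, _["pairs"] = 0);

  // M[i][j] = max pairs on seq[i..j]; stored as vector of rows i..n-1
  std::vector<std::vector<int> > M(n, std::vector<int>(n, 0));
  for (int len = h + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = M[i][j - 1];                      // j unpaired
      for (int k = i; k <= j - h - 1; ++k) {       // j paired with k
        if (!can_pair(seq[k], seq[j])) continue;
        int v = (k > i ? M[i][k - 1] : 0) + (k + 1 <= j - 1 ? M[k + 1][j - 1] : 0) + 1;
        if (v > best) best = v;
      }
      M[i][j] = best;
    }
  }

  // iterative traceback with explicit stack
  int npairs = 0;
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j || j - i < h + 1) continue;
    if (M[i][j] == M[i][j - 1]) {                  // prefer j unpaired
      stack.push_back(std::make_pair(i, j - 1));
      continue;
    }
    for (int k = i; k <= j - h - 1; ++k) {         // smallest admissible partner
      if (!can_pair(seq[k], seq[j])) continue;
      int v = (k > i ? M[i][k - 1] : 0) + (k + 1 <= j - 1 ? M[k + 1][j - 1] : 0) + 1;
      if (v == M[i][j]) {
        db[k] = '(';
        db[j] = ')';
        ++npairs;
        if (k > i) stack.push_back(std::make_pair(i, k - 1));
        stack.push_back(std::make_pair(k + 1, j - 1));
        break;
      }
    }
  }
  return List::create(_["db"] = db, _["pairs"] = npairs);
}
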