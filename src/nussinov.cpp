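#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Base-pair maximization (Nussinov-style) over Watson-Crick + G.U wobble
// pairs with a minimum hairpin loop, optional forced-unpaired constraints,
// and a deterministic traceback: at (i, j) the 5'-most base i is paired with
// the smallest admissible partner k achieving the optimum, and left unpaired
// only when no pairing achieves it.

static inline bool can_pair(char a, char b) {
  return (a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'U') || (a == 'U' && b == 'G');
}

// [[Rcpp::export]]
List cpp_fold_pairmax(std::string seq, int min_loop, std::string constraint) {
  const int n = (int)seq.size();
  if (n > 2000) stop("sequence longer than 2000 nt");
  for (int i = 0; i < n; ++i) {
    char c = seq[i];
    if (c != 'A' && c != 'C' && c != 'G' && c != 'U')
      stop("invalid RNA alphabet at position %d", i + 1);
  }
  std::vector<bool> blocked(n, false);
  if (!constraint.empty()) {
    if ((int)constraint.size() != n)
      stop("constraint length does not match sequence length");
    for (int i = 0; i < n; ++i) blocked[i] = (constraint[i] == 'x');
  }

  std::vector<std::vector<int>> M(n, std::vector<int>(n, 0));
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = M[i + 1][j]; // i unpaired
      if (!blocked[i]) {
        for (int k = i + min_loop + 1; k <= j; ++k) {
          if (blocked[k] || !can_pair(seq[i], seq[k])) continue;
          int inner = (k - 1 >= i + 1) ? M[i + 1][k - 1] : 0;
          int outer = (k + 1 <= j) ? M[k + 1][j] : 0;
          int v = inner + outer + 1;
          if (v > best) best = v;
        }
      }
      M[i][j] = best;
    }
  }

  std::string db(n, '.');
  std::vector<std::pair<int, int>> stack;
  if (n > 0) stack.push_back({0, n - 1});
  int pairs = 0;
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j || j - i < min_loop + 1) continue;
    int target = M[i][j];
    if (target == 0) continue;
    bool paired = false;
    if (!blocked[i]) {
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (blocked[k] || !can_pair(seq[i], seq[k])) continue;
        int inner = (k - 1 >= i + 1) ? M[i + 1][k - 1] : 0;
        int outer = (k + 1 <= j) ? M[k + 1][j] : 0;
        if (inner + outer + 1 == target) {
          db[i] = '(';
          db[k] = ')';
          ++pairs;
          if (k - 1 >= i + 1) stack.push_back({i + 1, k - 1});
          if (k + 1 <= j) stack.push_back({k + 1, j});
          paired = true;
          break;
        }
      }
    }
    if (!paired) stack.push_back({i + 1, j});
  }

  int total = (n > 1) ? M[0][n - 1] : 0;
  if (pairs != total) stop("internal error: traceback/DP disagreement");
  return List::create(_["dotbracket"] = db, _["pairs"] = total);
}
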