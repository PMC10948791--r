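#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Edge-anchored semi-global alignment of an adapter against a read end.
// Substitutions cost 1; insertions and deletions cost 2. Unit-cost indels
// would make a substitution at the adapter's terminal base score worse than
// a single-deletion reinterpretation, silently shifting the barcode frame
// by one; short-read data is substitution-dominated, so indels are
// admitted but disfavoured.
//
// 5' mode: some SUFFIX adapter[a..A) is aligned against a read PREFIX
// read[0..e); the skipped adapter prefix hangs off the read edge for free.
// 3' mode: some PREFIX adapter[0..b) is aligned against a read SUFFIX
// read[s..L); handled by reversing both strings and reusing the 5' logic.
//
// A qualifying alignment has matched adapter length >= min_overlap and
// errors / matched <= max_error_rate. Best = fewest errors, then longest
// matched adapter, then alignment end closest to the read edge.

struct AdapterHit {
  int start;   // match start in read (0-based)
  int end;     // one past match end in read
  int matched; // adapter bases involved
  int errors;  // edit operations
};

static bool find_prefix_hit(const std::string &seq, const std::string &adapter,
                            double max_error_rate, int min_overlap,
                            AdapterHit &best) {
  const int A = (int)adapter.size();
  const int L = (int)seq.size();
  bool found = false;

  const int SUB = 1, INDEL = 2;
  for (int a = 0; a <= A - min_overlap; ++a) {
    const int m = A - a; // matched adapter length for this suffix
    const int max_err = (int)std::floor(max_error_rate * m + 1e-9);
    const int cap = std::min(L, m + max_err); // read bases worth scanning
    // dp[j] = edit cost of adapter[a..a+i) vs seq[0..j)
    std::vector<int> dp(cap + 1), prev(cap + 1);
    for (int j = 0; j <= cap; ++j) prev[j] = j * INDEL; // leading read bases
    for (int i = 1; i <= m; ++i) {
      dp[0] = i * INDEL; // adapter bases beyond the read's right edge
      const char ac = adapter[a + i - 1];
      for (int j = 1; j <= cap; ++j) {
        int sub = prev[j - 1] + (ac == seq[j - 1] ? 0 : SUB);
        int del = prev[j] + INDEL;     // adapter base skipped
        int ins = dp[j - 1] + INDEL;   // extra read base inside adapter
        dp[j] = std::min(sub, std::min(del, ins));
      }
      std::swap(dp, prev);
    }
    // free end over the read: pick e minimising errors
    for (int e = 0; e <= cap; ++e) {
      int err = prev[e];
      if (err > max_err) continue;
      if (e == 0) continue; // must consume at least one read base
      AdapterHit h = {0, e, m, err};
      // lowest error rate (errors/matched, compared cross-multiplied), then
      // longest matched adapter, then a consumed read span closest to the
      // adapter length (penalising edge indels), then closest to the edge
      long h_rate = (long)h.errors * best.matched;
      long b_rate = (long)best.errors * h.matched;
      int h_dev = std::abs(h.end - h.matched);
      int b_dev = std::abs(best.end - best.matched);
      if (!found || h_rate < b_rate ||
          (h_rate == b_rate && h.matched > best.matched) ||
          (h_rate == b_rate && h.matched == best.matched &&
           (h_dev < b_dev || (h_dev == b_dev && h.end < best.end)))) {
        best = h;
        found = true;
      }
    }
  }
  return found;
}

// [[Rcpp::export]]
IntegerVector cpp_locate_adapter(std::string seq, std::string adapter,
                                 double max_error_rate, int min_overlap,
                                 int which_end) {
  if (adapter.size() > 100)
    stop("adapter longer than 100 nt: likely a misconfiguration");
  if (max_error_rate < 0 || max_error_rate >= 0.5)
    stop("max_error_rate must be in [0, 0.5)");
  if (min_overlap < 1) stop("min_overlap must be >= 1");
  if ((int)adapter.size() < min_overlap) return IntegerVector(0);

  AdapterHit best = {0, 0, 0, 0};
  bool found;
  if (which_end == 5) {
    found = find_prefix_hit(seq, adapter, max_error_rate, min_overlap, best);
    if (!found) return IntegerVector(0);
    return IntegerVector::create(best.start, best.end, best.matched,
                                 best.errors);
  }
  std::string rs(seq.rbegin(), seq.rend());
  std::string ra(adapter.rbegin(), adapter.rend());
  found = find_prefix_hit(rs, ra, max_error_rate, min_overlap, best);
  if (!found) return IntegerVector(0);
  int L = (int)seq.size();
  // map reversed-prefix coordinates back onto the forward read
  return IntegerVector::create(L - best.end, L, best.matched, best.errors);
}
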