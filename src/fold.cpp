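#include <Rcpp.h>
#include <string>
#include <vector>

// Maximum number of non-crossing base pairs (Watson-Crick plus G-T/G-U
// wobble) with a minimum hairpin loop of `min_loop` unpaired nucleotides,
// computed by the classic interval dynamic program. Used as the package's
// built-in secondary-structure stability score for sRNA filtering.

static inline bool can_pair(char a, char b) {
  if (a == 'U') a = 'T';
  if (b == 'U') b = 'T';
  return (a == 'A' && b == 'T') || (a == 'T' && b == 'A') ||
         (a == 'C' && b == 'G') || (a == 'G' && b == 'C') ||
         (a == 'G' && b == 'T') || (a == 'T' && b == 'G');
}

// [[Rcpp::export(name = ".max_noncrossing_pairs")]]
int max_noncrossing_pairs(std::string seq, int min_loop = 3) {
  int n = seq.size();
  if (n < min_loop + 2) return 0;
  std::vector<int> dp((size_t)n * n, 0);
  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int best = dp[(size_t)(i + 1) * n + j];  // i unpaired
      if (can_pair(seq[i], seq[j])) {
        int inner = (j - i - 1 > min_loop) ? dp[(size_t)(i + 1) * n + (j - 1)] : 0;
        if (inner + 1 > best) best = inner + 1;
      }
      for (int k = i + min_loop + 1; k < j; ++k) {  // i pairs with k
        if (!can_pair(seq[i], seq[k])) continue;
        int left = (k - i - 1 > min_loop) ? dp[(size_t)(i + 1) * n + (k - 1)] : 0;
        int right = dp[(size_t)(k + 1) * n + j];
        if (left + 1 + right > best) best = left + 1 + right;
      }
      dp[(size_t)i * n + j] = best;
    }
  }
  return dp[(size_t)0 * n + (n - 1)];
}
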