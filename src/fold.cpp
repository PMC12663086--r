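#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Nussinov maximum Watson-Crick base pairing, minimum hairpin loop of 3
// unpaired bases. Returns the negated pair count, a crude stand-in
// "energy" for windowed folding scans: always <= 0, more negative for
// more self-complementary windows, exactly 0 for homopolymers.

static inline bool wc_pair(char x, char y) {
  return (x == 'a' && y == 't') || (x == 't' && y == 'a') ||
         (x == 'c' && y == 'g') || (x == 'g' && y == 'c');
}

// [[Rcpp::export(name = ".nussinov_energy")]]
double nussinov_energy(std::string seq) {
  const int n = (int) seq.size();
  if (n == 0) return 0.0;
  std::vector<int> D((size_t) n * n, 0);
  for (int len = 5; len <= n; ++len) {  // j - i >= 4 allows the first pair
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = D[(size_t) (i + 1) * n + j];           // i unpaired
      for (int k = i + 4; k <= j; ++k) {                // i pairs with k
        if (!wc_pair(seq[(size_t) i], seq[(size_t) k])) continue;
        int inner = (k - i >= 5) ? D[(size_t) (i + 1) * n + (k - 1)] : 0;
        int right = (k < j) ? D[(size_t) (k + 1) * n + j] : 0;
        int cand = 1 + inner + right;
        if (cand > best) best = cand;
      }
      D[(size_t) i * n + j] = best;
    }
  }
  return -(double) D[(size_t) 0 * n + (n - 1)];
}
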