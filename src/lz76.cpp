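#include <Rcpp.h>
using namespace Rcpp;

// Lempel-Ziv 1976 production complexity: number of phrases in the
// exhaustive production history of the sequence.  Each phrase is the
// shortest extension of the parsed prefix that is not reproducible from the
// history (a copy, with overlap allowed, of a substring starting strictly
// before the phrase); the terminal phrase is counted even when it remains
// reproducible.  Kaspar-Schuster style scan, O(n * phrase length) typical.
// [[Rcpp::export(name = ".lz76_phrases")]]
int lz76_phrases(IntegerVector s) {
  const int n = s.size();
  if (n == 0) stop("empty sequence");
  int c = 1;        // first phrase is s[0]
  int l = 1;        // start of the current phrase
  int i = 0;        // candidate copy source
  int k = 1;        // current match length
  int kmax = 1;     // longest reproducible extension seen from any source
  if (n == 1) return 1;
  while (true) {
    if (s[i + k - 1] == s[l + k - 1]) {
      ++k;
      if (l + k > n) {   // ran off the end while still reproducible
        ++c;             // terminal (possibly reproducible) phrase
        break;
      }
    } else {
      if (k > kmax) kmax = k;
      ++i;
      if (i == l) {      // no source reproduces a longer extension
        ++c;
        l += kmax;
        if (l + 1 > n) break;
        i = 0; k = 1; kmax = 1;
      } else {
        k = 1;
      }
    }
  }
  return c;
}
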