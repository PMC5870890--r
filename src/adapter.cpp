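#include <Rcpp.h>
#include <cmath>
#include <cstring>
using namespace Rcpp;

// Leftmost acceptable 3' adapter match per read.
//
// A match at 0-based position p aligns adapter[0:k] with the read, where
// k = min(len(adapter), len(read) - p). It is acceptable when k >= min_overlap
// and the number of substitutions is <= floor(max_error_rate * k). Partial
// matches (k < len(adapter)) necessarily reach the read 3' end. Indels are
// not modeled.
//
// [[Rcpp::export]]
IntegerVector locate_adapter_cpp(CharacterVector seqs, std::string adapter,
                                 double max_error_rate, int min_overlap) {
  const int la = static_cast<int>(adapter.size());
  if (la == 0) stop("adapter must be non-empty");
  if (min_overlap < 1) stop("min_overlap must be >= 1");
  if (max_error_rate < 0 || max_error_rate >= 1)
    stop("max_error_rate must be in [0, 1)");
  const int n = seqs.size();
  IntegerVector out(n, NA_INTEGER);
  for (int i = 0; i < n; ++i) {
    if (seqs[i] == NA_STRING) continue;
    const char *s = CHAR(seqs[i]);
    const int ls = static_cast<int>(std::strlen(s));
    for (int p = 0; p + min_overlap <= ls; ++p) {
      const int k = std::min(la, ls - p);
      const int allowed = static_cast<int>(std::floor(max_error_rate * k));
      int mm = 0;
      bool ok = true;
      for (int j = 0; j < k; ++j) {
        if (s[p + j] != adapter[j] && ++mm > allowed) { ok = false; break; }
      }
      if (ok) { out[i] = p; break; }
    }
  }
  return out;
}
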