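#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>
using namespace Rcpp;

// Hamming-distance-1 pairs among equal-length strings. A single mismatch
// lies in one half, so every Hamming-1 pair agrees exactly on the other
// half: bucket by each half, verify candidates byte-wise with early exit.
// Returns 1-based index pairs.
// [[Rcpp::export(name = ".hamming1_pairs")]]
IntegerMatrix hamming1_pairs(CharacterVector seqs) {
  const int n = seqs.size();
  if (n < 2) return IntegerMatrix(0, 2);
  std::vector<const char*> s(n);
  const int L = LENGTH(STRING_ELT(seqs, 0));
  for (int i = 0; i < n; ++i) {
    s[i] = CHAR(STRING_ELT(seqs, i));
    if (LENGTH(STRING_ELT(seqs, i)) != L)
      stop("sequences must have equal length");
  }
  int h = L / 2;
  if (h < 1) h = 1;
  std::vector<int> pa, pb;
  auto scan = [&](int off, int len) {
    std::unordered_map<std::string, std::vector<int> > buckets;
    buckets.reserve(n * 2);
    for (int i = 0; i < n; ++i)
      buckets[std::string(s[i] + off, len)].push_back(i);
    for (std::unordered_map<std::string,
           std::vector<int> >::iterator it = buckets.begin();
         it != buckets.end(); ++it) {
      const std::vector<int>& v = it->second;
      const int m = v.size();
      if (m < 2) continue;
      for (int a = 0; a < m - 1; ++a)
        for (int b = a + 1; b < m; ++b) {
          int mism = 0;
          const char *x = s[v[a]], *y = s[v[b]];
          for (int p = 0; p < L; ++p) {
            if (x[p] != y[p] && ++mism > 1) break;
          }
          if (mism <= 1) {
            pa.push_back(v[a] + 1);
            pb.push_back(v[b] + 1);
          }
        }
    }
  };
  scan(0, h);
  scan(h, L - h);
  IntegerMatrix out(pa.size(), 2);
  for (int i = 0; i < (int)pa.size(); ++i) {
    out(i, 0) = pa[i];
    out(i, 1) = pb[i];
  }
  return out;
}
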