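#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Greedy abundance-sorted centroid clustering over equal-length sequences.
//
// Sequences must arrive sorted by abundance (descending). Each sequence is
// compared against existing centroids in founding order; it joins the first
// centroid with identity >= threshold (or, with best_hit, the highest-identity
// centroid above threshold, ties to the earliest), otherwise it founds a new
// cluster. Identity is matching positions / length, with 'N' matching
// nothing (including another 'N'). Returns the 1-based founding-sequence
// index of each sequence's cluster.
// [[Rcpp::export(name = ".cpp_greedy_cluster")]]
IntegerVector cpp_greedy_cluster(CharacterVector seqs, double threshold,
                                 bool best_hit) {
  const int n = seqs.size();
  IntegerVector cluster(n);
  if (n == 0) return cluster;
  if (threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]");

  const char* s0 = CHAR(STRING_ELT(seqs, 0));
  const int L = LENGTH(STRING_ELT(seqs, 0));
  (void)s0;
  for (int i = 1; i < n; ++i)
    if (LENGTH(STRING_ELT(seqs, i)) != L)
      stop("all sequences must have equal length");

  // identity >= threshold  <=>  mismatches <= L - ceil(threshold * L)
  const int allowed = L - (int)std::ceil(threshold * (double)L - 1e-9);

  std::vector<int> centroid_idx;  // founding sequence index per cluster
  centroid_idx.reserve(1024);

  for (int i = 0; i < n; ++i) {
    const char* a = CHAR(STRING_ELT(seqs, i));
    int hit = -1;
    int best_mm = allowed + 1;
    for (size_t c = 0; c < centroid_idx.size(); ++c) {
      const char* b = CHAR(STRING_ELT(seqs, centroid_idx[c]));
      // early exit once mismatches exceed what could still win
      const int limit = best_hit ? best_mm - 1 : allowed;
      int mm = 0;
      for (int j = 0; j < L; ++j) {
        if (a[j] != b[j] || a[j] == 'N') {
          if (++mm > limit) break;
        }
      }
      if (mm <= limit) {
        hit = centroid_idx[c];
        if (!best_hit) break;
        best_mm = mm;
        if (best_mm == 0) break;
      }
    }
    if (hit < 0) {
      centroid_idx.push_back(i);
      cluster[i] = i + 1;
    } else {
      cluster[i] = hit + 1;
    }
  }
  return cluster;
}
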