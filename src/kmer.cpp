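#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>

using namespace Rcpp;

// Exact canonical k-mer depth histogram. Each k-mer (k <= 31) is packed
// into a 62-bit code (A=0, C=1, G=2, T=3); the canonical form is the
// smaller of the code and its reverse complement. Windows containing any
// non-ACGT character are skipped. Returns a two-column data frame
// (depth, count): count[d] = number of distinct canonical k-mers seen
// exactly d times.

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// [[Rcpp::export]]
DataFrame count_kmers_cpp(CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("k must be in 1..31");
  if (k % 2 == 0) stop("k must be odd (canonical form is ill-defined for even k)");

  const uint64_t mask = (k == 31) ? ((1ULL << 62) - 1) : ((1ULL << (2 * k)) - 1);
  const int shift = 2 * (k - 1);
  std::unordered_map<uint64_t, uint64_t> counts;
  counts.reserve(1 << 20);

  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    const char *p = CHAR(STRING_ELT(seqs, s));
    int len = LENGTH(STRING_ELT(seqs, s));
    uint64_t fwd = 0, rev = 0;
    int filled = 0;  // valid bases currently in the rolling window
    for (int i = 0; i < len; ++i) {
      int c = base_code(p[i]);
      if (c < 0) { filled = 0; fwd = 0; rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)c) & mask;
      rev = (rev >> 2) | ((uint64_t)(3 - c) << shift);
      if (++filled >= k) {
        uint64_t canon = fwd < rev ? fwd : rev;
        ++counts[canon];
      }
    }
  }

  std::unordered_map<uint64_t, uint64_t> hist;
  for (const auto &kv : counts) ++hist[kv.second];

  std::vector<double> depth, cnt;
  depth.reserve(hist.size());
  cnt.reserve(hist.size());
  for (const auto &kv : hist) {
    depth.push_back((double)kv.first);
    cnt.push_back((double)kv.second);
  }
  // sort by depth
  std::vector<size_t> idx(depth.size());
  for (size_t i = 0; i < idx.size(); ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(),
            [&](size_t a, size_t b) { return depth[a] < depth[b]; });
  NumericVector d(idx.size()), n(idx.size());
  for (size_t i = 0; i < idx.size(); ++i) { d[i] = depth[idx[i]]; n[i] = cnt[idx[i]]; }
  return DataFrame::create(_["depth"] = d, _["count"] = n);
}
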