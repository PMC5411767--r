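#pragma once

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>

// 64-bit avalanche mix (splitmix64 finalizer); used as the fixed base hash so
// a k-mer indexes identically everywhere regardless of its tf-idf weight.
static inline uint64_t sx_mix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline uint64_t sx_xorshift64(uint64_t x) {
  // xorshift64* : the multiplicative step breaks the GF(2)-linearity of the
  // plain xorshift, which otherwise correlates draw streams across k-mers
  x ^= x << 13;
  x ^= x >> 7;
  x ^= x << 17;
  return x * 0x2545F4914F6CDD1DULL;
}

// Fixed constant seed for the base hash: k-mer identity must be stable across
// reads, sketches and spectra.  Per-sketch randomness enters only through the
// per-slot xorshift streams.
static const uint64_t SX_BASE_SEED = 0x5D1E9F2B7C4A6E38ULL;
// Base hashes are truncated to 53 bits so they are exactly representable as
// R doubles (R has no 64-bit integer type).
static const uint64_t SX_MASK53 = ((uint64_t)1 << 53) - 1;

static inline int sx_base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// Iterate canonical k-mer base hashes with 0-based start positions.
template <class F>
inline void sx_each_kmer(const std::string& seq, int k, F f) {
  const int n = (int)seq.size();
  if (n < k) return;
  const uint64_t mask = (k >= 32) ? ~(uint64_t)0 : (((uint64_t)1 << (2 * k)) - 1);
  const int shift = 2 * (k - 1);
  uint64_t fwd = 0, rc = 0;
  int run = 0;
  for (int i = 0; i < n; ++i) {
    int c = sx_base_code(seq[i]);
    if (c < 0) { run = 0; fwd = 0; rc = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rc = (rc >> 2) | ((uint64_t)(3 - c) << shift);
    if (++run >= k) {
      uint64_t canon = fwd < rc ? fwd : rc;
      uint64_t h = sx_mix64(canon ^ SX_BASE_SEED) & SX_MASK53;
      f(h, i + 1 - k);
    }
  }
}

inline std::string sx_revcomp(const std::string& s) {
  std::string r(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) {
    char c = s[s.size() - 1 - i];
    switch (c) {
    case 'A': case 'a': r[i] = 'T'; break;
    case 'C': case 'c': r[i] = 'G'; break;
    case 'G': case 'g': r[i] = 'C'; break;
    case 'T': case 't': r[i] = 'A'; break;
    default: r[i] = 'N';
    }
  }
  return r;
}

// Alignment ops (a = rows, b = columns):
//   1 = match, 2 = mismatch, 3 = insertion in b (consumes b), 4 = deletion (consumes a)
enum { SX_OP_M = 1, SX_OP_X = 2, SX_OP_I = 3, SX_OP_D = 4 };

struct OvAln {
  bool ok = false;
  int ia0 = 0, ia1 = 0, ja0 = 0, ja1 = 0;  // half-open aligned ranges in a and b
  int nmatch = 0, nsub = 0, nins = 0, ndel = 0;
  long score = 0;
  std::vector<uint8_t> ops;  // from (ia0, ja0) to (ia1, ja1), values SX_OP_*
};

// Banded overlap alignment (free leading/trailing gaps in both sequences),
// band centred on diagonal j - i = d0 with half-width `band`.
OvAln sx_ov_align(const std::string& a, const std::string& b, int d0, int band,
                  bool need_ops);

// Banded bit-parallel Levenshtein alignment: all of `a` vs a substring of
// `b` (free begin/end along b), band half-width B around offset d0.
struct BpAln {
  bool ok = false;
  int dist = 0;
  int ja0 = 0, ja1 = 0;  // aligned range in b; the whole of a is aligned
  int nmatch = 0, nsub = 0, nins = 0, ndel = 0;
  std::vector<uint8_t> ops;
};
BpAln sx_bp_align(const std::string& a, const std::string& b, int d0, int B,
                  bool need_ops);
// strip noisy terminal columns up to the first `anchor`-long match run
void sx_trim_ops(std::vector<uint8_t>& ops, int anchor, int* a_lead,
                 int* b_lead, int* a_tail, int* b_tail);

// band half-width for the bit-parallel aligner: static diagonal band wide
// enough for the offset-hint slack plus six s.d. of net indel drift
static inline int sx_band_bp(double err, int ovl_len) {
  if (err < 0) err = 0;
  if (err > 0.9) err = 0.9;
  double L = (double)(ovl_len > 0 ? ovl_len : 1);
  return 48 + (int)std::ceil(6.0 * std::sqrt(0.7 * err * L)) + (int)(0.002 * L);
}

// Band half-width from an expected error rate.  The aligner re-centres its
// band adaptively (drift is tracked row by row), so the band only needs to
// cover the offset-estimate slack plus local deviations, which grow with
// the error rate.
static inline int sx_band_for(double err, int ovl_len, int min_band, int max_band) {
  if (err < 0) err = 0;
  if (err > 0.9) err = 0.9;
  int b = 40 + (int)(130.0 * err) + (int)(0.002 * (double)(ovl_len > 0 ? ovl_len : 1));
  if (b < min_band) b = min_band;
  if (b > max_band) b = max_band;
  return b;
}
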