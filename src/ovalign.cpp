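#include "sketchasm.h"
#include <algorithm>
#include <cstring>

// Banded overlap alignment with an adaptively re-centred band.
//
// Scores: match +1, mismatch -2, gap -2 (int16 with a saturating floor).
// The band follows the best-scoring diagonal row by row (shift limited to
// one column per row), so a modest half-width tracks the indel drift of
// noisy long-read alignments without paying for a worst-case static band.
// Free end gaps in both sequences: the alignment may start on the top row
// or left column and end on the bottom row or right column.

static const int16_t SXO_NEG = -20000;
static const int16_t SXO_MATCH = 1, SXO_MISM = -2, SXO_GAP = -2;

OvAln sx_ov_align(const std::string& a, const std::string& b, int d0, int band,
                  bool need_ops) {
  OvAln res;
  const int m = (int)a.size(), n = (int)b.size();
  if (m == 0 || n == 0) return res;
  if (band < 16) band = 16;
  const int W = 2 * band + 1;

  // sentinel margin of 2 on each side covers the per-row band shift
  std::vector<int16_t> prevv((size_t)W + 4, SXO_NEG), curv((size_t)W + 4, SXO_NEG);
  int16_t* prev = prevv.data() + 2;
  int16_t* cur = curv.data() + 2;
  std::vector<uint8_t> tr;
  std::vector<int> row_lo((size_t)m + 1, 0);
  if (need_ops) tr.assign((size_t)(m + 1) * W, 0);

  long bscore = -1;
  int bi = -1, bj = -1;

  int center = d0;  // expected diagonal offset: j ~ i + center
  {
    int lo = std::max(0, d0 - band);
    int hi = std::min(n, d0 + band);
    row_lo[0] = d0 - band;
    for (int j = lo; j <= hi; ++j) prev[j - row_lo[0]] = 0;
  }
  int prev_lo = row_lo[0];

  for (int i = 1; i <= m; ++i) {
    const int lo_raw = i + center - band;
    const int jlo = std::max(0, lo_raw);
    const int jhi = std::min(n, i + center + band);
    row_lo[i] = lo_raw;
    if (lo_raw > n) break;  // band moved past the end of b
    std::fill(curv.begin(), curv.end(), SXO_NEG);
    if (jlo > jhi) {        // band not yet inside b; keep advancing rows
      prev_lo = lo_raw;
      std::swap(prevv, curv);
      prev = prevv.data() + 2;
      cur = curv.data() + 2;
      continue;
    }
    uint8_t* trow = need_ops ? &tr[(size_t)i * W] : nullptr;
    const char ai = a[i - 1];
    const int shift = lo_raw - prev_lo;  // in {0, 1, 2}

    int16_t rowbest = SXO_NEG;
    int rowarg = jlo;
    int j = jlo;
    if (j == 0) {  // free start along a
      int id0 = -lo_raw;
      int pid = id0 + shift;
      int16_t up = (int16_t)(prev[pid] + SXO_GAP);
      int16_t best = 0;
      uint8_t op = 0;
      if (up > best) { best = up; op = SX_OP_D; }
      cur[id0] = best;
      if (trow) trow[id0] = op;
      if (best > rowbest) { rowbest = best; rowarg = 0; }
      j = 1;
    }
    const int16_t* prs = prev + shift;
    const char* bp = b.data();
    int16_t carry = cur[j - 1 - lo_raw];  // running left neighbour
    if (need_ops) {
      for (; j <= jhi; ++j) {
        const int id = j - lo_raw;
        const bool eq = (ai == bp[j - 1]);
        const int16_t diag = (int16_t)(prs[id - 1] + (eq ? SXO_MATCH : SXO_MISM));
        const int16_t up = (int16_t)(prs[id] + SXO_GAP);
        const int16_t left = (int16_t)(carry + SXO_GAP);
        int16_t best = diag;
        uint8_t op = eq ? SX_OP_M : SX_OP_X;
        if (up > best) { best = up; op = SX_OP_D; }
        if (left > best) { best = left; op = SX_OP_I; }
        if (best < SXO_NEG) { best = SXO_NEG; op = 0; }
        cur[id] = best;
        carry = best;
        trow[id] = op;
        if (best > rowbest) { rowbest = best; rowarg = j; }
      }
    } else {
      for (; j <= jhi; ++j) {
        const int id = j - lo_raw;
        const int16_t diag =
            (int16_t)(prs[id - 1] + ((ai == bp[j - 1]) ? SXO_MATCH : SXO_MISM));
        const int16_t up = (int16_t)(prs[id] + SXO_GAP);
        const int16_t left = (int16_t)(carry + SXO_GAP);
        int16_t best = diag > up ? diag : up;
        if (left > best) best = left;
        if (best < SXO_NEG) best = SXO_NEG;
        cur[id] = best;
        carry = best;
        if (best > rowbest) { rowbest = best; rowarg = j; }
      }
    }
    // end-of-alignment candidates
    if (i == m) {
      for (int jj = jlo; jj <= jhi; ++jj) {
        int16_t v = cur[jj - lo_raw];
        if (v > 0 && (long)v > bscore) { bscore = v; bi = i; bj = jj; }
      }
    } else if (jhi == n) {
      int16_t v = cur[n - lo_raw];
      if (v > 0 && (long)v > bscore) { bscore = v; bi = i; bj = n; }
    }
    // adaptive recentring toward the best diagonal, one column per row
    int want = rowarg - i;
    center += (want > center) ? 1 : (want < center ? -1 : 0);
    prev_lo = lo_raw;
    std::swap(prevv, curv);
    prev = prevv.data() + 2;
    cur = curv.data() + 2;
  }
  if (bi < 0 || bscore <= 0) return res;

  res.ok = true;
  res.score = bscore;
  res.ia1 = bi;
  res.ja1 = bj;
  if (need_ops) {
    std::vector<uint8_t> ops;
    int i = bi, j = bj;
    while (i > 0) {
      int id = j - row_lo[i];
      if (id < 0 || id >= W) break;
      uint8_t op = tr[(size_t)i * W + id];
      if (op == 0) break;
      ops.push_back(op);
      switch (op) {
      case SX_OP_M: res.nmatch++; --i; --j; break;
      case SX_OP_X: res.nsub++; --i; --j; break;
      case SX_OP_D: res.ndel++; --i; break;
      case SX_OP_I: res.nins++; --j; break;
      }
    }
    res.ia0 = i;
    res.ja0 = j;
    std::reverse(ops.begin(), ops.end());
    res.ops = std::move(ops);
  } else {
    res.ia0 = 0;
    res.ja0 = 0;
  }
  return res;
}
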