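#include "sketchasm.h"
#include <algorithm>
#include <cstring>

// Banded bit-parallel Levenshtein alignment (Myers' algorithm in Hyyro's
// banded form).  Aligns ALL of `a` against a substring of `b` (free begin
// and end along b), with a diagonal band of half-width B around the
// expected offset d0 (j ~ i + d0).  The per-row state is held in bit
// vectors (VP/VN: in-row deltas along b; HP/HN: between-row deltas), so
// each DP cell costs a fraction of an instruction.  Rows are stored for a
// deterministic traceback.  Used wherever the overlap extent is already
// known approximately (correction evidence, voting, error re-estimation,
// and the fast path of overlap confirmation); the scored free-end aligner
// remains for extent discovery.

static inline int bp_code(char c) { return sx_base_code(c); }

BpAln sx_bp_align(const std::string& a, const std::string& b, int d0, int B,
                  bool need_ops) {
  BpAln res;
  const int m = (int)a.size(), n = (int)b.size();
  if (m == 0 || n == 0) return res;
  if (B < 32) B = 32;
  const int w = (2 * B + 64) / 64;  // words per state
  const int Wb = 64 * w;            // window width in bits

  // window of row i covers b columns [lo + i, lo + i + Wb)
  const int lo0 = d0 - B;

  std::vector<uint64_t> eq(4 * w, 0);  // match masks over current window
  std::vector<uint64_t> VP(w, 0), VN(w, 0), HP(w, 0), HN(w, 0);
  std::vector<uint64_t> X(w), D0(w);
  // stored rows (VP,VN,HP,HN) for traceback
  std::vector<uint64_t> store;
  if (need_ops) store.assign((size_t)(m + 1) * 4 * w, 0);

  auto set_eq_bit = [&](int t, int p) {
    if (p >= 0 && p < n) {
      int c = bp_code(b[p]);
      if (c >= 0) eq[(size_t)c * w + t / 64] |= (uint64_t)1 << (t % 64);
    }
  };
  for (int t = 0; t < Wb; ++t) set_eq_bit(t, lo0 + t);

  // row 0: D(0, j) = 0 for j >= 0 (free begin along b); wall left of b
  for (int t = 0; t < Wb; ++t) {
    int p = lo0 + t;
    if (p < 0) VN[t / 64] |= (uint64_t)1 << (t % 64);
  }
  long dtop = 0;  // D(i, lo + i + Wb)
  {
    // D(0, hi) with hi = lo0 + Wb: 0 if hi >= 0 else distance to 0
    int hi = lo0 + Wb;
    dtop = (hi >= 0) ? 0 : -hi;
  }
  if (need_ops) {
    std::memcpy(&store[0], VP.data(), w * 8);
    std::memcpy(&store[w], VN.data(), w * 8);
  }

  std::vector<long> dtop_row((size_t)m + 1, 0);
  dtop_row[0] = dtop;

  for (int i = 1; i <= m; ++i) {
    // shift window one column right: drop low bit, new top column enters
    auto shr1 = [&](std::vector<uint64_t>& v) {
      for (int k = 0; k < w; ++k) {
        uint64_t hibit = (k + 1 < w) ? (v[k + 1] & 1) : 0;
        v[k] = (v[k] >> 1) | (hibit << 63);
      }
    };
    for (int c = 0; c < 4; ++c) {
      for (int k = 0; k < w; ++k) {
        uint64_t hibit = (k + 1 < w) ? (eq[(size_t)c * w + k + 1] & 1) : 0;
        eq[(size_t)c * w + k] = (eq[(size_t)c * w + k] >> 1) | (hibit << 63);
      }
      eq[(size_t)c * w + w - 1] &= ~((uint64_t)1 << 63);
    }
    shr1(VP);
    shr1(VN);
    const int lo = lo0 + i;             // window left column this row
    set_eq_bit(Wb - 1, lo + Wb - 1);    // new top column match bits
    VP[w - 1] |= (uint64_t)1 << 63;     // wall: D grows rightward past band
    dtop += 1;                          // D(i-1, new top) = old top + 1

    // Myers step for character a[i-1]
    int ci = bp_code(a[i - 1]);
    const uint64_t* eqv = (ci >= 0) ? &eq[(size_t)ci * w] : nullptr;
    uint64_t carry_add = 0, carry_hp = 1, carry_hn = 0;  // wall left of band
    for (int k = 0; k < w; ++k) {
      uint64_t Eq = eqv ? eqv[k] : 0;
      X[k] = Eq | VN[k];
      unsigned __int128 sum = (unsigned __int128)VP[k] + (X[k] & VP[k]) + carry_add;
      uint64_t s = (uint64_t)sum;
      carry_add = (uint64_t)(sum >> 64);
      D0[k] = (s ^ VP[k]) | X[k];
      HN[k] = VP[k] & D0[k];
      HP[k] = VN[k] | ~(VP[k] | D0[k]);
    }
    uint64_t ch = carry_hp, cn = carry_hn;
    for (int k = 0; k < w; ++k) {
      uint64_t hp_s = (HP[k] << 1) | ch;
      uint64_t hn_s = (HN[k] << 1) | cn;
      ch = HP[k] >> 63;
      cn = HN[k] >> 63;
      VN[k] = hp_s & D0[k];
      VP[k] = hn_s | ~(hp_s | D0[k]);
    }
    // score at window top
    uint64_t top = (uint64_t)1 << 63;
    if (HP[w - 1] & top) dtop += 1;
    else if (HN[w - 1] & top) dtop -= 1;
    dtop_row[i] = dtop;
    if (need_ops) {
      uint64_t* dst = &store[(size_t)i * 4 * w];
      std::memcpy(dst, VP.data(), w * 8);
      std::memcpy(dst + w, VN.data(), w * 8);
      std::memcpy(dst + 2 * w, HP.data(), w * 8);
      std::memcpy(dst + 3 * w, HN.data(), w * 8);
    }
  }

  // walk the last row leftward to find min D over j in [0, n]
  const int lom = lo0 + m;
  int hi = lom + Wb;
  long d = dtop;
  int best_j = -1;
  long best_d = -1;
  {
    int jmax = std::min(n, hi);
    int jmin = std::max(0, lom + 1);
    // bring d from hi down to jmax
    int j = hi;
    auto vdelta = [&](int jj) -> int {
      int t = jj - 1 - lom;
      if (t < 0 || t >= Wb) return 1;
      uint64_t bit = (uint64_t)1 << (t % 64);
      if (VP[t / 64] & bit) return 1;
      if (VN[t / 64] & bit) return -1;
      return 0;
    };
    while (j > jmax) { d -= vdelta(j); --j; }
    for (; j >= jmin; --j) {
      if (best_d < 0 || d < best_d) { best_d = d; best_j = j; }
      d -= vdelta(j);
    }
  }
  if (best_j < 0) return res;
  res.dist = (int)best_d;
  res.ja1 = best_j;
  res.ok = true;
  if (!need_ops) {
    res.ja0 = std::max(0, best_j - m);  // approximate
    return res;
  }

  // traceback over stored rows
  auto bit_of = [&](const uint64_t* words, int t) -> bool {
    return (words[t / 64] >> (t % 64)) & 1;
  };
  auto delta3 = [&](const uint64_t* P, const uint64_t* N, int t) -> int {
    if (t < 0 || t >= Wb) return 1;
    if (bit_of(P, t)) return 1;
    if (bit_of(N, t)) return -1;
    return 0;
  };
  std::vector<uint8_t> ops;
  ops.reserve(m + 64);
  int i = m, j = best_j;
  long D = best_d;
  bool fail = false;
  while (i > 0) {
    const int lo_i = lo0 + i;
    const uint64_t* VPi = &store[(size_t)i * 4 * w];
    const uint64_t* VNi = VPi + w;
    const uint64_t* HPi = VPi + 2 * w;
    const uint64_t* HNi = VPi + 3 * w;
    const uint64_t* VPp = &store[(size_t)(i - 1) * 4 * w];
    const uint64_t* VNp = VPp + w;
    int tH = j - 1 - lo_i;  // H(i,j) stored at pattern bit j-1-lo_i
    int tV = j - 1 - lo_i;
    if (j > 0 && (tH < -1 || tH >= Wb)) { fail = true; break; }
    int Hij = (j >= 1) ? ((tH >= 0 && tH < Wb) ? (bit_of(HPi, tH) ? 1 : (bit_of(HNi, tH) ? -1 : 0)) : 1) : 1;
    // candidates
    bool did = false;
    if (i >= 1 && j >= 1) {
      long Dup = D - Hij;
      // V(i-1, j) = D(i-1, j) - D(i-1, j-1), stored at bit j-1-lo_{i-1}
      long Ddiag = Dup - delta3(VPp, VNp, j - 1 - (lo0 + i - 1));
      bool match = (j <= n) && (bp_code(a[i - 1]) >= 0) && (j - 1 < n) &&
                   (a[i - 1] == b[j - 1]);
      int cost = match ? 0 : 1;
      if (Ddiag + cost == D) {
        ops.push_back(match ? SX_OP_M : SX_OP_X);
        if (match) res.nmatch++; else res.nsub++;
        --i; --j; D = Ddiag;
        did = true;
      }
    }
    if (!did && Hij == 1) {  // from (i-1, j): consume a
      ops.push_back(SX_OP_D);
      res.ndel++;
      --i; D = D - 1;
      did = true;
    }
    if (!did && j >= 1) {
      int v = delta3(VPi, VNi, tV);
      if (v == 1) {  // from (i, j-1): consume b
        ops.push_back(SX_OP_I);
        res.nins++;
        --j; D = D - 1;
        did = true;
      }
    }
    if (!did) { fail = true; break; }
  }
  if (fail || D != 0) {
    res.ok = false;
    return res;
  }
  res.ja0 = j;
  std::reverse(ops.begin(), ops.end());
  res.ops = std::move(ops);
  return res;
}

// Strip noisy terminal columns (from imprecise extent hints): trim each end
// up to the first run of `anchor` consecutive matches.
void sx_trim_ops(std::vector<uint8_t>& ops, int anchor, int* a_lead,
                 int* b_lead, int* a_tail, int* b_tail) {
  *a_lead = *b_lead = *a_tail = *b_tail = 0;
  auto consume = [&](uint8_t op, int* da, int* db) {
    switch (op) {
    case SX_OP_M: case SX_OP_X: ++*da; ++*db; break;
    case SX_OP_D: ++*da; break;
    case SX_OP_I: ++*db; break;
    }
  };
  int run = 0, cut_f = -1;
  for (int i = 0; i < (int)ops.size(); ++i) {
    if (ops[i] == SX_OP_M) { if (++run >= anchor) { cut_f = i + 1 - run; break; } }
    else run = 0;
  }
  if (cut_f < 0) return;  // no anchor: keep everything
  run = 0;
  int cut_b = (int)ops.size();
  for (int i = (int)ops.size() - 1; i >= cut_f; --i) {
    if (ops[i] == SX_OP_M) { if (++run >= anchor) { cut_b = i + run; break; } }
    else run = 0;
  }
  if (cut_b > (int)ops.size()) cut_b = (int)ops.size();
  if (cut_f == 0 && cut_b == (int)ops.size()) return;
  for (int i = 0; i < cut_f; ++i) consume(ops[i], a_lead, b_lead);
  for (int i = cut_b; i < (int)ops.size(); ++i) consume(ops[i], a_tail, b_tail);
  std::vector<uint8_t> kept(ops.begin() + cut_f, ops.begin() + cut_b);
  ops.swap(kept);
}

// [[Rcpp::export]]
Rcpp::List bp_align_cpp(std::string a, std::string b, int d0, int band) {
  BpAln al = sx_bp_align(a, b, d0, band, true);
  return Rcpp::List::create(
      Rcpp::_["ok"] = al.ok, Rcpp::_["dist"] = al.dist,
      Rcpp::_["b_start"] = al.ja0, Rcpp::_["b_end"] = al.ja1,
      Rcpp::_["nmatch"] = al.nmatch, Rcpp::_["nsub"] = al.nsub,
      Rcpp::_["nins"] = al.nins, Rcpp::_["ndel"] = al.ndel,
      Rcpp::_["nops"] = (int)al.ops.size());
}

// [[Rcpp::export]]
Rcpp::List bp_ops_cpp(std::string a, std::string b, int d0, int band) {
  BpAln al = sx_bp_align(a, b, d0, band, true);
  Rcpp::IntegerVector ops((R_xlen_t)al.ops.size());
  for (R_xlen_t i = 0; i < (R_xlen_t)al.ops.size(); ++i) ops[i] = al.ops[i];
  return Rcpp::List::create(Rcpp::_["ok"] = al.ok, Rcpp::_["dist"] = al.dist,
                            Rcpp::_["b_start"] = al.ja0,
                            Rcpp::_["b_end"] = al.ja1, Rcpp::_["ops"] = ops);
}
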