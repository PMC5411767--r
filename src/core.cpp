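#include "sketchasm.h"
#include <unordered_map>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// k-mer spectrum
// ---------------------------------------------------------------------------

// Count canonical k-mers across all reads; record only the most abundant
// fraction of distinct k-mers (ties at the cutoff count are all kept, so the
// recorded set is deterministic).
// [[Rcpp::export]]
List count_kmers_cpp(CharacterVector reads, int k, double cutoff_frac) {
  std::unordered_map<uint64_t, int> counts;
  counts.reserve(1 << 20);
  double total = 0.0;
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    std::string s = as<std::string>(reads[r]);
    sx_each_kmer(s, k, [&](uint64_t h, int) {
      ++counts[h];
      total += 1.0;
    });
  }
  const double n_distinct = (double)counts.size();
  int f_max = 0, f_min = 0;
  for (auto& kv : counts) {
    if (kv.second > f_max) f_max = kv.second;
    if (f_min == 0 || kv.second < f_min) f_min = kv.second;
  }
  R_xlen_t n_rec = 0;
  if (cutoff_frac > 0 && n_distinct > 0)
    n_rec = (R_xlen_t)std::ceil(cutoff_frac * n_distinct);
  if (n_rec > (R_xlen_t)counts.size()) n_rec = (R_xlen_t)counts.size();

  int f_cut = f_max;
  std::vector<std::pair<uint64_t, int> > rec;
  if (n_rec > 0) {
    std::vector<int> cnt;
    cnt.reserve(counts.size());
    for (auto& kv : counts) cnt.push_back(kv.second);
    std::nth_element(cnt.begin(), cnt.begin() + (n_rec - 1), cnt.end(),
                     std::greater<int>());
    f_cut = cnt[n_rec - 1];
    for (auto& kv : counts)
      if (kv.second >= f_cut) rec.push_back(kv);
    std::sort(rec.begin(), rec.end());
  }
  NumericVector hash((R_xlen_t)rec.size());
  IntegerVector count((R_xlen_t)rec.size());
  for (R_xlen_t i = 0; i < (R_xlen_t)rec.size(); ++i) {
    hash[i] = (double)rec[i].first;
    count[i] = rec[i].second;
  }
  return List::create(_["hash"] = hash, _["count"] = count,
                      _["f_max"] = f_max, _["f_min"] = std::max(f_min, 1),
                      _["f_cut"] = f_cut, _["n_distinct"] = n_distinct,
                      _["total"] = total);
}

// idf weight for a frequency f_q given spectrum endpoints.  lo corresponds to
// f_q = f_max (weight 1); hi to the filter cutoff (weight idf_max); values are
// linearly rescaled onto [1, idf_max] and rounded half-up.
static inline int sx_idf_one(double f_q, double f_max, double a, int idf_max,
                             double lo, double hi) {
  if (!(hi > lo)) return 1;  // degenerate range: recorded k-mers sit at f_max
  double arg = f_max / f_q - a;
  double x = (arg <= 0) ? lo : std::log(arg);
  if (x < lo) x = lo;
  if (x > hi) x = hi;
  int w = (int)std::floor(1.0 + (idf_max - 1) * (x - lo) / (hi - lo) + 0.5);
  if (w < 1) w = 1;
  if (w > idf_max) w = idf_max;
  return w;
}

static inline void sx_idf_range(double f_max, double f_at_cut, double a,
                                double* lo, double* hi) {
  *lo = std::log(1.0 - a);
  double arg = (f_at_cut > 0) ? (f_max / f_at_cut - a) : -1.0;
  *hi = (arg > 0) ? std::log(arg) : *lo;
}

// Look up recorded count by binary search; -1 if not recorded.
static inline int sx_rec_count(uint64_t h, const double* rh, const int* rc,
                               R_xlen_t n) {
  R_xlen_t lo = 0, hi = n;
  double hd = (double)h;
  while (lo < hi) {
    R_xlen_t mid = (lo + hi) / 2;
    if (rh[mid] < hd) lo = mid + 1; else hi = mid;
  }
  if (lo < n && rh[lo] == hd) return rc[lo];
  return -1;
}

// [[Rcpp::export]]
IntegerVector idf_weights_cpp(NumericVector q, NumericVector rec_hash,
                              IntegerVector rec_count, double f_max,
                              double f_cut, double total, double a,
                              int idf_max, int cutoff_as, double cutoff_frac) {
  double f_at_cut = (cutoff_as == 0) ? f_cut
                                     : std::max(1.0, cutoff_frac * total);
  double lo, hi;
  sx_idf_range(f_max, f_at_cut, a, &lo, &hi);
  const double* rh = rec_hash.begin();
  const int* rc = rec_count.begin();
  R_xlen_t nr = rec_hash.size();
  IntegerVector out(q.size());
  for (R_xlen_t i = 0; i < q.size(); ++i) {
    int f = sx_rec_count((uint64_t)q[i], rh, rc, nr);
    out[i] = (f < 0) ? idf_max : sx_idf_one((double)f, f_max, a, idf_max, lo, hi);
  }
  return out;
}

// ---------------------------------------------------------------------------
// weighted MinHash sketches
// ---------------------------------------------------------------------------

// filter_mode: 0 = tf-idf weighting; 1 = all-or-nothing count threshold
// (k-mers with recorded count > max_count are excluded, all others weight 1).
// [[Rcpp::export]]
NumericMatrix build_sketches_cpp(CharacterVector reads, int k, int s,
                                 NumericVector rec_hash, IntegerVector rec_count,
                                 double f_max, double f_cut, double total,
                                 double a, int idf_max, int tf_cap,
                                 int cutoff_as, double cutoff_frac, int seed,
                                 int filter_mode, double max_count) {
  const R_xlen_t n = reads.size();
  NumericMatrix out(s, n);
  std::fill(out.begin(), out.end(), NA_REAL);
  double f_at_cut = (cutoff_as == 0) ? f_cut
                                     : std::max(1.0, cutoff_frac * total);
  double lo, hi;
  sx_idf_range(f_max, f_at_cut, a, &lo, &hi);
  const double* rh = rec_hash.begin();
  const int* rcnt = rec_count.begin();
  R_xlen_t nr = rec_hash.size();

  // Per-slot stream constants: the seed is mixed before the slot index is
  // added so different seeds yield disjoint constant streams.
  std::vector<uint64_t> slot_const(s);
  const uint64_t seed_mix = sx_mix64((uint64_t)(uint32_t)seed + 0x9E37u);
  for (int i = 0; i < s; ++i)
    slot_const[i] = sx_mix64(seed_mix + (uint64_t)i);

  std::vector<uint64_t> best(s), arg(s);
  std::unordered_map<uint64_t, int> tf;

  for (R_xlen_t r = 0; r < n; ++r) {
    std::string sq = as<std::string>(reads[r]);
    tf.clear();
    sx_each_kmer(sq, k, [&](uint64_t h, int) { ++tf[h]; });
    if (tf.empty()) continue;
    std::fill(best.begin(), best.end(), ~(uint64_t)0);
    std::fill(arg.begin(), arg.end(), ~(uint64_t)0);
    for (auto& kv : tf) {
      const uint64_t h = kv.first;
      int w;
      if (filter_mode == 1) {
        int f = sx_rec_count(h, rh, rcnt, nr);
        if (f > max_count) continue;  // hard-filtered repetitive k-mer
        w = 1;
      } else {
        int f = sx_rec_count(h, rh, rcnt, nr);
        int idf = (f < 0) ? idf_max
                          : sx_idf_one((double)f, f_max, a, idf_max, lo, hi);
        int tfv = kv.second > tf_cap ? tf_cap : kv.second;
        w = tfv * idf;
      }
      // four interleaved slot streams keep the dependent xorshift chains
      // from serialising the loop
      uint64_t* bb = best.data();
      uint64_t* aa = arg.data();
      const uint64_t* cc = slot_const.data();
      int i = 0;
      for (; i + 3 < s; i += 4) {
        uint64_t s0 = h ^ cc[i], s1 = h ^ cc[i + 1];
        uint64_t s2 = h ^ cc[i + 2], s3 = h ^ cc[i + 3];
        uint64_t m0 = bb[i], m1 = bb[i + 1], m2 = bb[i + 2], m3 = bb[i + 3];
        for (int j = 0; j < w; ++j) {
          s0 = sx_xorshift64(s0); s1 = sx_xorshift64(s1);
          s2 = sx_xorshift64(s2); s3 = sx_xorshift64(s3);
          if (s0 < m0) { m0 = s0; aa[i] = h; }
          if (s1 < m1) { m1 = s1; aa[i + 1] = h; }
          if (s2 < m2) { m2 = s2; aa[i + 2] = h; }
          if (s3 < m3) { m3 = s3; aa[i + 3] = h; }
        }
        bb[i] = m0; bb[i + 1] = m1; bb[i + 2] = m2; bb[i + 3] = m3;
      }
      for (; i < s; ++i) {
        uint64_t st = h ^ cc[i];
        uint64_t bi = bb[i];
        for (int j = 0; j < w; ++j) {
          st = sx_xorshift64(st);
          if (st < bi) { bi = st; aa[i] = h; }
        }
        bb[i] = bi;
      }
    }
    for (int i = 0; i < s; ++i)
      out(i, r) = (arg[i] == ~(uint64_t)0) ? NA_REAL : (double)arg[i];
  }
  return out;
}

// ---------------------------------------------------------------------------
// bottom sketches
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List bottom_sketches_cpp(CharacterVector reads, int k, int size) {
  const R_xlen_t n = reads.size();
  List out(n);
  for (R_xlen_t r = 0; r < n; ++r) {
    std::string sq = as<std::string>(reads[r]);
    // first and last occurrence per k-mer (the last position exposes
    // within-read duplications such as hairpin mirrors)
    std::unordered_map<uint64_t, std::pair<int, int> > occ;
    occ.reserve(2 * sq.size() + 16);
    sx_each_kmer(sq, k, [&](uint64_t h, int pos) {
      auto it = occ.find(h);
      if (it == occ.end()) occ.emplace(h, std::make_pair(pos, pos));
      else it->second.second = pos;
    });
    std::vector<std::pair<uint64_t, std::pair<int, int> > > v(occ.begin(), occ.end());
    if ((int)v.size() > size) {
      std::nth_element(v.begin(), v.begin() + size, v.end());
      v.resize(size);
    }
    std::sort(v.begin(), v.end());
    NumericVector val((R_xlen_t)v.size());
    IntegerVector pos((R_xlen_t)v.size());
    IntegerVector pos2((R_xlen_t)v.size());
    for (R_xlen_t i = 0; i < (R_xlen_t)v.size(); ++i) {
      val[i] = (double)v[i].first;
      pos[i] = v[i].second.first;
      pos2[i] = v[i].second.second;
    }
    out[r] = List::create(_["val"] = val, _["pos"] = pos, _["pos2"] = pos2);
  }
  return out;
}

// ---------------------------------------------------------------------------
// first-stage candidate pairs
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List find_candidates_cpp(NumericMatrix sk, int min_match, int max_bucket) {
  const int s = sk.nrow();
  const R_xlen_t n = sk.ncol();
  std::unordered_map<uint64_t, int> paircount;
  paircount.reserve(1 << 16);
  std::unordered_map<uint64_t, std::vector<int> > bucket;
  for (int i = 0; i < s; ++i) {
    bucket.clear();
    for (R_xlen_t r = 0; r < n; ++r) {
      double v = sk(i, r);
      if (ISNA(v)) continue;
      bucket[(uint64_t)v].push_back((int)r);
    }
    for (auto& kv : bucket) {
      std::vector<int>& b = kv.second;
      if ((int)b.size() < 2 || (int)b.size() > max_bucket) continue;
      for (size_t x = 0; x < b.size(); ++x)
        for (size_t y = x + 1; y < b.size(); ++y) {
          uint64_t key = ((uint64_t)(uint32_t)b[x] << 32) | (uint32_t)b[y];
          ++paircount[key];
        }
    }
  }
  std::vector<std::pair<uint64_t, int> > keep;
  for (auto& kv : paircount)
    if (kv.second >= min_match) keep.push_back(kv);
  std::sort(keep.begin(), keep.end());
  IntegerVector a((R_xlen_t)keep.size()), b((R_xlen_t)keep.size()),
      m((R_xlen_t)keep.size());
  for (R_xlen_t i = 0; i < (R_xlen_t)keep.size(); ++i) {
    a[i] = (int)(keep[i].first >> 32) + 1;  // 1-based read indices for R
    b[i] = (int)(keep[i].first & 0xffffffffu) + 1;
    m[i] = keep[i].second;
  }
  return List::create(_["a"] = a, _["b"] = b, _["matches"] = m);
}

// ---------------------------------------------------------------------------
// second stage: bottom-sketch overlap estimation
// ---------------------------------------------------------------------------

static inline double sx_mash(double j, int k) {
  if (j <= 0) return 1.0;
  if (j >= 1) return 0.0;
  double d = -std::log(2.0 * j / (1.0 + j)) / (double)k;
  if (d < 0) d = 0;
  if (d > 1) d = 1;
  return d;
}

// [[Rcpp::export]]
double mash_distance_cpp(double j, int k) { return sx_mash(j, k); }

static double sx_median(std::vector<double>& v) {
  size_t n = v.size();
  std::sort(v.begin(), v.end());
  if (n == 0) return NA_REAL;
  if (n % 2 == 1) return v[n / 2];
  return 0.5 * (v[n / 2 - 1] + v[n / 2]);
}

// Mash-style Jaccard of two (filtered) sorted bottom sketches: walk the merged
// union in ascending hash order, keep the bottom s' = min(size, |union|)
// values, count how many occur in both.
static double sx_bottom_jaccard(const std::vector<double>& A,
                                const std::vector<double>& B, int size) {
  size_t i = 0, j = 0, used = 0, shared = 0;
  while ((i < A.size() || j < B.size()) && used < (size_t)size) {
    if (i < A.size() && (j >= B.size() || A[i] < B[j])) { ++i; }
    else if (j < B.size() && (i >= A.size() || B[j] < A[i])) { ++j; }
    else { ++shared; ++i; ++j; }
    ++used;
  }
  if (used == 0) return 0.0;
  return (double)shared / (double)used;
}

static double sx_median_inplace(std::vector<double>& v) {
  size_t n = v.size();
  if (n == 0) return 0.0;
  std::nth_element(v.begin(), v.begin() + n / 2, v.end());
  double hi = v[n / 2];
  if (n % 2 == 1) return hi;
  double lo = *std::max_element(v.begin(), v.begin() + n / 2);
  return 0.5 * (lo + hi);
}

// Estimate extent, orientation and Mash error for candidate pairs from bottom
// sketches.  Returns parallel vectors; ok = 0 marks pairs with no overlap.
// [[Rcpp::export]]
List estimate_overlaps_cpp(List bottoms, IntegerVector pa, IntegerVector pb,
                           IntegerVector lens, int k, int sketch_size,
                           int min_shared) {
  const R_xlen_t np = pa.size();
  IntegerVector ok(np), a_start(np), a_end(np), b_start(np), b_end(np),
      orient(np), shared_n(np), kind(np);
  NumericVector error(np), jaccard(np);

  // pre-extract sketch arrays once
  const R_xlen_t nb = bottoms.size();
  std::vector<const double*> valp(nb);
  std::vector<const int*> posp(nb);
  std::vector<R_xlen_t> nsk(nb);
  for (R_xlen_t r = 0; r < nb; ++r) {
    List s = bottoms[r];
    NumericVector v = s["val"];
    IntegerVector q = s["pos"];
    valp[r] = v.begin();
    posp[r] = q.begin();
    nsk[r] = v.size();
  }
  std::vector<int> apos, bpos;
  std::vector<double> dsame, dflip, tmp, consd, fa, fb;

  for (R_xlen_t p = 0; p < np; ++p) {
    ok[p] = 0;
    int ia = pa[p] - 1, ib = pb[p] - 1;
    const double* va = valp[ia];
    const double* vb = valp[ib];
    const int* qa = posp[ia];
    const int* qb = posp[ib];
    const R_xlen_t na = nsk[ia], nbv = nsk[ib];
    int la = lens[ia], lb = lens[ib];

    // shared min-mers with positions
    apos.clear(); bpos.clear();
    {
      R_xlen_t i = 0, j = 0;
      while (i < na && j < nbv) {
        if (va[i] < vb[j]) ++i;
        else if (vb[j] < va[i]) ++j;
        else { apos.push_back(qa[i]); bpos.push_back(qb[j]); ++i; ++j; }
      }
    }
    if ((int)apos.size() < min_shared) continue;

    // orientation from position consistency under same vs flipped transform
    dsame.resize(apos.size()); dflip.resize(apos.size());
    for (size_t t = 0; t < apos.size(); ++t) {
      dsame[t] = (double)apos[t] - (double)bpos[t];
      dflip[t] = (double)apos[t] - (double)(lb - k - bpos[t]);
    }
    tmp = dsame;
    double msame = sx_median_inplace(tmp);
    tmp = dflip;
    double mflip = sx_median_inplace(tmp);
    // the true orientation's offsets cluster tightly (indel drift only);
    // the wrong orientation's offsets vary across the whole overlap
    double tol = std::max(64.0, 0.02 * std::min(la, lb));
    int csame = 0, cflip = 0;
    double ssame = 0, sflip = 0;  // spread of consistent offsets
    for (size_t t = 0; t < apos.size(); ++t) {
      double es = std::fabs(dsame[t] - msame), ef = std::fabs(dflip[t] - mflip);
      if (es <= tol) { ++csame; ssame += es; }
      if (ef <= tol) { ++cflip; sflip += ef; }
    }
    bool flip;
    if (cflip != csame) flip = cflip > csame;
    else flip = csame > 0 && (sflip / std::max(cflip, 1) < ssame / std::max(csame, 1));
    int ccons = flip ? cflip : csame;
    if (ccons < min_shared) continue;
    consd.clear();
    consd.reserve(ccons);
    for (size_t t = 0; t < apos.size(); ++t) {
      double d = flip ? dflip[t] : dsame[t];
      double m = flip ? mflip : msame;
      if (std::fabs(d - m) <= tol) consd.push_back(d);
    }
    double offd = sx_median_inplace(consd);
    int off = (int)std::lround(offd);

    // extents: intersect A [0, la) with B projected at offset
    int as = std::max(0, off);
    int ae = std::min(la, off + lb);
    if (ae - as < k) continue;
    // B extent in oriented coordinates, then mapped to forward strand
    int bs_o = as - off, be_o = ae - off;
    int bs_f = flip ? (lb - be_o) : bs_o;
    int be_f = flip ? (lb - bs_o) : be_o;

    // Jaccard on the overlap substrings: drop min-mers outside the extent
    fa.clear(); fb.clear();
    for (R_xlen_t i = 0; i < na; ++i)
      if (qa[i] >= as && qa[i] <= ae - k) fa.push_back(va[i]);
    for (R_xlen_t j = 0; j < nbv; ++j)
      if (qb[j] >= bs_f && qb[j] <= be_f - k) fb.push_back(vb[j]);
    double jac = sx_bottom_jaccard(fa, fb, sketch_size);
    double err = sx_mash(jac, k);

    int slop = std::max(100, (int)(0.03 * std::min(la, lb)));
    bool cont_a = (as <= slop) && (la - ae <= slop);
    bool cont_b = (bs_f <= slop) && (lb - be_f <= slop);

    ok[p] = 1;
    a_start[p] = as; a_end[p] = ae;
    b_start[p] = bs_f; b_end[p] = be_f;
    orient[p] = flip ? 1 : 0;
    error[p] = err;
    jaccard[p] = jac;
    shared_n[p] = ccons;
    kind[p] = (cont_a || cont_b) ? 1 : 0;  // 1 containment, 0 dovetail
  }
  return List::create(_["ok"] = ok, _["a_start"] = a_start, _["a_end"] = a_end,
                      _["b_start"] = b_start, _["b_end"] = b_end,
                      _["orient"] = orient, _["error"] = error,
                      _["jaccard"] = jaccard, _["shared"] = shared_n,
                      _["kind"] = kind);
}

// ---------------------------------------------------------------------------
// small helpers for the R API and tests
// ---------------------------------------------------------------------------

// Canonical base hash of each k-mer string (whole string = one k-mer).
// [[Rcpp::export]]
NumericVector kmer_hash_cpp(CharacterVector kmers) {
  NumericVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string s = as<std::string>(kmers[i]);
    double h = NA_REAL;
    sx_each_kmer(s, (int)s.size(), [&](uint64_t hh, int) { h = (double)hh; });
    out[i] = h;
  }
  return out;
}

// All canonical k-mer hashes of a read with positions (for oracles).
// [[Rcpp::export]]
List read_kmer_hashes_cpp(std::string read, int k) {
  std::vector<double> h;
  std::vector<int> p;
  sx_each_kmer(read, k, [&](uint64_t hh, int pos) {
    h.push_back((double)hh);
    p.push_back(pos);
  });
  return List::create(_["hash"] = wrap(h), _["pos"] = wrap(p));
}

// Hairpin-pivot votes: a hairpin read contains a sequence followed by its
// reverse complement, so its (canonical) min-mers occur twice at positions
// mirrored around the adapter.  For each candidate pair, shared min-mers
// that are duplicated in read a vote for the pivot at the midpoint of their
// two occurrences; a partner votes when enough of its shared min-mers form
// a tight pivot cluster.
// [[Rcpp::export]]
List hairpin_votes_cpp(List bottoms, IntegerVector pa, IntegerVector pb,
                       IntegerVector lens, int k, int min_each) {
  std::vector<int> vid, vpivot;
  const R_xlen_t nb2 = bottoms.size();
  std::vector<const double*> valp(nb2);
  std::vector<const int*> posp(nb2), pos2p(nb2);
  std::vector<R_xlen_t> nsk(nb2);
  for (R_xlen_t r = 0; r < nb2; ++r) {
    List s = bottoms[r];
    NumericVector v = s["val"];
    IntegerVector q = s["pos"];
    IntegerVector q2 = s["pos2"];
    valp[r] = v.begin();
    posp[r] = q.begin();
    pos2p[r] = q2.begin();
    nsk[r] = v.size();
  }
  std::vector<double> mids;
  for (R_xlen_t p = 0; p < pa.size(); ++p) {
    int ia = pa[p] - 1, ib = pb[p] - 1;
    const double* va = valp[ia];
    const double* vb = valp[ib];
    const int* qa = posp[ia];
    const int* qa2 = pos2p[ia];
    mids.clear();
    {
      R_xlen_t i = 0, j = 0;
      while (i < nsk[ia] && j < nsk[ib]) {
        if (va[i] < vb[j]) ++i;
        else if (vb[j] < va[i]) ++j;
        else {
          if (qa2[i] - qa[i] >= k)  // duplicated in read a
            mids.push_back((qa[i] + qa2[i] + k) / 2.0);
          ++i; ++j;
        }
      }
    }
    if ((int)mids.size() < min_each) continue;
    // densest window of pivot midpoints
    std::sort(mids.begin(), mids.end());
    double tol = 100.0;
    size_t best = 0, bi = 0, j2 = 0;
    for (size_t i = 0; i < mids.size(); ++i) {
      while (j2 < mids.size() && mids[j2] <= mids[i] + 2 * tol) ++j2;
      if (j2 - i > best) { best = j2 - i; bi = i; }
    }
    if ((int)best < min_each) continue;
    vid.push_back(pa[p]);
    vpivot.push_back((int)std::lround(mids[bi + best / 2]));
  }
  return List::create(_["a"] = wrap(vid), _["pivot"] = wrap(vpivot));
}
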