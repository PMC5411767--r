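#include "sketchasm.h"
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// The banded overlap aligner itself lives in ovalign.cpp.

// ---------------------------------------------------------------------------
// batch DP overlap confirmation
// ---------------------------------------------------------------------------

struct SubHint {
  int subA0, subA1, subB0, subB1, d0;
};

static SubHint sx_make_hint(int la, int lbo, int as, int ae, int bos, int boe,
                            int band) {
  SubHint h;
  int margin = band + 60;
  h.subA0 = std::max(0, as - margin);
  h.subA1 = std::min(la, ae + margin);
  h.subB0 = std::max(0, bos - margin);
  h.subB1 = std::min(lbo, boe + margin);
  int i0 = as - h.subA0, j0 = bos - h.subB0;
  h.d0 = j0 - i0;
  return h;
}

// [[Rcpp::export]]
List dp_overlap_batch_cpp(CharacterVector seqs, IntegerVector pa,
                          IntegerVector pb, IntegerVector orient,
                          IntegerVector a_s, IntegerVector a_e,
                          IntegerVector b_s, IntegerVector b_e,
                          NumericVector err_est, int min_band, int max_band,
                          int min_ovl) {
  const R_xlen_t np = pa.size();
  IntegerVector ok(np), oa_s(np), oa_e(np), ob_s(np), ob_e(np), kind(np),
      nmatch(np), nedit(np), cols(np);
  NumericVector error(np);

  // cache forward and reverse-complement strings per read
  const R_xlen_t nreads = seqs.size();
  std::vector<std::string> fwd(nreads), rc(nreads);
  std::vector<char> have_fwd(nreads, 0), have_rc(nreads, 0);
  auto get_fwd = [&](int r) -> const std::string& {
    if (!have_fwd[r]) { fwd[r] = as<std::string>(seqs[r]); have_fwd[r] = 1; }
    return fwd[r];
  };
  auto get_rc = [&](int r) -> const std::string& {
    if (!have_rc[r]) { rc[r] = sx_revcomp(get_fwd(r)); have_rc[r] = 1; }
    return rc[r];
  };
  for (R_xlen_t p = 0; p < np; ++p) {
    ok[p] = 0;
    int ia = pa[p] - 1, ib = pb[p] - 1;
    const std::string& A = get_fwd(ia);
    const int la = (int)A.size(), lb = (int)get_fwd(ib).size();
    bool flip = orient[p] == 1;
    const std::string& Bo = flip ? get_rc(ib) : get_fwd(ib);
    // hint in oriented B coordinates
    int bos = flip ? (lb - b_e[p]) : b_s[p];
    int boe = flip ? (lb - b_s[p]) : b_e[p];
    int ovl = std::max(a_e[p] - a_s[p], boe - bos);

    int as0 = 0, ae0 = 0, bs_o = 0, be_o = 0;
    int nm = 0, ns = 0, ni = 0, nd = 0, ncols = 0;
    bool confirmed = false;

    // fast path: bit-parallel alignment of the hinted A interval into a
    // B window; falls back to the scored free-end aligner when the
    // alignment fails or shows a locally divergent (partial) structure
    {
      int bband = sx_band_bp(err_est[p], ovl);
      int bmargin = bband + 60;
      int aa0 = std::max(0, std::min(a_s[p], la));
      int aa1 = std::max(aa0, std::min(a_e[p], la));
      int bb0 = std::max(0, bos - bmargin);
      int bb1 = std::min(lb, boe + bmargin);
      if (aa1 - aa0 >= 100 && bb1 - bb0 >= 100) {
        BpAln al = sx_bp_align(A.substr(aa0, aa1 - aa0),
                               Bo.substr(bb0, bb1 - bb0), bos - bb0, bband,
                               true);
        if (al.ok && !al.ops.empty()) {
          int alf, blf, alt, blt;
          sx_trim_ops(al.ops, 10, &alf, &blf, &alt, &blt);
          // recount ops and scan 400-column windows for local divergence
          double wmax = 0;
          std::vector<double> werr;
          int we = 0, wn = 0;
          for (uint8_t op : al.ops) {
            switch (op) {
            case SX_OP_M: ++nm; break;
            case SX_OP_X: ++ns; ++we; break;
            case SX_OP_I: ++ni; ++we; break;
            case SX_OP_D: ++nd; ++we; break;
            }
            if (++wn == 400) {
              werr.push_back(we / 400.0);
              we = 0; wn = 0;
            }
          }
          if (wn > 200) werr.push_back((double)we / wn);
          ncols = nm + ns + ni + nd;
          if (ncols > 0) {
            double med = 0;
            if (!werr.empty()) {
              std::vector<double> ws = werr;
              std::nth_element(ws.begin(), ws.begin() + ws.size() / 2, ws.end());
              med = ws[ws.size() / 2];
              wmax = *std::max_element(werr.begin(), werr.end());
            }
            bool partial_suspect =
                wmax >= 0.04 && wmax >= 3.0 * std::max(med, 0.004);
            if (!partial_suspect) {
              as0 = aa0 + alf;
              ae0 = aa1 - alt;
              bs_o = bb0 + al.ja0 + blf;
              be_o = bb0 + al.ja1 - blt;
              confirmed = true;
            }
          }
        }
      }
    }

    if (!confirmed) {  // scored free-end alignment discovers true extents
      nm = ns = ni = nd = ncols = 0;
      int band = sx_band_for(err_est[p], ovl, min_band, max_band);
      SubHint h = sx_make_hint(la, lb, a_s[p], a_e[p], bos, boe, band);
      std::string a = A.substr(h.subA0, h.subA1 - h.subA0);
      std::string b = Bo.substr(h.subB0, h.subB1 - h.subB0);
      OvAln al = sx_ov_align(a, b, h.d0, band, true);
      if (!al.ok) continue;
      as0 = h.subA0 + al.ia0;
      ae0 = h.subA0 + al.ia1;
      bs_o = h.subB0 + al.ja0;
      be_o = h.subB0 + al.ja1;
      nm = al.nmatch; ns = al.nsub; ni = al.nins; nd = al.ndel;
      ncols = nm + ns + ni + nd;
    }
    if (ae0 - as0 < min_ovl && be_o - bs_o < min_ovl) continue;
    if (ncols <= 0) continue;

    int bs_f = flip ? (lb - be_o) : bs_o;
    int be_f = flip ? (lb - bs_o) : be_o;
    int slop = std::max(100, (int)(0.03 * std::min(la, lb)));
    bool cont_a = (as0 <= slop) && (la - ae0 <= slop);
    bool cont_b = (bs_o <= slop) && (lb - be_o <= slop);
    bool left_end = (as0 <= slop) || (bs_o <= slop);
    bool right_end = (la - ae0 <= slop) || (lb - be_o <= slop);

    ok[p] = 1;
    oa_s[p] = as0; oa_e[p] = ae0;
    ob_s[p] = bs_f; ob_e[p] = be_f;
    nmatch[p] = nm;
    nedit[p] = ns + ni + nd;
    cols[p] = ncols;
    error[p] = (double)(ns + ni + nd) / (double)ncols;
    kind[p] = (cont_a || cont_b) ? 1 : ((left_end && right_end) ? 0 : 2);
  }
  return List::create(_["ok"] = ok, _["a_start"] = oa_s, _["a_end"] = oa_e,
                      _["b_start"] = ob_s, _["b_end"] = ob_e,
                      _["error"] = error, _["nmatch"] = nmatch,
                      _["nedit"] = nedit, _["cols"] = cols, _["kind"] = kind);
}

// ---------------------------------------------------------------------------
// banded global edit distance (identity checks)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List band_edit_cpp(std::string a, std::string b, int extra_band) {
  const int m = (int)a.size(), n = (int)b.size();
  int band = std::abs(n - m) + std::max(16, extra_band);
  const int W = 2 * band + 1;
  std::vector<int> prev(W), cur(W);
  const int INF = 1 << 29;
  // row 0
  for (int id = 0; id < W; ++id) {
    int j = id + (0 - band);
    prev[id] = (j >= 0 && j <= n) ? j : INF;
  }
  for (int i = 1; i <= m; ++i) {
    const int center = i;
    const int jlo = std::max(0, center - band), jhi = std::min(n, center + band);
    std::fill(cur.begin(), cur.end(), INF);
    for (int j = jlo; j <= jhi; ++j) {
      const int id = j - (center - band);
      int best = INF;
      if (j == 0) best = i;
      if (j >= 1) {
        int sc = prev[id] + ((a[i - 1] == b[j - 1]) ? 0 : 1);
        if (sc < best) best = sc;
      }
      if (id + 1 < W && prev[id + 1] < INF) {
        int sc = prev[id + 1] + 1;
        if (sc < best) best = sc;
      }
      if (id > 0 && cur[id - 1] < INF) {
        int sc = cur[id - 1] + 1;
        if (sc < best) best = sc;
      }
      cur[id] = best;
    }
    std::swap(prev, cur);
  }
  int idn = n - (m - band);
  int dist = (idn >= 0 && idn < W) ? prev[idn] : INF;
  return List::create(_["dist"] = dist,
                      _["identity"] = 1.0 - (double)dist / std::max(1, std::max(m, n)));
}

// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    out[i] = sx_revcomp(as<std::string>(x[i]));
  return out;
}

// ---------------------------------------------------------------------------
// overlap error adjustment: voting and edit application
// ---------------------------------------------------------------------------

// Majority-vote error detection for ALL reads in one pass.  Overlap
// records must be grouped by target read (column `a`); partner sequences
// are cached (forward and reverse complement) across records.
// [[Rcpp::export]]
List vote_all_cpp(CharacterVector seqs, IntegerVector ta, IntegerVector tb,
                  IntegerVector orient, IntegerVector t_s, IntegerVector t_e,
                  IntegerVector b_s, IntegerVector b_e, NumericVector err_est,
                  int min_band, int max_band, double support_frac,
                  int min_cover) {
  const R_xlen_t nrec = ta.size();
  const R_xlen_t nreads = seqs.size();
  std::vector<std::string> fwd(nreads), rc(nreads);
  std::vector<char> have_fwd(nreads, 0), have_rc(nreads, 0);
  auto get_fwd = [&](int r) -> const std::string& {
    if (!have_fwd[r]) { fwd[r] = as<std::string>(seqs[r]); have_fwd[r] = 1; }
    return fwd[r];
  };
  auto get_rc = [&](int r) -> const std::string& {
    if (!have_rc[r]) { rc[r] = sx_revcomp(get_fwd(r)); have_rc[r] = 1; }
    return rc[r];
  };

  std::vector<int> e_id, e_pos, e_type, e_to, e_from, e_cover, e_support;
  std::vector<int> votes, insvote, insbase;

  R_xlen_t g0 = 0;
  while (g0 < nrec) {
    R_xlen_t g1 = g0;
    while (g1 < nrec && ta[g1] == ta[g0]) ++g1;
    const int tgt = ta[g0] - 1;
    const std::string& target = get_fwd(tgt);
    const int L = (int)target.size();
    votes.assign(5 * (size_t)L, 0);
    insvote.assign((size_t)L + 1, 0);
    insbase.assign(4 * ((size_t)L + 1), 0);

    for (R_xlen_t q = g0; q < g1; ++q) {
      int pr = tb[q] - 1;
      bool flip = orient[q] == 1;
      const std::string& P = flip ? get_rc(pr) : get_fwd(pr);
      int lp = (int)P.size();
      int ps = flip ? (lp - b_e[q]) : b_s[q];
      int pe = flip ? (lp - b_s[q]) : b_e[q];
      int ovl = std::max(t_e[q] - t_s[q], pe - ps);
      int bband = sx_band_bp(err_est[q], ovl);
      int bmargin = bband + 60;
      int ta0 = std::max(0, t_s[q] - bmargin);
      int ta1 = std::min(L, t_e[q] + bmargin);
      int pa0 = std::max(0, std::min(ps, lp));
      int pa1 = std::max(pa0, std::min(pe, lp));
      if (pa1 - pa0 < 50 || ta1 - ta0 < 50) continue;
      BpAln al = sx_bp_align(P.substr(pa0, pa1 - pa0),
                             target.substr(ta0, ta1 - ta0), t_s[q] - ta0,
                             bband, true);
      if (!al.ok) continue;
      int alf, blf, alt, blt;
      sx_trim_ops(al.ops, 10, &alf, &blf, &alt, &blt);
      int ai = pa0 + alf;           // partner coordinate
      int ti = ta0 + al.ja0 + blf;  // target coordinate
      bool in_ins = false;
      for (uint8_t op : al.ops) {
        switch (op) {
        case SX_OP_M:
        case SX_OP_X: {
          int c = sx_base_code(P[ai]);
          if (c >= 0 && ti < L) ++votes[5 * (size_t)ti + c];
          ++ai; ++ti; in_ins = false;
          break;
        }
        case SX_OP_I:  // target base unmatched: partner votes gap
          if (ti < L) ++votes[5 * (size_t)ti + 4];
          ++ti; in_ins = false;
          break;
        case SX_OP_D: {  // partner inserts before target position ti
          if (!in_ins && ti <= L) {
            ++insvote[ti];
            int c = sx_base_code(P[ai]);
            if (c >= 0) ++insbase[4 * (size_t)ti + c];
          }
          ++ai; in_ins = true;
          break;
        }
        }
      }
    }

    for (int p = 0; p < L; ++p) {
      const int* v = &votes[5 * (size_t)p];
      int cover = v[0] + v[1] + v[2] + v[3] + v[4];
      if (cover < min_cover) continue;
      int readb = sx_base_code(target[p]);
      if (readb < 0) continue;
      int top = 0;
      for (int c = 1; c < 5; ++c)
        if (v[c] > v[top]) top = c;
      if (top == readb) continue;
      if (2 * v[top] <= cover) continue;                       // strict majority
      if ((double)v[readb] >= support_frac * cover) continue;  // variant kept
      e_id.push_back(tgt + 1);
      e_pos.push_back(p);
      e_type.push_back(top == 4 ? 1 : 0);
      e_to.push_back(top == 4 ? -1 : top);
      e_from.push_back(readb);
      e_cover.push_back(cover);
      e_support.push_back(v[top]);
    }
    for (int p = 0; p <= L; ++p) {
      if (insvote[p] == 0) continue;
      auto colsum = [&](int q) {
        const int* v = &votes[5 * (size_t)q];
        return v[0] + v[1] + v[2] + v[3] + v[4];
      };
      int covL = (p > 0) ? colsum(p - 1) : insvote[p];
      int covR = (p < L) ? colsum(p) : insvote[p];
      int cov = std::min(covL, covR);
      if (cov < min_cover) continue;
      if (2 * insvote[p] <= cov) continue;
      if ((double)(cov - insvote[p]) >= support_frac * cov) continue;
      const int* ib = &insbase[4 * (size_t)p];
      int top = 0;
      for (int c = 1; c < 4; ++c)
        if (ib[c] > ib[top]) top = c;
      e_id.push_back(tgt + 1);
      e_pos.push_back(p);
      e_type.push_back(2);
      e_to.push_back(top);
      e_from.push_back(-1);
      e_cover.push_back(cov);
      e_support.push_back(insvote[p]);
    }
    g0 = g1;
  }
  return List::create(_["id"] = wrap(e_id), _["pos"] = wrap(e_pos),
                      _["type"] = wrap(e_type), _["to"] = wrap(e_to),
                      _["from"] = wrap(e_from), _["cover"] = wrap(e_cover),
                      _["support"] = wrap(e_support));
}

// [[Rcpp::export]]
std::string apply_edits_cpp(std::string seq, IntegerVector pos,
                            IntegerVector type, IntegerVector to) {
  static const char BASES[] = "ACGT";
  // apply right-to-left so positions stay valid
  std::vector<int> ord(pos.size());
  for (R_xlen_t i = 0; i < pos.size(); ++i) ord[i] = (int)i;
  std::sort(ord.begin(), ord.end(),
            [&](int x, int y) { return pos[x] > pos[y]; });
  for (int i : ord) {
    int p = pos[i];
    if (type[i] == 0 && p >= 0 && p < (int)seq.size()) {
      seq[p] = BASES[to[i] & 3];
    } else if (type[i] == 1 && p >= 0 && p < (int)seq.size()) {
      seq.erase((size_t)p, 1);
    } else if (type[i] == 2 && p >= 0 && p <= (int)seq.size()) {
      seq.insert((size_t)p, 1, BASES[to[i] & 3]);
    }
  }
  return seq;
}
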