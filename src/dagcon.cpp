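#include "sketchasm.h"
#include <unordered_map>
#include <algorithm>

using namespace Rcpp;

// Alignment-tag DAG consensus in the falcon_sense / pbdagcon family.
// Nodes are (template position, insertion offset delta, base) tags; every
// evidence alignment contributes a chain of tags, and consecutive tags add
// weight 1 to the connecting edge.  The consensus is the highest-total-weight
// path; template columns whose best advancing edge has weight < min_edge_w
// split the output into pieces.

static const int SX_DELTA_CAP = 100;

static inline uint64_t tag_key(int tpos, int delta, int base) {
  // tpos shifted by +1 so a virtual source could sit at 0 if ever needed
  return ((uint64_t)(uint32_t)(tpos + 1) << 16) | ((uint64_t)(delta & 0x1fff) << 3) |
         (uint64_t)(base & 7);
}
static inline int key_tpos(uint64_t k) { return (int)(k >> 16) - 1; }
static inline int key_base(uint64_t k) { return (int)(k & 7); }

// [[Rcpp::export]]
List dag_consensus_cpp(std::string templ, CharacterVector evidence,
                       IntegerVector t_s, IntegerVector t_e, IntegerVector p_s,
                       IntegerVector p_e, NumericVector err_est, int min_band,
                       int max_band, int min_edge_w, int min_piece_len,
                       bool include_template) {
  const int T = (int)templ.size();
  std::vector<std::vector<uint64_t> > chains;
  chains.reserve(evidence.size() + 1);

  if (include_template) {
    std::vector<uint64_t> ch;
    ch.reserve(T);
    for (int p = 0; p < T; ++p) {
      int c = sx_base_code(templ[p]);
      if (c < 0) c = 0;
      ch.push_back(tag_key(p, 0, c));
    }
    chains.push_back(std::move(ch));
  }

  int n_aligned = 0;
  for (R_xlen_t q = 0; q < evidence.size(); ++q) {
    std::string P = as<std::string>(evidence[q]);
    int lp = (int)P.size();
    int ovl = std::max(t_e[q] - t_s[q], p_e[q] - p_s[q]);
    std::vector<uint64_t> ch;
    bool built = false;

    // fast path: bit-parallel alignment of the evidence interval into a
    // template window
    {
      int bband = sx_band_bp(err_est[q], ovl);
      int bmargin = bband + 60;
      int ta0 = std::max(0, t_s[q] - bmargin);
      int ta1 = std::min(T, t_e[q] + bmargin);
      int pa0 = std::max(0, std::min(p_s[q], lp));
      int pa1 = std::max(pa0, std::min(p_e[q], lp));
      if (pa1 - pa0 >= 50 && ta1 - ta0 >= 50) {
        std::string ae = P.substr(pa0, pa1 - pa0);
        std::string bt = templ.substr(ta0, ta1 - ta0);
        int d0 = t_s[q] - ta0;
        BpAln al = sx_bp_align(ae, bt, d0, bband, true);
        if (al.ok) {
          int alf, blf, alt, blt;
          sx_trim_ops(al.ops, 10, &alf, &blf, &alt, &blt);
          int ai = pa0 + alf;           // evidence coordinate
          int ti = ta0 + al.ja0 + blf;  // template coordinate
          ch.reserve(al.ops.size());
          int delta = 0;
          int last_tpos = -2;
          for (uint8_t op : al.ops) {
            switch (op) {
            case SX_OP_M:
            case SX_OP_X: {
              int c = sx_base_code(P[ai]);
              if (c >= 0 && ti < T) {
                ch.push_back(tag_key(ti, 0, c));
                last_tpos = ti;
              }
              delta = 0;
              ++ai; ++ti;
              break;
            }
            case SX_OP_I:  // consumes template: evidence lacks this base
              if (ti < T) {
                ch.push_back(tag_key(ti, 0, 4));
                last_tpos = ti;
              }
              delta = 0;
              ++ti;
              break;
            case SX_OP_D: {  // consumes evidence: insertion vs template
              if (last_tpos >= -1 && delta < SX_DELTA_CAP) {
                ++delta;
                int c = sx_base_code(P[ai]);
                if (c >= 0) ch.push_back(tag_key(last_tpos, delta, c));
              }
              ++ai;
              break;
            }
            }
          }
          built = true;
        }
      }
    }

    if (!built) {  // fallback: scored free-end alignment (template as rows)
      int band = sx_band_for(err_est[q], ovl, min_band, max_band);
      int margin = band + 60;
      int subA0 = std::max(0, t_s[q] - margin);
      int subA1 = std::min(T, t_e[q] + margin);
      int subB0 = std::max(0, p_s[q] - margin);
      int subB1 = std::min(lp, p_e[q] + margin);
      int d0 = (p_s[q] - subB0) - (t_s[q] - subA0);
      std::string a = templ.substr(subA0, subA1 - subA0);
      std::string b = P.substr(subB0, subB1 - subB0);
      OvAln al = sx_ov_align(a, b, d0, band, true);
      if (!al.ok) continue;
      ch.reserve(al.ops.size());
      int ai = subA0 + al.ia0;
      int bi = subB0 + al.ja0;
      int delta = 0;
      int last_tpos = -2;
      for (uint8_t op : al.ops) {
        switch (op) {
        case SX_OP_M:
        case SX_OP_X: {
          int c = sx_base_code(P[bi]);
          if (c >= 0 && ai < T) {
            ch.push_back(tag_key(ai, 0, c));
            last_tpos = ai;
          }
          delta = 0;
          ++ai; ++bi;
          break;
        }
        case SX_OP_D:
          if (ai < T) {
            ch.push_back(tag_key(ai, 0, 4));
            last_tpos = ai;
          }
          delta = 0;
          ++ai;
          break;
        case SX_OP_I: {
          if (last_tpos >= -1 && delta < SX_DELTA_CAP) {
            ++delta;
            int c = sx_base_code(P[bi]);
            if (c >= 0) ch.push_back(tag_key(last_tpos, delta, c));
          }
          ++bi;
          break;
        }
        }
      }
    }
    if (!ch.empty()) {
      ++n_aligned;
      chains.push_back(std::move(ch));
    }
  }

  // node table and edge counts
  std::unordered_map<uint64_t, int> node_id;
  std::vector<uint64_t> node_key;
  std::unordered_map<uint64_t, int> edge_count;
  node_id.reserve(1 << 16);
  edge_count.reserve(1 << 17);
  auto get_id = [&](uint64_t k) {
    auto it = node_id.find(k);
    if (it != node_id.end()) return it->second;
    int id = (int)node_key.size();
    node_id.emplace(k, id);
    node_key.push_back(k);
    return id;
  };
  for (auto& ch : chains) {
    int prev = -1;
    for (uint64_t k : ch) {
      int id = get_id(k);
      if (prev >= 0 && prev != id) {
        uint64_t ek = ((uint64_t)(uint32_t)prev << 32) | (uint32_t)id;
        ++edge_count[ek];
      }
      prev = id;
    }
  }

  // advance support per template column transition: the total weight of
  // parallel edges crossing into column c (each aligned read crosses a
  // junction once, so this is the local evidence coverage of the junction)
  std::vector<int> support((size_t)T + 1, 0);
  for (auto& kv : edge_count) {
    int u = (int)(kv.first >> 32), v = (int)(kv.first & 0xffffffffu);
    int tu = key_tpos(node_key[u]), tv = key_tpos(node_key[v]);
    if (tv > tu && tv >= 0 && tv <= T) support[tv] += kv.second;
  }
  // column presence: a column is covered when either of its adjacent
  // junctions carries enough advancing weight
  std::vector<int> colw((size_t)T + 1, 0);
  for (int c = 0; c < T; ++c)
    colw[c] = std::max(support[c], (c + 1 <= T) ? support[c + 1] : 0);

  // segments of template columns
  std::vector<std::pair<int, int> > segs;  // [c0, c1] inclusive columns
  if (min_edge_w <= 1) {
    if (T > 0) segs.push_back(std::make_pair(0, T - 1));
  } else {
    int c0 = -1;
    for (int c = 0; c < T; ++c) {
      bool okcol = colw[c] >= min_edge_w;
      bool okadv = (c0 < 0) ? okcol : (support[c] >= min_edge_w && okcol);
      if (okadv) {
        if (c0 < 0) c0 = c;
      } else {
        if (c0 >= 0) segs.push_back(std::make_pair(c0, c - 1));
        c0 = okcol ? c : -1;
      }
    }
    if (c0 >= 0) segs.push_back(std::make_pair(c0, T - 1));
  }

  // sort nodes topologically: key order (tpos, delta, base) is topological
  const int nv = (int)node_key.size();
  std::vector<int> order(nv);
  for (int i = 0; i < nv; ++i) order[i] = i;
  std::sort(order.begin(), order.end(), [&](int x, int y) {
    return node_key[x] < node_key[y];
  });
  std::vector<int> rank(nv);
  for (int i = 0; i < nv; ++i) rank[order[i]] = i;

  // incoming edges per node (by rank)
  std::vector<std::vector<std::pair<int, int> > > incoming(nv);
  for (auto& kv : edge_count) {
    int u = (int)(kv.first >> 32), v = (int)(kv.first & 0xffffffffu);
    incoming[rank[v]].push_back(std::make_pair(rank[u], kv.second));
  }
  for (auto& in : incoming)
    std::sort(in.begin(), in.end());

  std::vector<std::string> pieces;
  std::vector<int> piece_s, piece_e, piece_nev;

  std::vector<long> score(nv);
  std::vector<int> pred(nv);

  for (auto& seg : segs) {
    int c0 = seg.first, c1 = seg.second;
    long bests = -1;
    int bestv = -1;
    for (int r = 0; r < nv; ++r) {
      int v = order[r];
      int tp = key_tpos(node_key[v]);
      if (tp < c0 || tp > c1) { score[r] = -1; pred[r] = -1; continue; }
      long sc = 0;
      int pr = -1;
      bool v_is_templ = (tp >= 0 && tp < T && key_base(node_key[v]) ==
                         sx_base_code(templ[tp]) &&
                         ((node_key[v] >> 3) & 0x1fff) == 0);
      for (auto& e : incoming[r]) {
        if (e.first < 0 || score[e.first] < 0) continue;
        int utp = key_tpos(node_key[order[e.first]]);
        if (utp < c0) continue;
        long cand = score[e.first] + e.second;
        if (cand > sc) { sc = cand; pr = e.first; }
      }
      score[r] = sc;
      pred[r] = pr;
      if (sc > bests || (sc == bests && v_is_templ)) {
        bests = sc;
        bestv = r;
      }
    }
    if (bestv < 0 || bests <= 0) continue;
    // traceback, keeping each node's incoming edge weight
    std::vector<int> path_nodes;
    std::vector<int> path_w;  // weight of the edge into each node (0 at start)
    int r = bestv;
    while (r >= 0) {
      path_nodes.push_back(order[r]);
      int pr = pred[r];
      int w = 0;
      if (pr >= 0) {
        uint64_t ek = ((uint64_t)(uint32_t)order[pr] << 32) | (uint32_t)order[r];
        auto it = edge_count.find(ek);
        if (it != edge_count.end()) w = it->second;
      }
      path_w.push_back(w);
      r = pr;
    }
    std::reverse(path_nodes.begin(), path_nodes.end());
    std::reverse(path_w.begin(), path_w.end());
    // trim path tails supported only by a single sequence (e.g. the
    // template beyond the evidence): keep the span between the first and
    // last edges of weight >= 2 when any exist
    int lo_i2 = 0, hi_i2 = (int)path_nodes.size() - 1;
    {
      int first_strong = -1, last_strong = -1;
      for (int t = 1; t < (int)path_nodes.size(); ++t) {
        if (path_w[t] >= 2) {
          if (first_strong < 0) first_strong = t - 1;
          last_strong = t;
        }
      }
      if (first_strong >= 0) { lo_i2 = first_strong; hi_i2 = last_strong; }
    }
    std::string out;
    int pstart = key_tpos(node_key[path_nodes[lo_i2]]);
    int pend = key_tpos(node_key[path_nodes[hi_i2]]) + 1;
    for (int t = lo_i2; t <= hi_i2; ++t) {
      int b = key_base(node_key[path_nodes[t]]);
      if (b < 4) out.push_back("ACGT"[b]);
    }
    if ((int)out.size() >= min_piece_len) {
      pieces.push_back(out);
      piece_s.push_back(pstart);
      piece_e.push_back(pend);
      piece_nev.push_back(n_aligned);
    }
  }

  return List::create(_["piece"] = wrap(pieces), _["start"] = wrap(piece_s),
                      _["end"] = wrap(piece_e), _["n_evidence"] = n_aligned,
                      _["n_pieces"] = (int)pieces.size());
}
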