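#include <Rcpp.h>
#include <string>
#include <vector>
#include <queue>
#include <set>
#include <array>
#include <unordered_map>
#include <algorithm>
using namespace Rcpp;

// Ungapped overlap scoring: match +1, mismatch -2 (fixed). An overlap
// qualifies when it contains an exact stretch >= min_seed, its score is
// >= min_score and its mismatch fraction is <= max_mm_frac.

static std::string revcomp_str(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) {
    switch (c) {
    case 'A': c = 'T'; break;
    case 'C': c = 'G'; break;
    case 'G': c = 'C'; break;
    case 'T': c = 'A'; break;
    default:  c = 'N'; break;
    }
  }
  return r;
}

struct OvlEval {
  int ovlen = 0, matches = 0, mismatches = 0, score = 0, max_exact = 0;
};

// offset: position of b's start relative to a's start (0-based, may be < 0)
static OvlEval eval_overlap(const std::string &a, const std::string &b,
                            int offset) {
  OvlEval e;
  int astart = std::max(0, offset);
  int aend = std::min((int) a.size(), offset + (int) b.size());
  if (aend <= astart) return e;
  e.ovlen = aend - astart;
  int run = 0;
  for (int i = astart; i < aend; ++i) {
    char ca = a[i], cb = b[i - offset];
    if (ca == cb && ca != 'N') {
      ++e.matches;
      if (++run > e.max_exact) e.max_exact = run;
    } else {
      ++e.mismatches;
      run = 0;
    }
  }
  e.score = e.matches - 2 * e.mismatches;
  return e;
}

static bool qualifies(const OvlEval &e, int min_seed, int min_score,
                      double max_mm_frac) {
  return e.ovlen > 0 && e.max_exact >= min_seed && e.score >= min_score &&
         (double) e.mismatches <= max_mm_frac * (double) e.ovlen;
}

// Exhaustive scan over all offsets and both orientations of b; returns the
// best qualifying overlap or NULL. Tie-break: higher score, then larger
// overlap, then '+' orientation, then smaller offset.
// [[Rcpp::export]]
SEXP best_overlap_cpp(std::string a, std::string b, int min_seed,
                      int min_score, double max_mm_frac) {
  bool found = false;
  OvlEval best;
  int best_off = 0, best_orient = 0;
  for (int orient = 0; orient < 2; ++orient) {
    std::string bo = orient ? revcomp_str(b) : b;
    int lo = -((int) bo.size() - min_seed);
    int hi = (int) a.size() - min_seed;
    for (int off = lo; off <= hi; ++off) {
      OvlEval e = eval_overlap(a, bo, off);
      if (!qualifies(e, min_seed, min_score, max_mm_frac)) continue;
      bool better = !found;
      if (found) {
        if (e.score != best.score) better = e.score > best.score;
        else if (e.ovlen != best.ovlen) better = e.ovlen > best.ovlen;
        else if (orient != best_orient) better = orient < best_orient;
        else better = off < best_off;
      }
      if (better) {
        found = true;
        best = e;
        best_off = off;
        best_orient = orient;
      }
    }
  }
  if (!found) return R_NilValue;
  return List::create(
      _["offset"] = best_off,
      _["orientation"] = best_orient == 0 ? "+" : "-",
      _["score"] = best.score, _["overlap_len"] = best.ovlen,
      _["matches"] = best.matches, _["mismatches"] = best.mismatches);
}

// ---------------------------------------------------------------------------
// Greedy layout-based overlap-layout-consensus assembly.
//
// All qualifying pairwise read overlaps are ranked by score; overlaps are
// consumed best-first, merging the two reads' contigs by placing one layout
// into the coordinate frame of the other (union-find, smaller into larger).
// The consensus of each final contig is a per-column majority vote over its
// member reads; ties go to the member earliest in input order.

struct Member {
  int read;    // index into input reads
  int offset;  // 0-based offset of (oriented) read within the contig frame
  bool rc;
};

struct Cand {
  int score, ovlen, orient, offset, i, j;
};
struct CandWorse {
  bool operator()(const Cand &x, const Cand &y) const {
    if (x.score != y.score) return x.score < y.score;
    if (x.ovlen != y.ovlen) return x.ovlen < y.ovlen;
    if (x.orient != y.orient) return x.orient > y.orient;
    if (x.offset != y.offset) return x.offset > y.offset;
    if (x.i != y.i) return x.i > y.i;
    return x.j > y.j;
  }
};

// placement of a segment of length len_x given relative coords (dx, ox)
// w.r.t. the forward orientation of a read placed at (off_r, rc_r, len_r)
static inline void place_via(int off_r, bool rc_r, int len_r, int dx, bool ox,
                             int len_x, int &out_off, bool &out_rc) {
  if (!rc_r) {
    out_off = off_r + dx;
    out_rc = ox;
  } else {
    out_off = off_r + len_r - dx - len_x;
    out_rc = !ox;
  }
}

// [[Rcpp::export]]
List assemble_cpp(CharacterVector seqs, int min_seed, int min_score,
                  double max_mm_frac) {
  const int n = seqs.size();
  std::vector<std::string> reads(n);
  std::vector<int> rlen(n);
  for (int i = 0; i < n; ++i) {
    reads[i] = as<std::string>(seqs[i]);
    rlen[i] = (int) reads[i].size();
  }

  // ---- candidate read pairs via shared exact k-mers (k = min_seed) ----
  typedef std::unordered_map<std::string,
                             std::vector<std::pair<int, int>>> KmerIdx;
  KmerIdx idx;
  std::priority_queue<Cand, std::vector<Cand>, CandWorse> heap;
  const int k = min_seed;
  for (int j = 0; j < n; ++j) {
    // scan j (both orientations) against reads 0..j-1 already indexed
    std::set<std::array<int, 3>> cands;
    for (int orient = 0; orient < 2; ++orient) {
      std::string q = orient ? revcomp_str(reads[j]) : reads[j];
      if ((int) q.size() < k) continue;
      for (int p = 0; p + k <= (int) q.size(); ++p) {
        std::string km = q.substr(p, k);
        if (km.find_first_not_of("ACGT") != std::string::npos) continue;
        KmerIdx::const_iterator it = idx.find(km);
        if (it == idx.end()) continue;
        for (size_t h = 0; h < it->second.size(); ++h) {
          int i = it->second[h].first;
          if (i == j) continue;
          cands.insert({i, orient, it->second[h].second - p});
        }
      }
    }
    for (const auto &c : cands) {
      const std::string bo =
          c[1] ? revcomp_str(reads[j]) : reads[j];
      OvlEval e = eval_overlap(reads[c[0]], bo, c[2]);
      if (qualifies(e, min_seed, min_score, max_mm_frac))
        heap.push({e.score, e.ovlen, c[1], c[2], c[0], j});
    }
    if (rlen[j] >= k) {
      for (int p = 0; p + k <= rlen[j]; ++p) {
        std::string km = reads[j].substr(p, k);
        if (km.find_first_not_of("ACGT") != std::string::npos) continue;
        idx[km].push_back(std::make_pair(j, p));
      }
    }
  }

  // ---- union-find layout merging ----
  std::vector<int> contig_of(n);
  std::vector<int> off(n, 0);
  std::vector<char> rc(n, 0);
  std::vector<std::vector<int>> members(n);
  for (int i = 0; i < n; ++i) {
    contig_of[i] = i;
    members[i].push_back(i);
  }

  while (!heap.empty()) {
    Cand c = heap.top();
    heap.pop();
    int ci = contig_of[c.i], cj = contig_of[c.j];
    if (ci == cj) continue;
    // overlap: oriented read j placed at c.offset relative to read i forward
    bool merge_j_into_i = members[ci].size() >= members[cj].size();
    int src, dst, anchor_dst, anchor_src, dx;
    bool ox;
    if (merge_j_into_i) {
      dst = ci; src = cj; anchor_dst = c.i; anchor_src = c.j;
      dx = c.offset; ox = c.orient != 0;
    } else {
      dst = cj; src = ci; anchor_dst = c.j; anchor_src = c.i;
      // invert: read i relative to read j forward
      if (!c.orient) {
        dx = -c.offset;
        ox = false;
      } else {
        dx = rlen[c.j] + c.offset - rlen[c.i];
        ox = true;
      }
    }
    // placement of anchor_src (forward) in dst frame, via anchor_dst
    int pos_src;
    bool or_src;
    place_via(off[anchor_dst], rc[anchor_dst] != 0, rlen[anchor_dst], dx, ox,
              rlen[anchor_src], pos_src, or_src);
    // transform every member of src into dst frame, via anchor_src
    int aoff = off[anchor_src];
    bool arc = rc[anchor_src] != 0;
    int alen = rlen[anchor_src];
    for (int m : members[src]) {
      // member relative to anchor_src forward within the src frame
      int dm;
      bool om;
      if (!arc) {
        dm = off[m] - aoff;
        om = rc[m] != 0;
      } else {
        dm = aoff + alen - off[m] - rlen[m];
        om = rc[m] == 0;
      }
      int noff;
      bool nrc;
      place_via(pos_src, or_src, alen, dm, om, rlen[m], noff, nrc);
      off[m] = noff;
      rc[m] = nrc ? 1 : 0;
      contig_of[m] = dst;
      members[dst].push_back(m);
    }
    members[src].clear();
  }

  // ---- consensus voting per final contig ----
  std::vector<int> roots;
  for (int i = 0; i < n; ++i)
    if (!members[i].empty()) roots.push_back(i);
  // order: more members first, then earliest member read
  std::sort(roots.begin(), roots.end(), [&](int x, int y) {
    if (members[x].size() != members[y].size())
      return members[x].size() > members[y].size();
    return *std::min_element(members[x].begin(), members[x].end()) <
           *std::min_element(members[y].begin(), members[y].end());
  });

  static const char *B = "ACGTN";
  List out(roots.size());
  for (size_t a = 0; a < roots.size(); ++a) {
    std::vector<int> mem = members[roots[a]];
    std::sort(mem.begin(), mem.end());  // input order = tie-break priority
    int mn = off[mem[0]], mx = 0;
    for (int m : mem) mn = std::min(mn, off[m]);
    for (int m : mem) mx = std::max(mx, off[m] - mn + rlen[m]);
    std::vector<std::array<int, 5>> cnt(mx, std::array<int, 5>{0, 0, 0, 0, 0});
    std::vector<int> depth(mx, 0);
    std::vector<std::string> oriented(mem.size());
    for (size_t t = 0; t < mem.size(); ++t) {
      int m = mem[t];
      oriented[t] = rc[m] ? revcomp_str(reads[m]) : reads[m];
      int o = off[m] - mn;
      for (int p = 0; p < rlen[m]; ++p) {
        int bi = 4;
        switch (oriented[t][p]) {
        case 'A': bi = 0; break;
        case 'C': bi = 1; break;
        case 'G': bi = 2; break;
        case 'T': bi = 3; break;
        }
        cnt[o + p][bi]++;
        depth[o + p]++;
      }
    }
    std::string cons(mx, 'N');
    for (int col = 0; col < mx; ++col) {
      int best = 0;
      for (int bi = 1; bi < 5; ++bi)
        if (cnt[col][bi] > cnt[col][best]) best = bi;
      int nb = 0;
      for (int bi = 0; bi < 5; ++bi)
        if (cnt[col][bi] == cnt[col][best]) ++nb;
      if (nb > 1) {
        for (size_t t = 0; t < mem.size(); ++t) {
          int o = off[mem[t]] - mn;
          if (col >= o && col < o + rlen[mem[t]]) {
            char ch = oriented[t][col - o];
            int bi = 4;
            switch (ch) {
            case 'A': bi = 0; break;
            case 'C': bi = 1; break;
            case 'G': bi = 2; break;
            case 'T': bi = 3; break;
            }
            if (cnt[col][bi] == cnt[col][best]) {
              best = bi;
              break;
            }
          }
        }
      }
      cons[col] = B[best];
    }
    IntegerVector rd(mem.size()), of(mem.size());
    LogicalVector rcv(mem.size());
    for (size_t t = 0; t < mem.size(); ++t) {
      rd[t] = mem[t] + 1;
      of[t] = off[mem[t]] - mn + 1;  // 1-based
      rcv[t] = rc[mem[t]] != 0;
    }
    out[a] = List::create(_["consensus"] = cons, _["read"] = rd,
                          _["offset"] = of, _["rc"] = rcv,
                          _["depth"] = wrap(depth));
  }
  return out;
}
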